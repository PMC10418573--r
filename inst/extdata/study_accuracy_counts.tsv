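# Per-stimulus counts of clinicians and non-clinicians who correctly or
# incorrectly judged whether the image shows a person affected by a genetic
# condition, from the motivating eye-tracking study (16 stimuli, in
# presentation order). name_* columns count responses that also named the
# correct condition; missing eye-tracking results make row totals uneven.
stimulus	clinician_correct	clinician_incorrect	clinician_named	nonclinician_correct	nonclinician_incorrect	nonclinician_named
WS	17	5	4	13	9	3
Unaffected_1	22	0	0	19	3	0
RSTS1	21	0	3	21	1	0
Unaffected_2	19	3	0	14	8	0
WHS	20	2	0	19	3	0
Unaffected_3	22	0	0	20	2	0
CdLS	22	0	10	22	0	5
DS	22	0	18	21	1	1
Unaffected_4	15	6	0	15	6	0
KS	19	3	11	13	9	2
NS	21	0	9	21	0	0
Unaffected_5	18	4	0	18	4	0
22q11DS	21	1	3	19	3	0
PWS	16	5	0	10	12	0
Unaffected_6	14	8	0	19	3	0
BWS	8	13	1	5	17	0
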
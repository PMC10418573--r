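# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A fixation sequence from a compact matrix (x, y, onset, duration).
make_seq <- function(m, participant = "p1", group = "clinician",
                     stimulus = "s1", viewing_ms = 7000) {
  df <- as.data.frame(m)
  names(df) <- c("x_px", "y_px", "onset_ms", "duration_ms")
  fixation_sequence(participant, group, stimulus, df, viewing_ms = viewing_ms)
}

# Random binary map of given dimensions with on-probability p.
random_mask <- function(h, w, p = 0.5, kind = "low") {
  structure(matrix(as.integer(stats::runif(h * w) < p), h, w),
            threshold_kind = kind, source_kind = "gaze",
            class = c("binary_map", "matrix", "array"))
}

# Random nonnegative attention map.
random_map <- function(h, w, kind = "gaze") {
  attention_map(matrix(stats::rexp(h * w), h, w), kind = kind)
}

# Brute-force IoU by explicit cell counting.
iou_bruteforce <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1L
      if (a[i, j] == 1 || b[i, j] == 1) uni <- uni + 1L
    }
  }
  if (uni == 0L) 0 else inter / uni
}

# A small synthetic cohort configuration for fast end-to-end tests;
# overrides win over the small defaults.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_clinicians = 6, n_non_clinicians = 6, n_stimuli = 4,
         n_affected = 2, image_px = 96),
    list(...))
  do.call(cohort_config, args)
}
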
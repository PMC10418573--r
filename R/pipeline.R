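# Orchestration: simulate -> preprocess -> compare -> saliency -> stats,
# from one config, with TSV/JSON report output.

#' Pipeline run configuration
#'
#' Bundles the module configurations and the master seed. `cohort` entries
#' override [cohort_config()] defaults; `heatmap`, `compare`, and `saliency`
#' hold the preprocessing, thresholding/bootstrap, and occlusion settings.
#'
#' @param cohort named list of [cohort_config()] overrides.
#' @param heatmap list: `radius_px` (25), `kernel` (`"linear"`), `smooth_px`
#'   (11).
#' @param compare list: `q_low` (0.25), `q_high` (0.75), `n_boot` (1000).
#' @param saliency list: `enabled` (`TRUE`), `box_px` (20), `stride_px`
#'   (10), `fill` (`"mean"`); set `enabled = FALSE` to skip the saliency
#'   stage.
#' @param seed master seed for all randomness in the run.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = list(), heatmap = list(), compare = list(),
                       saliency = list(), seed = 0) {
  hm <- utils::modifyList(list(radius_px = 25, kernel = "linear",
                               smooth_px = 11), heatmap)
  cp <- utils::modifyList(list(q_low = 0.25, q_high = 0.75, n_boot = 1000),
                          compare)
  sl <- utils::modifyList(list(enabled = TRUE, box_px = 20, stride_px = 10,
                               fill = "mean"), saliency)
  structure(list(cohort = cohort, heatmap = hm, compare = cp, saliency = sl,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(cohort = if (is.null(y$cohort)) list() else y$cohort,
             heatmap = if (is.null(y$heatmap)) list() else y$heatmap,
             compare = if (is.null(y$compare)) list() else y$compare,
             saliency = if (is.null(y$saliency)) list() else y$saliency,
             seed = if (is.null(y$seed)) 0 else y$seed)
}

# Per-stimulus subgroup membership: participants who did / did not correctly
# judge that stimulus. Membership is recomputed per stimulus — a participant
# correct on stimulus A and wrong on B is "successful" for A only.
subgroup_members <- function(responses, stimulus_id, group, successful) {
  sel <- responses$stimulus_id == stimulus_id & responses$group == group &
    responses$judgment != "missing" & !is.na(responses$judgment)
  correct <- responses$judgment == responses$truth
  responses$participant_id[sel & (correct == successful)]
}

# The four participant-group comparisons mirrored in the report.
PIPELINE_COMPARISONS <- list(
  succ_clin_vs_succ_nonclin = list(a = c("clinician", TRUE),
                                   b = c("non_clinician", TRUE)),
  succ_vs_under_clin = list(a = c("clinician", TRUE),
                            b = c("clinician", FALSE)),
  succ_vs_under_nonclin = list(a = c("non_clinician", TRUE),
                               b = c("non_clinician", FALSE)),
  under_clin_vs_under_nonclin = list(a = c("clinician", FALSE),
                                     b = c("non_clinician", FALSE))
)

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the study (stimuli, fixations, responses), preprocesses both
#' participant groups, runs the per-stimulus subgroup IoU comparisons with
#' bootstrap standard errors and random-effects pooling at both thresholds,
#' optionally computes toy-classifier occlusion saliency and its
#' threshold-matched IoU against successful clinicians, and computes the
#' cohort accuracy contingency analysis. Deterministic given the config.
#'
#' @param cfg a [run_config()].
#' @param progress print one line per stage (default `FALSE`).
#' @return a report bundle: list with `stimuli`, `responses`,
#'   `contingency`, `accuracy`, `chi_square`, `preprocessed` (per group),
#'   `comparisons` (per comparison and threshold: per-stimulus effects and
#'   the pooled `meta_result`), `saliency` (or `NULL`), and `config`.
#' @export
run_pipeline <- function(cfg = run_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (progress) message("[pipeline] ", ...)
  ccfg <- do.call(cohort_config, utils::modifyList(cfg$cohort,
                                                   list(seed = cfg$seed)))
  px <- ccfg$image_px

  say("simulate: ", ccfg$n_stimuli, " stimuli, ",
      ccfg$n_clinicians + ccfg$n_non_clinicians, " participants at ",
      px, " px")
  stimuli <- gen_stimuli(ccfg)
  cohort <- gen_cohort(ccfg, stimuli)
  responses <- gen_responses(ccfg, stimuli)

  contingency <- build_contingency(responses)
  acc <- accuracy(contingency)
  chi <- chi_square(contingency)

  say("preprocess")
  pcfg <- preprocess_config(radius_px = cfg$heatmap$radius_px,
                            kernel = cfg$heatmap$kernel,
                            smooth_px = cfg$heatmap$smooth_px)
  pre <- lapply(stats::setNames(GROUP_LEVELS, GROUP_LEVELS), function(g) {
    preprocess_group(cohort$sequences, g, px, px, pcfg)
  })

  say("compare: ", length(PIPELINE_COMPARISONS), " comparisons x 2 thresholds")
  sids <- vapply(stimuli, function(s) s$stimulus_id, "")
  run_comparison <- function(name, side_a, side_b) {
    lapply(stats::setNames(c("low", "high"), c("low", "high")), function(kind) {
      effects <- list()
      for (sid in sids) {
        ids_a <- subgroup_members(responses, sid, side_a[1],
                                  as.logical(side_a[2]))
        ids_b <- subgroup_members(responses, sid, side_b[1],
                                  as.logical(side_b[2]))
        maps_a <- pre[[side_a[1]]]$participant_maps[[sid]]
        maps_b <- pre[[side_b[1]]]$participant_maps[[sid]]
        maps_a <- maps_a[names(maps_a) %in% ids_a]
        maps_b <- maps_b[names(maps_b) %in% ids_b]
        if (length(maps_a) == 0L || length(maps_b) == 0L) next
        effects[[sid]] <- bootstrap_iou(
          unname(maps_a), unname(maps_b), kind = kind,
          n_boot = cfg$compare$n_boot,
          seed = str_seed(paste(name, kind, sid), base = cfg$seed),
          q_low = cfg$compare$q_low, q_high = cfg$compare$q_high,
          common_a = pre[[side_a[1]]]$common,
          common_b = pre[[side_b[1]]]$common,
          smooth_px = cfg$heatmap$smooth_px, stimulus_id = sid)
      }
      meta <- if (length(effects) >= 2) {
        suppressWarnings(re_meta_analysis(unname(effects)))
      } else {
        NULL
      }
      list(effects = unname(effects), meta = meta)
    })
  }
  comparisons <- lapply(stats::setNames(names(PIPELINE_COMPARISONS),
                                        names(PIPELINE_COMPARISONS)),
                        function(nm) {
    run_comparison(nm, PIPELINE_COMPARISONS[[nm]]$a,
                   PIPELINE_COMPARISONS[[nm]]$b)
  })

  saliency_res <- NULL
  if (isTRUE(cfg$saliency$enabled)) {
    say("saliency: occlusion maps for affected stimuli")
    affected <- Filter(function(s) s$truth == "affected", stimuli)
    sal_effects <- list(low = list(), high = list())
    for (st in affected) {
      clf <- toy_classifier(st$target_region, input_size = px)
      sal <- occlusion_map(clf, st$image, label_index = 2,
                           box_px = cfg$saliency$box_px,
                           stride_px = cfg$saliency$stride_px,
                           fill = cfg$saliency$fill)
      sid <- st$stimulus_id
      ids <- subgroup_members(responses, sid, "clinician", TRUE)
      maps <- pre$clinician$participant_maps[[sid]]
      maps <- maps[names(maps) %in% ids]
      if (length(maps) == 0L || sum(sal) == 0) next
      for (kind in c("low", "high")) {
        sal_effects[[kind]][[sid]] <- bootstrap_iou(
          unname(maps), list(sal), kind = kind,
          n_boot = cfg$compare$n_boot,
          seed = str_seed(paste("saliency", kind, sid), base = cfg$seed),
          q_low = cfg$compare$q_low, q_high = cfg$compare$q_high,
          common_a = pre$clinician$common, common_b = NULL,
          smooth_px = cfg$heatmap$smooth_px, stimulus_id = sid)
      }
    }
    saliency_res <- lapply(sal_effects, function(effs) {
      list(effects = unname(effs),
           mean_iou = mean(vapply(effs, function(e) e$effect, numeric(1))),
           meta = if (length(effs) >= 2) {
             suppressWarnings(re_meta_analysis(unname(effs)))
           } else {
             NULL
           })
    })
  }

  list(stimuli = stimuli, responses = responses, contingency = contingency,
       accuracy = acc, chi_square = chi, preprocessed = pre,
       comparisons = comparisons, saliency = saliency_res, config = cfg)
}

# Flatten one comparison's effects + RE row into a forest-plot style table.
forest_table <- function(comp) {
  eff <- comp$effects
  n <- length(eff)
  df <- data.frame(
    stimulus_id = vapply(eff, function(e) e$stimulus_id, ""),
    effect = vapply(eff, function(e) e$effect, numeric(1)),
    se = vapply(eff, function(e) e$se, numeric(1)),
    pooled = rep(NA_real_, n), ci_low = rep(NA_real_, n),
    ci_high = rep(NA_real_, n), tau2 = rep(NA_real_, n),
    q_stat = rep(NA_real_, n), stringsAsFactors = FALSE
  )
  if (!is.null(comp$meta)) {
    m <- comp$meta
    df <- rbind(df, data.frame(stimulus_id = "RE_model", effect = m$pooled,
                               se = NA_real_, pooled = m$pooled,
                               ci_low = m$ci_low, ci_high = m$ci_high,
                               tau2 = m$tau2, q_stat = m$q_stat,
                               stringsAsFactors = FALSE))
  }
  df
}

#' Write a report bundle to disk
#'
#' Writes one forest-style TSV per comparison and threshold (per-stimulus
#' effect and bootstrap SE, with a final RE-model row), plus
#' `responses.tsv`, per-stimulus AOI JSONs, and `report.json` with the
#' contingency table, accuracy, chi-square, pooled effects, and the seed.
#'
#' @param bundle result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bundle$responses, file.path(out_dir, "responses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(out_dir, "aois"), showWarnings = FALSE)
  for (st in bundle$stimuli) {
    write_aoi_set(st$aoi_set,
                  file.path(out_dir, "aois", paste0(st$stimulus_id, ".json")))
  }
  meta_json <- list()
  for (nm in names(bundle$comparisons)) {
    for (kind in names(bundle$comparisons[[nm]])) {
      comp <- bundle$comparisons[[nm]][[kind]]
      utils::write.table(
        forest_table(comp),
        file.path(out_dir, sprintf("forest_%s_%s.tsv", nm, kind)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(comp$meta)) {
        meta_json[[nm]][[kind]] <- comp$meta[c("pooled", "ci_low", "ci_high",
                                               "tau2", "q_stat", "k")]
      }
    }
  }
  sal_json <- NULL
  if (!is.null(bundle$saliency)) {
    sal_json <- lapply(bundle$saliency, function(s) {
      c(list(mean_iou = s$mean_iou),
        if (!is.null(s$meta)) s$meta[c("pooled", "ci_low", "ci_high")])
    })
    for (kind in names(bundle$saliency)) {
      utils::write.table(
        forest_table(bundle$saliency[[kind]]),
        file.path(out_dir, sprintf("forest_saliency_vs_clin_%s.tsv", kind)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report <- list(
    seed = bundle$config$seed,
    contingency = unclass(bundle$contingency),
    accuracy_pct = as.list(bundle$accuracy),
    chi_square = bundle$chi_square,
    comparisons = meta_json,
    saliency_vs_successful_clinicians = sal_json
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
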
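# Group-level preprocessing: per-stimulus group averages, common-attention
# estimation over all stimuli, and common-pattern subtraction.
#
# Standard heat maps mostly show that everyone looks at the eyes, nose, and
# mouth. That shared face-viewing behaviour swamps group differences, so the
# average gaze pattern of a group over all stimuli (its "common attention")
# is subtracted from each per-stimulus group average before comparisons.

#' Per-stimulus group average heat map
#'
#' @param group `"clinician"` or `"non_clinician"`.
#' @param stimulus_id stimulus identifier.
#' @param map normalized [attention_map()] (kind `"gaze"`).
#' @param n_participants number of participants contributing (>= 1).
#' @return a `group_average` object.
#' @export
group_average <- function(group, stimulus_id, map, n_participants) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot(is_attention_map(map), n_participants >= 1)
  if (abs(sum(map) - 1) > 1e-6) {
    stop("group average map must be normalized to unit mass", call. = FALSE)
  }
  structure(list(group = group, stimulus_id = as.character(stimulus_id),
                 map = map, n_participants = as.integer(n_participants)),
            class = "group_average")
}

#' Common attention pattern of a participant group
#'
#' Averages one group's per-stimulus average heat maps over all stimuli and
#' normalizes, yielding the group's generic face-viewing pattern
#' (eyes/nose/mouth). Computed separately per group.
#'
#' @param group_averages list of [group_average()]s, all from the same group
#'   with identical map dimensions.
#' @return a `common_attention` object with fields `group`, `map`
#'   (normalized [attention_map()]), and `n_stimuli`.
#' @export
common_attention <- function(group_averages) {
  if (length(group_averages) == 0L) stop("need at least one stimulus", call. = FALSE)
  stopifnot(all(vapply(group_averages, inherits, logical(1), "group_average")))
  groups <- unique(vapply(group_averages, function(g) g$group, ""))
  if (length(groups) != 1L) {
    stop("common attention must be computed within one group; got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  avg <- average_maps(lapply(group_averages, function(g) g$map), normalize = TRUE)
  structure(list(group = groups, map = normalize_map(avg),
                 n_stimuli = length(group_averages)),
            class = "common_attention")
}

#' Subtract a group's common attention from a per-stimulus average
#'
#' Cell-wise difference with negative values clipped to 0: residual
#' attention measures where this stimulus drew *more* gaze than the group's
#' typical face-viewing pattern. The result is deliberately not renormalized
#' — absolute residual attention is meaningful. Groups must match: clinician
#' maps are corrected with the clinician common pattern.
#'
#' @param ga a [group_average()].
#' @param common a [common_attention()] for the same group.
#' @return an [attention_map()] of kind `"difference"`.
#' @export
subtract_common <- function(ga, common) {
  stopifnot(inherits(ga, "group_average"), inherits(common, "common_attention"))
  if (ga$group != common$group) {
    stop("group mismatch: average is '", ga$group, "' but common pattern is '",
         common$group, "'", call. = FALSE)
  }
  check_same_dim(ga$map, common$map, what = "average and common maps")
  as_map(pmax(unclass(ga$map) - unclass(common$map), 0), kind = "difference")
}

#' Preprocessing configuration
#'
#' @param radius_px fixation kernel support (default 25 px).
#' @param kernel fixation kernel shape (see [fixations_to_map()]).
#' @param smooth_px box-smoothing side applied to residual maps (odd;
#'   default 11).
#' @param per_participant subtract the common pattern from each participant's
#'   map before averaging instead of from the group average (default
#'   `FALSE`).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(radius_px = 25, kernel = "linear",
                              smooth_px = 11, per_participant = FALSE) {
  structure(list(radius_px = radius_px, kernel = kernel,
                 smooth_px = smooth_px, per_participant = per_participant),
            class = "preprocess_config")
}

#' Full preprocessing pipeline for one participant group
#'
#' For each stimulus: rasterize every participant's fixations, normalize to
#' unit mass, average across participants; then compute the group's common
#' attention over all stimuli, subtract it from each per-stimulus average,
#' and box-smooth the residuals. Deterministic given inputs and config.
#' Stimuli with no contributing participant are omitted with a warning.
#'
#' @param sequences list of [fixation_sequence()]s (other groups' sequences
#'   are ignored).
#' @param group group to process.
#' @param width_px,height_px stimulus dimensions (all stimuli share them;
#'   inputs are assumed pre-aligned).
#' @param config a [preprocess_config()].
#' @return list with components `residuals` (named list of smoothed
#'   difference [attention_map()]s per stimulus), `group_averages` (named
#'   list of [group_average()]s), `participant_maps` (named list per stimulus
#'   of per-participant normalized maps), and `common`
#'   (the [common_attention()]).
#' @export
preprocess_group <- function(sequences, group, width_px, height_px,
                             config = preprocess_config()) {
  group <- match.arg(group, GROUP_LEVELS)
  seqs <- Filter(function(s) s$group == group, sequences)
  if (length(seqs) == 0L) stop("no sequences for group '", group, "'", call. = FALSE)
  stim_ids <- sort(unique(vapply(seqs, function(s) s$stimulus_id, "")))
  participant_maps <- list()
  group_avgs <- list()
  for (sid in stim_ids) {
    ss <- Filter(function(s) s$stimulus_id == sid, seqs)
    maps <- list()
    for (s in ss) {
      m <- fixations_to_map(s, width_px, height_px,
                            radius_px = config$radius_px, kernel = config$kernel)
      if (sum(m) > 0) {
        maps[[s$participant_id]] <- normalize_map(m)
      }
    }
    if (length(maps) == 0L) {
      warning("stimulus '", sid, "' has no contributing participants; omitted",
              call. = FALSE)
      next
    }
    participant_maps[[sid]] <- maps
    group_avgs[[sid]] <- group_average(group, sid,
                                       average_maps(maps, normalize = FALSE),
                                       n_participants = length(maps))
  }
  if (length(group_avgs) == 0L) {
    stop("no stimulus had gaze data for group '", group, "'", call. = FALSE)
  }
  common <- common_attention(unname(group_avgs))
  residuals <- lapply(group_avgs, function(ga) {
    if (config$per_participant) {
      diffs <- lapply(participant_maps[[ga$stimulus_id]], function(pm) {
        pmax(unclass(pm) - unclass(common$map), 0)
      })
      resid <- as_map(Reduce(`+`, diffs) / length(diffs), kind = "difference")
    } else {
      resid <- subtract_common(ga, common)
    }
    box_smooth(resid, config$smooth_px)
  })
  list(residuals = residuals, group_averages = group_avgs,
       participant_maps = participant_maps, common = common)
}
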
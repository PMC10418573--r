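# Synthetic study generator: stimuli with planted attention structure, two
# participant groups' fixation streams, response records with target
# accuracies, and an analytic toy classifier. Every pipeline stage can be
# exercised end-to-end without access to restricted facial image data.
#
# The gaze model is a Gaussian mixture: three "common" components at fixed
# eyes/nose/mouth coordinates shared by all stimuli (generic face-viewing
# behaviour), plus one stimulus-specific component per stimulus (the planted
# "dysmorphic feature") whose mixing weight differs by participant group.
# This is the simplest generator reproducing the qualitative structure of
# face-viewing gaze data; it is not a model of gaze physiology.

# Common face-attention layout as fractions of the image side: left eye,
# right eye, nose, mouth.
COMMON_LAYOUT <- data.frame(
  name = c("eye_left", "eye_right", "nose", "mouth"),
  fx = c(0.32, 0.68, 0.50, 0.50),
  fy = c(0.38, 0.38, 0.56, 0.72),
  weight = c(0.30, 0.30, 0.20, 0.20)
)

#' Attention profile
#'
#' A Gaussian-mixture description of where attention concentrates:
#' components with pixel-coordinate centres, isotropic spreads, and mixing
#' weights summing to 1.
#'
#' @param components data frame with columns `x`, `y` (0-based pixel
#'   centres), `sd_px`, `weight`.
#' @param label `"common"`, `"group_specific"`, or `"stimulus_specific"`.
#' @return an `attention_profile`.
#' @export
attention_profile <- function(components,
                              label = c("common", "group_specific",
                                        "stimulus_specific")) {
  label <- match.arg(label)
  components <- as.data.frame(components)
  stopifnot(all(c("x", "y", "sd_px", "weight") %in% names(components)),
            all(components$weight > 0))
  components$weight <- components$weight / sum(components$weight)
  structure(list(components = components, label = label),
            class = "attention_profile")
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study design the package emulates: 22 clinicians and
#' 22 non-clinicians viewing 16 aligned facial stimuli (10 affected, 6
#' unaffected) for 7 seconds each, with target affected/unaffected judgment
#' accuracies of 85.6% (clinicians) and 76.9% (non-clinicians).
#'
#' @param n_clinicians,n_non_clinicians participants per group.
#' @param n_stimuli number of stimuli; `n_affected` of them are affected.
#' @param n_affected number of affected stimuli.
#' @param image_px square stimulus side in pixels (default 448, the
#'   classifier input convention).
#' @param viewing_ms viewing window per stimulus (default 7000 ms).
#' @param fixations_per_trial mean fixation count per trial (Poisson).
#' @param group_accuracy named vector of target correct-judgment
#'   probabilities per group.
#' @param specific_weight named vector: mixing weight of the
#'   stimulus-specific attention component per group (clinicians attend the
#'   planted feature more).
#' @param separate_group_components if `TRUE`, each group gets its own
#'   disjoint stimulus-specific component (groups look at *different*
#'   feature locations); if `FALSE` (default) both groups share one.
#' @param duration_shape,duration_mean_ms Gamma fixation-duration model
#'   (shape 2, mean 300 ms — the typical fixation duration scale).
#' @param named_condition_frac fraction of correct clinician responses on
#'   affected stimuli that also name the condition.
#' @param seed integer master seed; all generators are pure functions of
#'   (config, seed).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_clinicians = 22, n_non_clinicians = 22,
                          n_stimuli = 16, n_affected = 10,
                          image_px = 448, viewing_ms = 7000,
                          fixations_per_trial = 20,
                          group_accuracy = c(clinician = 0.856,
                                             non_clinician = 0.769),
                          specific_weight = c(clinician = 0.30,
                                              non_clinician = 0.15),
                          separate_group_components = FALSE,
                          duration_shape = 2, duration_mean_ms = 300,
                          named_condition_frac = 0.5,
                          seed = 0) {
  if (n_affected > n_stimuli) {
    stop("n_affected cannot exceed n_stimuli", call. = FALSE)
  }
  stopifnot(n_clinicians >= 1, n_non_clinicians >= 1, n_stimuli >= 1,
            image_px >= 32, viewing_ms > 0,
            all(group_accuracy >= 0 & group_accuracy <= 1),
            all(specific_weight >= 0 & specific_weight < 1),
            all(GROUP_LEVELS %in% names(group_accuracy)),
            all(GROUP_LEVELS %in% names(specific_weight)))
  structure(list(
    n_clinicians = n_clinicians, n_non_clinicians = n_non_clinicians,
    n_stimuli = n_stimuli, n_affected = n_affected, image_px = image_px,
    viewing_ms = viewing_ms, fixations_per_trial = fixations_per_trial,
    group_accuracy = group_accuracy, specific_weight = specific_weight,
    separate_group_components = separate_group_components,
    duration_shape = duration_shape, duration_mean_ms = duration_mean_ms,
    named_condition_frac = named_condition_frac, seed = as.integer(seed)
  ), class = "cohort_config")
}

common_profile <- function(image_px) {
  attention_profile(
    data.frame(x = COMMON_LAYOUT$fx * (image_px - 1),
               y = COMMON_LAYOUT$fy * (image_px - 1),
               sd_px = 0.04 * image_px,
               weight = COMMON_LAYOUT$weight),
    label = "common"
  )
}

# Sample a component centre uniformly in the central face box, rejecting
# locations closer than min_dist to any point in `avoid` (rows x, y).
sample_center <- function(image_px, avoid, min_dist) {
  for (i in 1:1000) {
    x <- stats::runif(1, 0.20, 0.80) * (image_px - 1)
    y <- stats::runif(1, 0.20, 0.85) * (image_px - 1)
    if (nrow(avoid) == 0 ||
        all(sqrt((avoid[, 1] - x)^2 + (avoid[, 2] - y)^2) >= min_dist)) {
      return(c(x, y))
    }
  }
  stop("could not place a component away from existing ones", call. = FALSE)
}

# Regular octagon around a centre; used for the AOI over the planted feature.
octagon <- function(cx, cy, r, image_px) {
  ang <- (0:7) * pi / 4 + pi / 8
  cbind(pmin(image_px - 1, pmax(0, cx + r * cos(ang))),
        pmin(image_px - 1, pmax(0, cy + r * sin(ang))))
}

#' Generate synthetic stimuli
#'
#' Each stimulus gets the shared common attention profile (eyes/nose/mouth),
#' one planted stimulus-specific component per group (shared between groups
#' unless `separate_group_components`), an AOI polygon around the planted
#' feature, an affected/unaffected truth label, and a smooth template image
#' with brightened component regions (no faces are generated). Deterministic
#' given the config seed.
#'
#' @param cfg a [cohort_config()].
#' @return list of stimulus objects, each with `stimulus_id`, `truth`,
#'   `image` (matrix in `[0, 1]`), `common` / `specific` attention profiles,
#'   `aoi_set`, and `target_region` (`c(x0, y0, x1, y1)`, 0-based inclusive
#'   box around the planted feature, used by [toy_classifier()]).
#' @export
gen_stimuli <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  px <- cfg$image_px
  common <- common_profile(px)
  sd_spec <- 0.03 * px
  with_seed(str_seed("stimuli", base = cfg$seed), {
    affected_idx <- sample.int(cfg$n_stimuli, cfg$n_affected)
    lapply(seq_len(cfg$n_stimuli), function(i) {
      avoid <- as.matrix(common$components[, c("x", "y")])
      ctr <- sample_center(px, avoid, min_dist = 0.14 * px)
      centers <- list(clinician = ctr, non_clinician = ctr)
      if (cfg$separate_group_components) {
        centers$non_clinician <- sample_center(px, rbind(avoid, ctr),
                                               min_dist = 0.14 * px)
      }
      specific <- lapply(centers, function(c2) {
        attention_profile(
          data.frame(x = c2[1], y = c2[2], sd_px = sd_spec, weight = 1),
          label = "stimulus_specific"
        )
      })
      sid <- sprintf("stim%02d", i)
      aoi <- aoi_set(sid,
                     list(planted_feature = octagon(ctr[1], ctr[2],
                                                    3 * sd_spec, px)),
                     width_px = px, height_px = px)
      half <- 3 * sd_spec
      region <- c(max(0, floor(ctr[1] - half)), max(0, floor(ctr[2] - half)),
                  min(px - 1, ceiling(ctr[1] + half)),
                  min(px - 1, ceiling(ctr[2] + half)))
      # template image: low-frequency noise plus brightened component bumps
      img <- matrix(stats::rnorm(px * px, 0, 1), px, px)
      img <- box_mean(img, 2 * floor(px / 16) + 1)
      img <- 0.35 + 0.5 * (img - min(img)) / max(1e-12, diff(range(img))) * 0.3
      bumps <- rbind(
        cbind(common$components$x, common$components$y,
              common$components$sd_px),
        c(ctr[1], ctr[2], sd_spec)
      )
      xg <- 0:(px - 1)
      for (b in seq_len(nrow(bumps))) {
        gx <- exp(-(xg - bumps[b, 1])^2 / (2 * bumps[b, 3]^2))
        gy <- exp(-(xg - bumps[b, 2])^2 / (2 * bumps[b, 3]^2))
        img <- img + 0.4 * outer(gy, gx)
      }
      img <- pmin(pmax(img, 0), 1)  # first arg keeps the dim attribute
      list(stimulus_id = sid,
           truth = if (i %in% affected_idx) "affected" else "unaffected",
           image = img, common = common, specific = specific,
           aoi_set = aoi, target_region = region)
    })
  })
}

#' Generate one participant's fixation sequences
#'
#' Per trial, the fixation count is Poisson, locations are drawn from the
#' stimulus's Gaussian mixture (common components plus the group-weighted
#' stimulus-specific component), durations are Gamma with mean
#' `duration_mean_ms`, and onsets are sequential with short saccade gaps.
#' Durations are rescaled when necessary so each trial fits in the viewing
#' window. Reproducible: the RNG stream is derived from the config seed and
#' the participant id.
#'
#' @param cfg a [cohort_config()].
#' @param stimuli output of [gen_stimuli()].
#' @param participant_id participant identifier.
#' @param group `"clinician"` or `"non_clinician"`.
#' @return list of [fixation_sequence()]s, one per stimulus.
#' @export
gen_fixations <- function(cfg, stimuli, participant_id, group) {
  group <- match.arg(group, GROUP_LEVELS)
  px <- cfg$image_px
  w_spec <- cfg$specific_weight[[group]]
  with_seed(str_seed(participant_id, base = cfg$seed), {
    lapply(stimuli, function(st) {
      comp <- st$common$components
      spec <- st$specific[[group]]$components
      centers <- rbind(as.matrix(comp[, c("x", "y")]),
                       as.matrix(spec[, c("x", "y")]))
      sds <- c(comp$sd_px, spec$sd_px)
      wts <- c(comp$weight * (1 - w_spec), spec$weight * w_spec)
      n <- stats::rpois(1, cfg$fixations_per_trial)
      if (n == 0) {
        return(fixation_sequence(participant_id, group, st$stimulus_id,
                                 data.frame(x_px = numeric(), y_px = numeric(),
                                            onset_ms = numeric(),
                                            duration_ms = numeric()),
                                 viewing_ms = cfg$viewing_ms))
      }
      ci <- sample.int(length(wts), n, replace = TRUE, prob = wts)
      x <- pmin(px - 1, pmax(0, stats::rnorm(n, centers[ci, 1], sds[ci])))
      y <- pmin(px - 1, pmax(0, stats::rnorm(n, centers[ci, 2], sds[ci])))
      dur <- stats::rgamma(n, shape = cfg$duration_shape,
                           scale = cfg$duration_mean_ms / cfg$duration_shape)
      dur <- pmax(dur, 10)
      gaps <- stats::runif(n, 20, 60)
      if (sum(gaps) >= cfg$viewing_ms * 0.5) {
        gaps <- gaps * (cfg$viewing_ms * 0.5) / sum(gaps)
      }
      # 0.995 leaves slack for the 0.1 ms rounding below
      budget <- 0.995 * (cfg$viewing_ms - sum(gaps))
      if (sum(dur) > budget) dur <- dur * budget / sum(dur)
      onset <- cumsum(gaps) + c(0, cumsum(dur)[-n])
      fixation_sequence(
        participant_id, group, st$stimulus_id,
        data.frame(x_px = round(x, 1), y_px = round(y, 1),
                   onset_ms = round(onset, 1), duration_ms = round(dur, 1)),
        viewing_ms = cfg$viewing_ms
      )
    })
  })
}

#' Generate the full cohort's fixation sequences
#'
#' @param cfg a [cohort_config()].
#' @param stimuli output of [gen_stimuli()].
#' @return list with `sequences` (flat list of [fixation_sequence()]s) and
#'   `participants` (data frame of `participant_id`, `group`).
#' @export
gen_cohort <- function(cfg, stimuli) {
  participants <- data.frame(
    participant_id = c(sprintf("clin%02d", seq_len(cfg$n_clinicians)),
                       sprintf("nonclin%02d", seq_len(cfg$n_non_clinicians))),
    group = rep(GROUP_LEVELS, c(cfg$n_clinicians, cfg$n_non_clinicians)),
    stringsAsFactors = FALSE
  )
  sequences <- list()
  for (i in seq_len(nrow(participants))) {
    sequences <- c(sequences,
                   gen_fixations(cfg, stimuli, participants$participant_id[i],
                                 participants$group[i]))
  }
  list(sequences = sequences, participants = participants)
}

#' Generate response records at target accuracies
#'
#' Each participant judges each stimulus; the judgment is correct with the
#' group's target probability (independent Bernoulli draws). A configurable
#' fraction of correct clinician responses on affected stimuli also name the
#' condition. Deterministic given the config seed.
#'
#' @param cfg a [cohort_config()].
#' @param stimuli output of [gen_stimuli()].
#' @return data frame of response records (see [read_response_table()]).
#' @export
gen_responses <- function(cfg, stimuli) {
  participants <- data.frame(
    participant_id = c(sprintf("clin%02d", seq_len(cfg$n_clinicians)),
                       sprintf("nonclin%02d", seq_len(cfg$n_non_clinicians))),
    group = rep(GROUP_LEVELS, c(cfg$n_clinicians, cfg$n_non_clinicians)),
    stringsAsFactors = FALSE
  )
  truths <- vapply(stimuli, function(s) s$truth, "")
  sids <- vapply(stimuli, function(s) s$stimulus_id, "")
  with_seed(str_seed("responses", base = cfg$seed), {
    rows <- lapply(seq_len(nrow(participants)), function(i) {
      g <- participants$group[i]
      correct <- stats::rbinom(length(sids), 1, cfg$group_accuracy[[g]]) == 1
      judgment <- ifelse(correct, truths,
                         ifelse(truths == "affected", "unaffected", "affected"))
      named <- ifelse(
        correct & g == "clinician" & truths == "affected" &
          stats::runif(length(sids)) < cfg$named_condition_frac,
        paste0("condition_", sids), NA_character_)
      data.frame(participant_id = participants$participant_id[i], group = g,
                 stimulus_id = sids, truth = truths, judgment = judgment,
                 named_condition = named, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Analytic toy classifier
#'
#' A classifier whose probability for the target label is a logistic
#' function of the summed pixel intensity inside a rectangular target
#' region. Its occlusion saliency is therefore analytically concentrated on
#' that region, giving tests a classifier with known ground truth. Satisfies
#' the [classifier_adapter()] contract.
#'
#' @param target_region `c(x0, y0, x1, y1)`, 0-based inclusive pixel box.
#' @param input_size square image side (default 448).
#' @param labels class labels; probability mass outside the target label is
#'   split evenly.
#' @param label_index index of the target label within `labels`.
#' @param gain logistic slope per unit summed intensity; the default
#'   `4 / area` puts a half-bright region at logit 2.
#' @return a [classifier_adapter()].
#' @export
toy_classifier <- function(target_region, input_size = 448,
                           labels = c("unaffected", "affected"),
                           label_index = 2, gain = NULL) {
  stopifnot(length(target_region) == 4)
  x0 <- target_region[1]; y0 <- target_region[2]
  x1 <- target_region[3]; y1 <- target_region[4]
  if (x0 < 0 || y0 < 0 || x1 >= input_size || y1 >= input_size ||
      x0 > x1 || y0 > y1) {
    stop("target_region outside image bounds", call. = FALSE)
  }
  area <- (x1 - x0 + 1) * (y1 - y0 + 1)
  if (is.null(gain)) gain <- 4 / area
  rows <- (y0:y1) + 1
  cols <- (x0:x1) + 1
  k <- length(labels)
  predict <- function(image) {
    img <- if (length(dim(image)) == 3) image[, , 1] else image
    p <- stats::plogis(gain * sum(img[rows, cols]))
    probs <- rep((1 - p) / (k - 1), k)
    probs[label_index] <- p
    probs
  }
  classifier_adapter(predict, labels, input_size = input_size)
}
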
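test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(seed = 14)
  s1 <- gen_stimuli(cfg); s2 <- gen_stimuli(cfg)
  expect_identical(s1, s2)
  f1 <- gen_fixations(cfg, s1, "clin03", "clinician")
  f2 <- gen_fixations(cfg, s1, "clin03", "clinician")
  expect_identical(f1, f2)
  r1 <- gen_responses(cfg, s1); r2 <- gen_responses(cfg, s1)
  expect_identical(r1, r2)
  # different seeds genuinely differ
  expect_false(identical(s1, gen_stimuli(small_cfg(seed = 15))))
  # different participants get independent streams
  expect_false(identical(f1, gen_fixations(cfg, s1, "clin04", "clinician")))
})

test_that("stimuli carry the planted structure they promise", {
  cfg <- small_cfg(seed = 8, n_stimuli = 8, n_affected = 5)
  st <- gen_stimuli(cfg)
  expect_length(st, 8)
  expect_equal(sum(vapply(st, function(s) s$truth == "affected", logical(1))), 5)
  for (s in st) {
    ctr <- s$specific$clinician$components
    # the AOI polygon contains its component centre
    expect_true(point_in_polygon(ctr$x, ctr$y,
                                 s$aoi_set$aois$planted_feature))
    # the toy-classifier target region contains it too
    expect_true(ctr$x >= s$target_region[1] && ctr$x <= s$target_region[3])
    expect_true(ctr$y >= s$target_region[2] && ctr$y <= s$target_region[4])
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
  expect_error(small_cfg(n_stimuli = 4, n_affected = 9), "exceed")
  # disjoint group components stay apart
  cfgd <- small_cfg(seed = 8, separate_group_components = TRUE)
  for (s in gen_stimuli(cfgd)) {
    a <- s$specific$clinician$components
    b <- s$specific$non_clinician$components
    expect_gt(sqrt((a$x - b$x)^2 + (a$y - b$y)^2), 0.1 * cfgd$image_px)
  }
})

test_that("fixation streams respect the viewing window and the gaze mixture", {
  cfg <- small_cfg(seed = 10)
  st <- gen_stimuli(cfg)
  for (pid in c("clin01", "nonclin02")) {
    grp <- if (pid == "clin01") "clinician" else "non_clinician"
    for (s in gen_fixations(cfg, st, pid, grp)) {
      fx <- s$fixations
      if (nrow(fx) == 0) next
      expect_true(all(fx$onset_ms >= 0))
      expect_true(all(fx$duration_ms > 0))
      expect_lte(max(fx$onset_ms + fx$duration_ms), cfg$viewing_ms)
      expect_true(!is.unsorted(fx$onset_ms))
      expect_true(all(fx$x_px >= 0 & fx$x_px <= cfg$image_px - 1))
    }
  }
  # with zero stimulus-specific weight, the empirical fixation density has
  # its mass near the three common face regions (eyes merge into one band)
  cfg0 <- cohort_config(n_clinicians = 1, n_non_clinicians = 1, n_stimuli = 1,
                        n_affected = 1, image_px = 200,
                        fixations_per_trial = 10000, viewing_ms = 1e7,
                        duration_mean_ms = 100,
                        specific_weight = c(clinician = 0, non_clinician = 0),
                        seed = 12)
  st0 <- gen_stimuli(cfg0)
  fx <- gen_fixations(cfg0, st0, "clin01", "clinician")[[1]]$fixations
  comp <- st0[[1]]$common$components
  near <- function(cx, cy) {
    mean(sqrt((fx$x_px - cx)^2 + (fx$y_px - cy)^2) < 3 * comp$sd_px[1])
  }
  fractions <- mapply(near, comp$x, comp$y)
  # each planted common component captures roughly its mixture weight
  expect_true(all(abs(fractions - comp$weight) < 0.1))
  expect_gt(sum(fractions), 0.85)
})

test_that("responses hit their target accuracies on average", {
  cfg <- small_cfg(seed = 16, group_accuracy = c(clinician = 1,
                                                 non_clinician = 0.5))
  st <- gen_stimuli(cfg)
  resp <- gen_responses(cfg, st)
  expect_true(all(resp$judgment[resp$group == "clinician"] ==
                    resp$truth[resp$group == "clinician"]))
  # named conditions only for correct clinician calls on affected stimuli
  named <- resp[!is.na(resp$named_condition), ]
  expect_true(all(named$group == "clinician"))
  expect_true(all(named$truth == "affected"))
  expect_true(all(named$judgment == "affected"))
})

test_that("the toy classifier honors the adapter contract", {
  region <- c(10, 12, 29, 31)
  clf <- toy_classifier(region, input_size = 64)
  # zero intensity inside the region: logistic at 0 -> 0.5
  img0 <- matrix(0, 64, 64)
  expect_equal(clf$predict(img0)[2], 0.5)
  # probabilities sum to 1 for arbitrary inputs and label counts
  set.seed(49)
  clf4 <- toy_classifier(region, input_size = 64,
                         labels = paste0("d", 1:4), label_index = 3)
  for (rep in 1:5) {
    p <- clf4$predict(matrix(stats::runif(64 * 64), 64, 64))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # brighter region raises the target probability
  img1 <- img0; img1[13:32, 11:30] <- 1
  expect_gt(clf$predict(img1)[2], clf$predict(img0)[2])
  expect_error(toy_classifier(c(-1, 0, 10, 10), input_size = 64), "bounds")
})

test_that("toy-classifier occlusion saliency lands in the planted region", {
  for (seed in 0:3) {
    cfg <- cohort_config(n_stimuli = 1, n_affected = 1, image_px = 128,
                         seed = seed)
    st <- gen_stimuli(cfg)[[1]]
    clf <- toy_classifier(st$target_region, input_size = 128)
    sal <- occlusion_map(clf, st$image, label_index = 2,
                         box_px = 20, stride_px = 10, fill = "zero")
    peak <- map_argmax(sal)
    expect_true(peak[["x"]] >= st$target_region[1] &&
                  peak[["x"]] <= st$target_region[3])
    expect_true(peak[["y"]] >= st$target_region[2] &&
                  peak[["y"]] <= st$target_region[4])
  }
})

test_that("identical groups look identical; disjoint groups do not", {
  # identical mixture profiles for both groups: the per-stimulus group
  # average maps must binarize to near-identical low-threshold masks
  cfg <- cohort_config(image_px = 224, seed = 0,
                       specific_weight = c(clinician = 0.3,
                                           non_clinician = 0.3))
  st <- gen_stimuli(cfg)
  co <- gen_cohort(cfg, st)
  pre <- lapply(stats::setNames(c("clinician", "non_clinician"),
                                c("clinician", "non_clinician")),
                function(g) preprocess_group(co$sequences, g, 224, 224))
  pooled_for <- function(common, kind) {
    effs <- lapply(st, function(s) {
      sid <- s$stimulus_id
      bootstrap_iou(unname(pre$clinician$participant_maps[[sid]]),
                    unname(pre$non_clinician$participant_maps[[sid]]),
                    kind = kind, n_boot = 50,
                    seed = gazecompare:::str_seed(paste("inv", kind, sid), 0),
                    common_a = if (common) pre$clinician$common else NULL,
                    common_b = if (common) pre$non_clinician$common else NULL,
                    smooth_px = 11, stimulus_id = sid)
    })
    suppressWarnings(re_meta_analysis(effs))$pooled
  }
  shared_low <- pooled_for(common = FALSE, "low")
  expect_gte(shared_low, 0.9)
  # disjoint group-specific components: residual attention of the two
  # groups concentrates on different features, so the pooled high-threshold
  # IoU collapses far below the shared-profile value
  cfgd <- cohort_config(image_px = 224, seed = 0,
                        separate_group_components = TRUE)
  std <- gen_stimuli(cfgd)
  cod <- gen_cohort(cfgd, std)
  prd <- lapply(stats::setNames(c("clinician", "non_clinician"),
                                c("clinician", "non_clinician")),
                function(g) preprocess_group(cod$sequences, g, 224, 224))
  effd <- lapply(std, function(s) {
    sid <- s$stimulus_id
    bootstrap_iou(unname(prd$clinician$participant_maps[[sid]]),
                  unname(prd$non_clinician$participant_maps[[sid]]),
                  kind = "high", n_boot = 50,
                  seed = gazecompare:::str_seed(paste("invd", sid), 0),
                  common_a = prd$clinician$common,
                  common_b = prd$non_clinician$common,
                  smooth_px = 11, stimulus_id = sid)
  })
  disjoint_high <- suppressWarnings(re_meta_analysis(effd))$pooled
  expect_lt(disjoint_high, shared_low)
})
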
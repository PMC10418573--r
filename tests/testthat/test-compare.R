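test_that("binarization thresholds at quantiles of nonzero values", {
  # nonzero values 1..100: the high mask keeps exactly 76..100
  v <- matrix(c(0:100, rep(0, 20)), 11, 11)
  m <- attention_map(v)
  hi <- binarize(m, "high")
  expect_setequal(v[hi == 1], 76:100)
  lo <- binarize(m, "low")
  expect_setequal(v[lo == 1], 26:100)
  # low mask contains high mask; raising q never grows the mask
  expect_true(all(lo[hi == 1] == 1))
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sizes <- vapply(qs, function(q) sum(binarize(m, "low", q_low = q)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # all-zero map -> empty masks of both kinds
  z <- attention_map(matrix(0, 3, 3))
  expect_equal(sum(binarize(z, "low")), 0)
  expect_equal(sum(binarize(z, "high")), 0)
  expect_error(binarize(m, "low", q_low = 0), "quantile")
})

test_that("IoU matches brute-force counting and its algebraic identities", {
  set.seed(13)
  for (rep in 1:10) {
    a <- random_mask(20, 20, p = stats::runif(1, 0.2, 0.8))
    b <- random_mask(20, 20, p = stats::runif(1, 0.2, 0.8))
    v <- iou(a, b)
    expect_equal(v, iou_bruteforce(a, b))
    expect_equal(v, iou(b, a))          # symmetry
    expect_gte(v, 0); expect_lte(v, 1)
    if (sum(a) > 0) expect_equal(iou(a, a), 1)
  }
  # identical / disjoint special cases
  a <- random_mask(5, 5, p = 1)
  expect_equal(iou(a, a), 1)
  d1 <- random_mask(4, 4, p = 0); d1[1, 1] <- 1L
  d2 <- random_mask(4, 4, p = 0); d2[4, 4] <- 1L
  expect_equal(iou(d1, d2), 0)
  # rows 0-1 vs rows 1-2 of a full-width 3-row mask -> 1/3
  r1 <- random_mask(3, 4, p = 0); r1[1:2, ] <- 1L
  r2 <- random_mask(3, 4, p = 0); r2[2:3, ] <- 1L
  expect_equal(iou(r1, r2), 1 / 3)
  # both empty -> 0 with warning
  e <- random_mask(3, 3, p = 0)
  expect_warning(z <- iou(e, e), "empty")
  expect_equal(z, 0)
  # guards
  expect_error(iou(a, random_mask(6, 6)), "mismatch")
  expect_error(iou(a, random_mask(5, 5, kind = "high")), "threshold kind")
})

test_that("bootstrap IoU is seeded, degenerate-safe, and stable across seeds", {
  m <- normalize_map(random_map(16, 16))
  # both groups one identical participant: effect 1, se 0
  e <- bootstrap_iou(list(m), list(m), "low", n_boot = 50, seed = 1)
  expect_equal(e$effect, 1)
  expect_equal(e$se, 0)
  # same list on both sides -> effect 1
  set.seed(21)
  grp <- lapply(1:5, function(i) normalize_map(random_map(16, 16)))
  e2 <- bootstrap_iou(grp, grp, "high", n_boot = 50, seed = 1)
  expect_equal(e2$effect, 1)
  # reproducible given seed
  ga <- lapply(1:8, function(i) normalize_map(random_map(16, 16)))
  gb <- lapply(1:8, function(i) normalize_map(random_map(16, 16)))
  r1 <- bootstrap_iou(ga, gb, "low", n_boot = 100, seed = 5)
  r2 <- bootstrap_iou(ga, gb, "low", n_boot = 100, seed = 5)
  expect_identical(r1, r2)
  # bootstrap SE stable across seeds (within 20% relative)
  cfg <- small_cfg(seed = 4)
  st <- gen_stimuli(cfg)[1]
  co <- gen_cohort(small_cfg(seed = 4, n_clinicians = 10,
                             n_non_clinicians = 10, n_stimuli = 1,
                             n_affected = 1), st)
  pm <- lapply(Filter(function(s) s$group == "clinician", co$sequences),
               function(s) normalize_map(fixations_to_map(s, 96, 96)))
  pn <- lapply(Filter(function(s) s$group == "non_clinician", co$sequences),
               function(s) normalize_map(fixations_to_map(s, 96, 96)))
  s0 <- bootstrap_iou(pm, pn, "low", n_boot = 400, seed = 0)
  s1 <- bootstrap_iou(pm, pn, "low", n_boot = 400, seed = 1)
  expect_lt(abs(s0$se - s1$se) / max(s0$se, 1e-9), 0.2)
  expect_error(bootstrap_iou(list(m), list(m), n_boot = 1), "n_boot")
})

test_that("bootstrap equals the naive resample-and-recompute oracle", {
  # small groups: replay the same RNG stream through an independent
  # implementation built from the public average/binarize/iou primitives
  set.seed(31)
  ga <- lapply(1:4, function(i) normalize_map(random_map(12, 12)))
  gb <- lapply(1:3, function(i) normalize_map(random_map(12, 12)))
  fast <- bootstrap_iou(ga, gb, "low", n_boot = 30, seed = 9)
  naive_mask <- function(maps) {
    binarize(average_maps(maps, normalize = FALSE), "low")
  }
  set.seed(9)
  reps <- vapply(1:30, function(r) {
    ia <- sample.int(4, replace = TRUE)
    ib <- sample.int(3, replace = TRUE)
    iou(naive_mask(ga[ia]), naive_mask(gb[ib]))
  }, numeric(1))
  expect_equal(fast$effect, iou(naive_mask(ga), naive_mask(gb)))
  expect_equal(fast$se, stats::sd(reps))
})

test_that("DerSimonian-Laird pooling matches its formulas and metafor", {
  eff <- function(y, se, sid = "s") {
    structure(list(stimulus_id = sid, effect = y, se = se, n_boot = 100L),
              class = "effect_estimate")
  }
  # equal effects, equal se: pooled = y, tau2 = 0, Q = 0
  same <- lapply(1:4, function(i) eff(0.42, 0.1, paste0("s", i)))
  m <- re_meta_analysis(same)
  expect_equal(m$pooled, 0.42)
  expect_equal(m$tau2, 0)
  expect_equal(m$q_stat, 0)
  # two symmetric effects with equal se -> midpoint
  m2 <- re_meta_analysis(list(eff(0.4, 0.1, "a"), eff(0.6, 0.1, "b")))
  expect_equal(m2$pooled, 0.5)
  # independent oracle: metafor's DL estimator on random inputs
  skip_if_not_installed("metafor")
  set.seed(17)
  for (rep in 1:5) {
    k <- sample(5:16, 1)
    y <- stats::runif(k, 0.1, 0.9)
    se <- stats::runif(k, 0.02, 0.2)
    ours <- re_meta_analysis(data.frame(effect = y, se = se))
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(ours$pooled, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$q_stat, ref$QE, tolerance = 1e-10)
  }
})

test_that("with tau2 = 0 the RE model reduces to fixed-effect pooling", {
  set.seed(19)
  y <- stats::runif(10); se <- stats::runif(10, 0.05, 0.3)
  fe <- re_meta_analysis(data.frame(effect = y, se = se), method = "FE")
  w <- 1 / se^2
  expect_equal(fe$pooled, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(fe$tau2, 0)
  # homogeneous effects: DL tau2 underflows to 0 and equals FE
  y2 <- rep(0.5, 6); se2 <- stats::runif(6, 0.05, 0.2)
  dl <- re_meta_analysis(data.frame(effect = y2, se = se2))
  fe2 <- re_meta_analysis(data.frame(effect = y2, se = se2), method = "FE")
  expect_equal(dl$pooled, fe2$pooled, tolerance = 1e-12)
  # se floor kicks in with a warning
  expect_warning(
    re_meta_analysis(data.frame(effect = c(0.3, 0.4), se = c(0, 0.1))),
    "floor")
  expect_error(re_meta_analysis(data.frame(effect = 0.3, se = 0.1)),
               "at least 2")
})
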
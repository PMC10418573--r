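# Dual-threshold binarization, intersection-over-union, bootstrap standard
# errors, and random-effects pooling across stimuli.

#' Binarize an attention map at a quantile threshold
#'
#' Two thresholds are used throughout the analyses: a low one that removes
#' only spurious noise, and a high one that keeps only the regions of
#' highest attention. Thresholds are quantiles of the map's *nonzero* values
#' — most of a face image is zero-attention background, and including it
#' would make the thresholds degenerate. A cell enters the mask when its
#' value strictly exceeds the threshold, so the low mask always contains the
#' high mask.
#'
#' @param map a nonnegative [attention_map()]; an all-zero map yields an
#'   all-zero mask.
#' @param kind `"low"` or `"high"`.
#' @param q_low,q_high quantile levels in (0, 1) for the two threshold kinds
#'   (defaults 0.25 and 0.75).
#' @return a `binary_map`: a 0/1 integer matrix with attributes
#'   `threshold_kind` and `source_kind`.
#' @export
binarize <- function(map, kind = c("low", "high"), q_low = 0.25, q_high = 0.75) {
  kind <- match.arg(kind)
  stopifnot(is_attention_map(map))
  q <- if (kind == "low") q_low else q_high
  if (q <= 0 || q >= 1) stop("quantile level must be in (0, 1)", call. = FALSE)
  v <- unclass(map)
  if (any(v < 0)) stop("binarize requires a nonnegative map", call. = FALSE)
  t <- nonzero_quantile(v, q)
  mask <- if (is.na(t)) matrix(0L, nrow(v), ncol(v)) else (v > t) * 1L
  source_kind <- if (map_kind(map) == "saliency") "saliency" else "gaze"
  structure(mask, threshold_kind = kind, source_kind = source_kind,
            class = c("binary_map", "matrix", "array"))
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map [%s threshold, %s]> %d x %d px, %d cells on\n",
              attr(x, "threshold_kind"), attr(x, "source_kind"),
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' `|a AND b| / |a OR b|`, in `[0, 1]`; 1 means identical masks, 0 disjoint.
#' Masks must share dimensions and threshold kind (like is compared with
#' like). When both masks are empty the IoU is defined as 0 (dissimilar by
#' convention, with a warning) so downstream meta-analysis inputs stay
#' finite.
#'
#' @param a,b `binary_map`s from [binarize()].
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "binary_map"), inherits(b, "binary_map"))
  check_same_dim(a, b, what = "masks")
  if (!identical(attr(a, "threshold_kind"), attr(b, "threshold_kind"))) {
    stop("threshold kind mismatch: '", attr(a, "threshold_kind"), "' vs '",
         attr(b, "threshold_kind"), "'", call. = FALSE)
  }
  union <- sum(a | b)
  if (union == 0L) {
    warning("both masks empty; IoU defined as 0", call. = FALSE)
    return(0)
  }
  sum(a & b) / union
}

#' Bootstrap IoU between two participant groups on one stimulus
#'
#' The point estimate is the IoU of the binarized group-average maps built
#' from all participants. Uncertainty comes from resampling participants
#' (the exchangeable unit) with replacement within each group independently,
#' recomputing average, optional common-pattern subtraction and smoothing,
#' binarization, and IoU per replicate; the standard error is the standard
#' deviation of the replicates.
#'
#' @param group_a,group_b lists of per-participant normalized
#'   [attention_map()]s.
#' @param kind threshold kind, `"low"` or `"high"`.
#' @param n_boot number of bootstrap replicates (>= 2; default 1000).
#' @param seed integer seed for reproducibility.
#' @param q_low,q_high threshold quantiles passed to [binarize()].
#' @param common_a,common_b optional [common_attention()]s (or plain
#'   [attention_map()]s) subtracted from the respective group average before
#'   binarization, with negatives clipped.
#' @param smooth_px optional odd box side applied after subtraction.
#' @param stimulus_id carried through to the result.
#' @return an `effect_estimate`: list with `stimulus_id`, `effect`, `se`,
#'   `n_boot`.
#' @export
bootstrap_iou <- function(group_a, group_b, kind = c("low", "high"),
                          n_boot = 1000, seed = NULL,
                          q_low = 0.25, q_high = 0.75,
                          common_a = NULL, common_b = NULL,
                          smooth_px = NULL, stimulus_id = NA_character_) {
  kind <- match.arg(kind)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  q <- if (kind == "low") q_low else q_high
  if (q <= 0 || q >= 1) stop("quantile level must be in (0, 1)", call. = FALSE)
  h <- nrow(group_a[[1]]); w <- ncol(group_a[[1]])
  for (m in c(group_a, group_b)) check_same_dim(group_a[[1]], m)
  common_vec <- function(common) {
    if (is.null(common)) return(NULL)
    cm <- if (inherits(common, "common_attention")) common$map else common
    check_same_dim(group_a[[1]], cm, what = "maps and common pattern")
    as.vector(unclass(cm))
  }
  ca <- common_vec(common_a); cb <- common_vec(common_b)
  # participants x pixels stacks; a bootstrap average is a weighted column
  # mean with multinomial weights, so replicates avoid re-copying maps
  stack_a <- do.call(rbind, lapply(group_a, function(m) as.vector(unclass(m))))
  stack_b <- do.call(rbind, lapply(group_b, function(m) as.vector(unclass(m))))
  mask_of <- function(stack, wts, cvec) {
    v <- as.vector(wts %*% stack) / sum(wts)
    if (!is.null(cvec)) v <- v - cvec
    v[v < 0] <- 0
    m <- matrix(v, h, w)
    if (!is.null(smooth_px) && smooth_px > 1) m <- box_mean(m, smooth_px)
    nz <- m[m > 0]
    if (length(nz) == 0L) return(m > 0)
    m > stats::quantile(nz, q, names = FALSE, type = 7)
  }
  iou_of <- function(ma, mb) {
    u <- sum(ma | mb)
    if (u == 0L) 0 else sum(ma & mb) / u
  }
  ones_a <- rep(1, nrow(stack_a)); ones_b <- rep(1, nrow(stack_b))
  effect <- iou_of(mask_of(stack_a, ones_a, ca), mask_of(stack_b, ones_b, cb))
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      wa <- tabulate(sample.int(nrow(stack_a), replace = TRUE), nrow(stack_a))
      wb <- tabulate(sample.int(nrow(stack_b), replace = TRUE), nrow(stack_b))
      iou_of(mask_of(stack_a, wa, ca), mask_of(stack_b, wb, cb))
    }, numeric(1))
  })
  structure(list(stimulus_id = stimulus_id, effect = effect,
                 se = stats::sd(reps), n_boot = as.integer(n_boot)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: IoU = %.3f (bootstrap SE %.3f, %d replicates)\n",
              x$stimulus_id, x$effect, x$se, x$n_boot))
  invisible(x)
}

#' Random-effects meta-analysis of per-stimulus effects
#'
#' Pools per-stimulus IoU estimates across stimuli with the
#' DerSimonian-Laird estimator of the between-stimulus variance tau^2:
#' fixed weights \eqn{w_i = 1/se_i^2}, heterogeneity
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))},
#' random-effects weights \eqn{w^*_i = 1/(se_i^2 + \tau^2)}, pooled effect
#' \eqn{\sum w^*_i y_i / \sum w^*_i} with 95% CI
#' \eqn{\pm 1.96 (\sum w^*_i)^{-1/2}}. With `method = "FE"` (or when
#' tau^2 = 0) this reduces to fixed-effect inverse-variance pooling.
#'
#' @param effects list of [bootstrap_iou()] `effect_estimate`s, or a data
#'   frame with columns `effect` and `se` (optionally `stimulus_id`).
#' @param method `"DL"` (default) or `"FE"` (tau^2 forced to 0).
#' @param se_floor standard errors of exactly 0 (degenerate single-member
#'   groups) are raised to this floor with a warning so weights stay finite.
#' @return a `meta_result`: list with `pooled`, `ci_low`, `ci_high`, `tau2`,
#'   `q_stat`, `k`, `method`.
#' @export
re_meta_analysis <- function(effects, method = c("DL", "FE"), se_floor = 1e-6) {
  method <- match.arg(method)
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  if (is.list(effects) && !is.data.frame(effects)) {
    effects <- data.frame(
      stimulus_id = vapply(effects, function(e) as.character(e$stimulus_id), ""),
      effect = vapply(effects, function(e) e$effect, numeric(1)),
      se = vapply(effects, function(e) e$se, numeric(1))
    )
  }
  k <- nrow(effects)
  if (k < 2) stop("meta-analysis needs at least 2 stimuli", call. = FALSE)
  y <- effects$effect
  se <- effects$se
  if (any(!is.finite(y)) || any(!is.finite(se))) {
    stop("effects and standard errors must be finite", call. = FALSE)
  }
  if (any(se < se_floor)) {
    warning("standard error(s) below ", se_floor, " raised to the floor",
            call. = FALSE)
    se <- pmax(se, se_floor)
  }
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  tau2 <- if (method == "FE") 0 else {
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  half <- 1.96 / sqrt(sum(wstar))
  structure(list(pooled = pooled, ci_low = pooled - half,
                 ci_high = pooled + half, tau2 = tau2, q_stat = q,
                 k = as.integer(k), method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result [%s]> pooled = %.3f [%.3f, %.3f], tau2 = %.4g, Q = %.2f, k = %d\n",
              x$method, x$pooled, x$ci_low, x$ci_high, x$tau2, x$q_stat, x$k))
  invisible(x)
}
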
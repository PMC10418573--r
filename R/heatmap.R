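# Building continuous attention maps from fixations, plus the smoothing and
# averaging primitives used by the preprocessing pipeline.

# Kernel patch of side 2r+1 centred on the fixation. Linear falloff
# (1 - d/r, clipped at 0) is the default; it matches the qualitative shape of
# the eye-tracker vendor's rendering kernel. All kernels have support
# radius_px and peak 1 at the centre, so a fixation deposits at most
# duration_ms per cell and total mass = duration_ms * sum(kernel) when the
# patch is fully inside the image.
fixation_kernel <- function(radius_px, kernel = c("linear", "gaussian", "flat")) {
  kernel <- match.arg(kernel)
  off <- -radius_px:radius_px
  d <- sqrt(outer(off^2, off^2, "+"))
  switch(kernel,
    linear = pmax(1 - d / radius_px, 0),  # first arg keeps the dim attribute
    gaussian = ifelse(d <= radius_px, exp(-d^2 / (2 * (radius_px / 2)^2)), 0),
    flat = (d <= radius_px) * 1
  )
}

#' Rasterize a fixation sequence into a gaze heat map
#'
#' Each fixation deposits mass equal to its duration (ms) through a radially
#' decreasing kernel of support `radius_px` centred at its position;
#' contributions from different fixations add. Fixation centres falling
#' outside the image are clipped to the boundary (off-screen gaze still
#' carries signal); the number of clipped fixations is reported in a message.
#'
#' @param seq a [fixation_sequence()].
#' @param width_px,height_px stimulus dimensions in pixels.
#' @param radius_px kernel support radius in pixels (default 25, the
#'   eye-tracking radius used throughout the analyses).
#' @param kernel kernel shape: `"linear"` (default, falloff `1 - d/r`),
#'   `"gaussian"`, or `"flat"`.
#' @return an [attention_map()] of kind `"gaze"`. An empty sequence yields an
#'   all-zero map.
#' @export
fixations_to_map <- function(seq, width_px, height_px, radius_px = 25,
                             kernel = c("linear", "gaussian", "flat")) {
  stopifnot(inherits(seq, "fixation_sequence"),
            width_px >= 1, height_px >= 1, radius_px >= 1)
  k <- fixation_kernel(radius_px, kernel)
  acc <- matrix(0, height_px, width_px)
  fx <- seq$fixations
  if (nrow(fx) == 0L) return(attention_map(acc, kind = "gaze"))
  # 0-based continuous coordinates -> 1-based matrix indices
  cx <- round(fx$x_px) + 1
  cy <- round(fx$y_px) + 1
  clipped <- cx < 1 | cx > width_px | cy < 1 | cy > height_px
  if (any(clipped)) {
    message(sum(clipped), " fixation(s) outside image bounds clipped to boundary")
    cx <- pmin(width_px, pmax(1, cx))
    cy <- pmin(height_px, pmax(1, cy))
  }
  side <- 2 * radius_px + 1
  for (i in seq_len(nrow(fx))) {
    r0 <- cy[i] - radius_px; r1 <- cy[i] + radius_px
    c0 <- cx[i] - radius_px; c1 <- cx[i] + radius_px
    kr <- max(1, 2 - r0):(side - max(0, r1 - height_px))
    kc <- max(1, 2 - c0):(side - max(0, c1 - width_px))
    rr <- max(1, r0):min(height_px, r1)
    cc <- max(1, c0):min(width_px, c1)
    acc[rr, cc] <- acc[rr, cc] + fx$duration_ms[i] * k[kr, kc]
  }
  attention_map(acc, kind = "gaze")
}

#' Box smoothing
#'
#' Replaces every cell by the mean of its `kernel_px` x `kernel_px`
#' neighbourhood. At image borders the neighbourhood is truncated and the
#' mean is taken over in-bounds cells only, so a constant map stays constant.
#'
#' @param map an [attention_map()].
#' @param kernel_px odd box side length; 1 is the identity.
#' @return an [attention_map()] of the same kind.
#' @export
box_smooth <- function(map, kernel_px) {
  stopifnot(is_attention_map(map))
  if (kernel_px < 1 || kernel_px %% 2 == 0) {
    stop("kernel_px must be odd and >= 1", call. = FALSE)
  }
  if (kernel_px == 1) return(map)
  as_map(box_mean(unclass(map), kernel_px), kind = map_kind(map))
}

# Separable running-box mean with border truncation, O(n) per dimension via
# cumulative sums. Used by box_smooth and the synthetic stimulus generator.
box_mean <- function(m, k) {
  r <- (k - 1) / 2
  run <- function(x) {
    # windowed sums along rows with truncation; column-major cumsum carries
    # across columns, but both window ends sit in the same column so the
    # carry-in cancels — the top row holds each column's carry-in
    n <- nrow(x)
    cs <- cumsum(x)
    dim(cs) <- dim(x)
    top <- c(0, cs[n, -ncol(x)])
    cs0 <- rbind(top, cs)
    hi <- pmin(n, seq_len(n) + r) + 1L
    lo <- pmax(0L, seq_len(n) - r - 1L) + 1L
    cs0[hi, , drop = FALSE] - cs0[lo, , drop = FALSE]
  }
  sums <- t(run(t(run(m))))
  counts_r <- pmin(nrow(m), seq_len(nrow(m)) + r) - pmax(1, seq_len(nrow(m)) - r) + 1
  counts_c <- pmin(ncol(m), seq_len(ncol(m)) + r) - pmax(1, seq_len(ncol(m)) - r) + 1
  sums / outer(counts_r, counts_c)
}

#' Normalize an attention map to unit mass
#'
#' Scales values to sum to 1 (probability-mass convention) so participants
#' with longer total fixation time do not dominate group averages.
#'
#' @param map an [attention_map()] with at least one positive value.
#' @return the normalized [attention_map()].
#' @export
normalize_map <- function(map) {
  stopifnot(is_attention_map(map))
  s <- sum(map)
  if (s <= 0) stop("cannot normalize an all-zero attention map", call. = FALSE)
  as_map(unclass(map) / s, kind = map_kind(map))
}

#' Average attention maps
#'
#' Cell-wise arithmetic mean. By default each input is normalized to unit
#' mass first, which is the convention for cross-participant averaging; set
#' `normalize = FALSE` for a plain mean (e.g. of already-commensurate maps).
#'
#' @param maps non-empty list of [attention_map()]s with identical
#'   dimensions.
#' @param normalize normalize each input to unit mass before averaging
#'   (default `TRUE`).
#' @return an [attention_map()]; kind is taken from the first input.
#' @export
average_maps <- function(maps, normalize = TRUE) {
  if (length(maps) == 0L) stop("need at least one map to average", call. = FALSE)
  stopifnot(all(vapply(maps, is_attention_map, logical(1))))
  ref <- maps[[1]]
  for (i in seq_along(maps)) {
    check_same_dim(ref, maps[[i]], what = sprintf("maps 1 and %d", i))
  }
  if (normalize) maps <- lapply(maps, normalize_map)
  acc <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  as_map(acc, kind = map_kind(ref))
}
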
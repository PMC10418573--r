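# Occlusion-sensitivity saliency maps for a pluggable classifier, ensemble
# averaging, and threshold-matched comparison against gaze heat maps.

#' Classifier adapter
#'
#' Wraps any image classifier behind the interface the saliency code needs:
#' a `predict` function taking a height x width (x channels) numeric array
#' with values in `[0, 1]` and returning a probability vector over `labels`
#' (nonnegative, summing to 1 within 1e-6). Lets users plug a trained deep
#' model; tests use an analytic toy classifier.
#'
#' @param predict function(image) -> numeric probability vector.
#' @param labels ordered character vector of class labels.
#' @param input_size required square image side in pixels (default 448, the
#'   resize convention for the classifier ensemble).
#' @return a `classifier_adapter`.
#' @export
classifier_adapter <- function(predict, labels, input_size = 448) {
  stopifnot(is.function(predict), length(labels) >= 2, input_size >= 1)
  structure(list(predict = predict, labels = as.character(labels),
                 input_size = as.integer(input_size)),
            class = "classifier_adapter")
}

# Validate the probability contract at each call site.
check_probs <- function(p, clf) {
  if (length(p) != length(clf$labels) || any(p < -1e-9) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("classifier returned a non-normalized probability vector",
         call. = FALSE)
  }
  invisible(p)
}

# Left edges (1-based) of occlusion boxes along one axis: a stride grid,
# extended with a final position so the last box touches the image edge.
occlusion_positions <- function(size, box, stride) {
  pos <- seq(1L, size - box + 1L, by = stride)
  if (pos[length(pos)] != size - box + 1L) pos <- c(pos, size - box + 1L)
  pos
}

#' Occlusion-sensitivity saliency map
#'
#' Slides an occluding box over the image on a stride grid; at each position
#' the box is replaced by a fill value and the drop in the classifier's
#' probability for `label_index` is recorded. Each pixel's saliency is the
#' mean drop over all boxes covering it (at the default box 20 / stride 10
#' every interior pixel is covered by exactly 4 boxes); negative pixel values
#' — occlusions that *increase* the target probability — are clipped to 0.
#'
#' @param clf a [classifier_adapter()].
#' @param image numeric array, height x width (x channels), values in
#'   `[0, 1]`; height and width must equal `clf$input_size`.
#' @param label_index 1-based index into `clf$labels` of the class whose
#'   probability is probed (normally the ground-truth label).
#' @param box_px occluder side in pixels (default 20).
#' @param stride_px step between box positions (default 10); must satisfy
#'   `1 <= stride_px <= box_px <= input_size`.
#' @param fill occluder fill: `"mean"` (per-channel image mean, default),
#'   `"gray"` (0.5), or `"zero"`.
#' @param attribution `"footprint"` (default: a box's drop is spread over its
#'   whole footprint and pixels average over covering boxes) or `"center"`
#'   (the drop is assigned to the box's central stride cell only).
#' @return an [attention_map()] of kind `"saliency"`.
#' @export
occlusion_map <- function(clf, image, label_index,
                          box_px = 20, stride_px = 10,
                          fill = c("mean", "gray", "zero"),
                          attribution = c("footprint", "center")) {
  fill <- match.arg(fill)
  attribution <- match.arg(attribution)
  stopifnot(inherits(clf, "classifier_adapter"))
  dims <- dim(image)
  if (is.null(dims)) stop("image must be a matrix or array", call. = FALSE)
  h <- dims[1]; w <- dims[2]
  if (h != clf$input_size || w != clf$input_size) {
    stop("image is ", h, "x", w, " but the classifier expects ",
         clf$input_size, "x", clf$input_size, call. = FALSE)
  }
  if (stride_px < 1 || stride_px > box_px || box_px > clf$input_size) {
    stop("need 1 <= stride_px <= box_px <= input_size", call. = FALSE)
  }
  if (label_index < 1 || label_index > length(clf$labels)) {
    stop("label_index out of range", call. = FALSE)
  }
  nch <- if (length(dims) == 3) dims[3] else 1L
  fill_val <- switch(fill,
    mean = if (nch == 1L) mean(image) else apply(image, 3, mean),
    gray = rep(0.5, nch),
    zero = rep(0, nch)
  )
  p0 <- check_probs(clf$predict(image), clf)[label_index]
  rows <- occlusion_positions(h, box_px, stride_px)
  cols <- occlusion_positions(w, box_px, stride_px)
  drop_sum <- matrix(0, h, w)
  cover <- matrix(0, h, w)
  for (r0 in rows) {
    for (c0 in cols) {
      rr <- r0:(r0 + box_px - 1)
      cc <- c0:(c0 + box_px - 1)
      occ <- image
      if (nch == 1L) {
        occ[rr, cc] <- fill_val
      } else {
        for (ch in seq_len(nch)) occ[rr, cc, ch] <- fill_val[ch]
      }
      drop <- p0 - check_probs(clf$predict(occ), clf)[label_index]
      if (attribution == "footprint") {
        drop_sum[rr, cc] <- drop_sum[rr, cc] + drop
        cover[rr, cc] <- cover[rr, cc] + 1
      } else {
        cr <- (r0 + box_px %/% 2 - stride_px %/% 2):(r0 + box_px %/% 2 + (stride_px - 1) %/% 2)
        cc2 <- (c0 + box_px %/% 2 - stride_px %/% 2):(c0 + box_px %/% 2 + (stride_px - 1) %/% 2)
        cr <- cr[cr >= 1 & cr <= h]; cc2 <- cc2[cc2 >= 1 & cc2 <= w]
        drop_sum[cr, cc2] <- drop_sum[cr, cc2] + drop
        cover[cr, cc2] <- cover[cr, cc2] + 1
      }
    }
  }
  sal <- ifelse(cover > 0, drop_sum / pmax(cover, 1), 0)
  attention_map(pmax(sal, 0), kind = "saliency")
}

#' Average an ensemble of saliency maps
#'
#' Plain cell-wise mean of saliency maps, e.g. from the models of a 5-fold
#' cross-validation ensemble. All maps must have the same kind and
#' dimensions.
#'
#' @param maps non-empty list of [attention_map()]s of identical kind.
#' @return an [attention_map()] of the shared kind.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map", call. = FALSE)
  stopifnot(all(vapply(maps, is_attention_map, logical(1))))
  kinds <- unique(vapply(maps, map_kind, ""))
  if (length(kinds) != 1L) {
    stop("cannot average maps of mixed kinds: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  average_maps(maps, normalize = FALSE)
}

#' Threshold-matched IoU between a saliency map and a gaze map
#'
#' Binarizes both maps at the *same* quantile threshold kind (low, then
#' high) and computes the IoU at each, so model and human attention are
#' filtered identically before comparison. If the saliency map's resolution
#' differs from the attention map's, it is resampled by nearest neighbour
#' first (preserving mask topology).
#'
#' @param sal saliency [attention_map()].
#' @param att gaze or difference [attention_map()].
#' @param q_low,q_high threshold quantiles (see [binarize()]).
#' @return data frame with columns `kind` (`"low"`, `"high"`) and `iou`.
#' @export
saliency_vs_attention <- function(sal, att, q_low = 0.25, q_high = 0.75) {
  stopifnot(is_attention_map(sal), is_attention_map(att))
  if (nrow(sal) != nrow(att) || ncol(sal) != ncol(att)) {
    sal <- attention_map(resample_nearest(unclass(sal), nrow(att), ncol(att)),
                         kind = map_kind(sal))
  }
  vals <- vapply(c("low", "high"), function(k) {
    iou(binarize(sal, k, q_low, q_high), binarize(att, k, q_low, q_high))
  }, numeric(1))
  data.frame(kind = c("low", "high"), iou = unname(vals))
}
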
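# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded
#' computations (bootstraps, generators) do not disturb the session stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a character string; used to derive independent
# per-participant RNG streams from a single cohort seed.
str_seed <- function(x, base = 0L) {
  codes <- utf8ToInt(as.character(x))
  h <- as.numeric(base %% 2147483647)
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Quantile of the nonzero cells of a map; returns NA when the map is all-zero.
nonzero_quantile <- function(values, q) {
  nz <- values[values > 0]
  if (length(nz) == 0L) return(NA_real_)
  stats::quantile(nz, probs = q, names = FALSE, type = 7)
}

# Nearest-neighbour resampling of a matrix to new dimensions. Preserves mask
# topology better than interpolation, which is why it is used ahead of IoU.
resample_nearest <- function(m, nrow_out, ncol_out) {
  ri <- pmin(nrow(m), pmax(1L, round((seq_len(nrow_out) - 0.5) * nrow(m) / nrow_out + 0.5)))
  ci <- pmin(ncol(m), pmax(1L, round((seq_len(ncol_out) - 0.5) * ncol(m) / ncol_out + 0.5)))
  m[ri, ci, drop = FALSE]
}

#' Boundary-inclusive point-in-polygon test (even-odd rule)
#'
#' A point lying exactly on a polygon edge or vertex counts as inside. The
#' even-odd (ray crossing) rule handles non-convex polygons.
#'
#' @param x,y point coordinates (vectors of equal length).
#' @param poly two-column matrix of polygon vertices (x, y), not necessarily
#'   closed.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  vapply(seq_along(x), function(k) {
    xp <- x[k]; yp <- y[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # on-segment check (boundary-inclusive)
      cross <- (xj - xi) * (yp - yi) - (yj - yi) * (xp - xi)
      if (abs(cross) < 1e-9 &&
          xp >= min(xi, xj) - 1e-9 && xp <= max(xi, xj) + 1e-9 &&
          yp >= min(yi, yj) - 1e-9 && yp <= max(yi, yj) + 1e-9) {
        return(TRUE)
      }
      if ((yi > yp) != (yj > yp)) {
        xcross <- xi + (yp - yi) * (xj - xi) / (yj - yi)
        if (xp < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# TRUE when a polygon has no two non-adjacent edges that intersect.
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  segs_intersect <- function(a, b) {
    d1 <- (b[2, 1] - b[1, 1]) * (a[1, 2] - b[1, 2]) - (b[2, 2] - b[1, 2]) * (a[1, 1] - b[1, 1])
    d2 <- (b[2, 1] - b[1, 1]) * (a[2, 2] - b[1, 2]) - (b[2, 2] - b[1, 2]) * (a[2, 1] - b[1, 1])
    d3 <- (a[2, 1] - a[1, 1]) * (b[1, 2] - a[1, 2]) - (a[2, 2] - a[1, 2]) * (b[1, 1] - a[1, 1])
    d4 <- (a[2, 1] - a[1, 1]) * (b[2, 2] - a[1, 2]) - (a[2, 2] - a[1, 2]) * (b[2, 1] - a[1, 1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segs_intersect(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}
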
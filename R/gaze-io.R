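# Reading and writing fixation tables, AOI definitions, and heat-map images.
#
# Coordinate convention everywhere: 0-based pixels, origin top-left,
# x = column, y = row. Matches the raster image convention; conversion to
# R's 1-based matrix indices happens only inside rasterizing code.

GROUP_LEVELS <- c("clinician", "non_clinician")

#' Fixation sequences
#'
#' One participant's time-ordered fixations on one stimulus. Fixations carry
#' a position (`x_px`, `y_px`, 0-based pixels), an onset relative to stimulus
#' presentation, and a duration, both in milliseconds. Sequences from a
#' seven-second viewing paradigm must fit inside the viewing window.
#'
#' @param participant_id opaque participant identifier.
#' @param group `"clinician"` or `"non_clinician"`.
#' @param stimulus_id opaque stimulus identifier.
#' @param fixations data frame with columns `x_px`, `y_px`, `onset_ms`,
#'   `duration_ms`. Rows are sorted by onset; overlapping fixations are an
#'   error.
#' @param viewing_ms length of the viewing window in ms (default 7000);
#'   `NULL` disables the window check.
#' @return a `fixation_sequence` object.
#' @export
fixation_sequence <- function(participant_id, group, stimulus_id, fixations,
                              viewing_ms = 7000) {
  group <- match.arg(group, GROUP_LEVELS)
  fixations <- as.data.frame(fixations)
  required <- c("x_px", "y_px", "onset_ms", "duration_ms")
  missing <- setdiff(required, names(fixations))
  if (length(missing)) {
    stop("fixations table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fixations <- fixations[required]
  if (nrow(fixations)) {
    if (any(fixations$duration_ms <= 0)) stop("fixation durations must be > 0", call. = FALSE)
    if (any(fixations$onset_ms < 0)) stop("fixation onsets must be >= 0", call. = FALSE)
    fixations <- fixations[order(fixations$onset_ms), , drop = FALSE]
    rownames(fixations) <- NULL
    ends <- fixations$onset_ms + fixations$duration_ms
    if (nrow(fixations) > 1 &&
        any(fixations$onset_ms[-1] < ends[-nrow(fixations)] - 1e-9)) {
      stop("fixations overlap in time for participant ", participant_id,
           ", stimulus ", stimulus_id, call. = FALSE)
    }
    if (!is.null(viewing_ms) && any(ends > viewing_ms + 1e-9)) {
      stop("fixation extends past the ", viewing_ms, " ms viewing window ",
           "(participant ", participant_id, ", stimulus ", stimulus_id, ")",
           call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         stimulus_id = as.character(stimulus_id), fixations = fixations),
    class = "fixation_sequence"
  )
}

#' @export
print.fixation_sequence <- function(x, ...) {
  cat(sprintf("<fixation_sequence> %s (%s) on %s: %d fixations, %.0f ms total\n",
              x$participant_id, x$group, x$stimulus_id,
              nrow(x$fixations), sum(x$fixations$duration_ms)))
  invisible(x)
}

#' Read a fixation table
#'
#' Parses a Tobii-style tab-separated fixation export into a list of
#' [fixation_sequence()] objects, one per (participant, stimulus) pair.
#' Expected columns: `participant_id`, `group`, `stimulus_id`, `x_px`,
#' `y_px`, `onset_ms`, `duration_ms`. Lines starting with `#` are ignored.
#' Rows with missing coordinates are dropped and counted in a message;
#' non-numeric values in numeric columns are a row-level error naming the
#' offending line.
#'
#' @param source path to a TSV file or a connection.
#' @param viewing_ms viewing window passed to [fixation_sequence()].
#' @return list of `fixation_sequence`, ordered by participant then stimulus.
#' @export
read_fixation_table <- function(source, viewing_ms = 7000) {
  df <- utils::read.delim(source, comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "stimulus_id",
                "x_px", "y_px", "onset_ms", "duration_ms")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("fixation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("x_px", "y_px", "onset_ms", "duration_ms")
  for (col in num_cols) {
    raw <- trimws(df[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data line %d",
                   raw[bad[1]], col, bad[1]), call. = FALSE)
    }
    df[[col]] <- val
  }
  dropped <- is.na(df$x_px) | is.na(df$y_px)
  if (any(dropped)) {
    message(sum(dropped), " fixation row(s) with missing coordinates dropped")
    df <- df[!dropped, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(list())
  keys <- interaction(df$participant_id, df$stimulus_id, drop = TRUE, sep = "\r")
  out <- lapply(split(df, keys), function(d) {
    fixation_sequence(d$participant_id[1], d$group[1], d$stimulus_id[1],
                      d[c("x_px", "y_px", "onset_ms", "duration_ms")],
                      viewing_ms = viewing_ms)
  })
  ord <- order(vapply(out, function(s) s$participant_id, ""),
               vapply(out, function(s) s$stimulus_id, ""))
  unname(out[ord])
}

#' Write a fixation table
#'
#' Inverse of [read_fixation_table()]; a write/read round trip preserves all
#' fields.
#'
#' @param sequences list of [fixation_sequence()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(sequences, path) {
  rows <- lapply(sequences, function(s) {
    if (nrow(s$fixations) == 0L) return(NULL)
    cbind(data.frame(participant_id = s$participant_id, group = s$group,
                     stimulus_id = s$stimulus_id, stringsAsFactors = FALSE),
          s$fixations)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(participant_id = character(), group = character(),
                     stimulus_id = character(), x_px = numeric(),
                     y_px = numeric(), onset_ms = numeric(),
                     duration_ms = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heat-map color scheme
#'
#' The three-level color scheme used for rendered gaze heat maps:
#' high `#943126`, medium `#B03A2E`, low `#CB4335`, with fully transparent
#' background.
#'
#' @param high_hex,medium_hex,low_hex RGB hex codes; must be distinct.
#' @return a `color_scheme` object.
#' @export
color_scheme <- function(high_hex = "#943126", medium_hex = "#B03A2E",
                         low_hex = "#CB4335") {
  codes <- c(high = high_hex, medium = medium_hex, low = low_hex)
  if (anyDuplicated(toupper(codes))) {
    stop("color scheme codes must be distinct", call. = FALSE)
  }
  rgb <- t(grDevices::col2rgb(codes))  # 3 x {r,g,b}, 0..255
  rownames(rgb) <- names(codes)
  structure(list(codes = codes, rgb = rgb), class = "color_scheme")
}

#' Decode a rendered heat-map image into an attention map
#'
#' Maps scheme colors to ordinal attention levels (high = 3, medium = 2,
#' low = 1) and transparent background to 0. Anti-aliased edge pixels whose
#' color is within a Euclidean RGB distance `tolerance` of a scheme code are
#' accepted silently; pixels farther than that are assigned the nearest code
#' with a warning reporting the off-palette fraction.
#'
#' @param rgba height x width x 4 array in `[0, 1]` (as from
#'   [png::readPNG()]); background pixels have alpha 0.
#' @param scheme a [color_scheme()].
#' @param tolerance Euclidean RGB distance (0-255 scale) within which a pixel
#'   matches a code; default 16.
#' @return an [attention_map()] of kind `"gaze"` with values in {0, 1, 2, 3}.
#' @export
decode_heatmap_image <- function(rgba, scheme = color_scheme(), tolerance = 16) {
  stopifnot(length(dim(rgba)) == 3, dim(rgba)[3] >= 3)
  h <- dim(rgba)[1]; w <- dim(rgba)[2]
  alpha <- if (dim(rgba)[3] >= 4) rgba[, , 4] else matrix(1, h, w)
  px <- cbind(as.vector(rgba[, , 1]), as.vector(rgba[, , 2]),
              as.vector(rgba[, , 3])) * 255
  ref <- scheme$rgb  # rows: high, medium, low
  d2 <- sapply(seq_len(nrow(ref)), function(i) {
    (px[, 1] - ref[i, 1])^2 + (px[, 2] - ref[i, 2])^2 + (px[, 3] - ref[i, 3])^2
  })
  nearest <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  levels <- c(high = 3, medium = 2, low = 1)[nearest]
  levels[as.vector(alpha) == 0] <- 0
  off <- as.vector(alpha) > 0 & mind > tolerance
  if (any(off)) {
    warning(sprintf("%.1f%% of foreground pixels matched no scheme color within tolerance %g; assigned nearest code",
                    100 * mean(off[as.vector(alpha) > 0]), tolerance), call. = FALSE)
  }
  attention_map(matrix(levels, h, w), kind = "gaze")
}

#' Encode an attention map as a heat-map image
#'
#' Inverse of [decode_heatmap_image()] up to quantization. Maps whose values
#' are not already the ordinal levels {0, 1, 2, 3} are quantized by terciles
#' of their nonzero values (upper tercile = high). Level 0 renders as fully
#' transparent background.
#'
#' @param map an [attention_map()] with nonnegative values.
#' @param scheme a [color_scheme()].
#' @return height x width x 4 RGBA array in `[0, 1]`.
#' @export
encode_heatmap_image <- function(map, scheme = color_scheme()) {
  stopifnot(is_attention_map(map))
  v <- unclass(map)
  if (any(v < 0)) {
    stop("cannot encode negative attention values; clip the difference map first",
         call. = FALSE)
  }
  lev <- v
  if (!all(v %in% 0:3)) {
    lev <- matrix(0, nrow(v), ncol(v))
    nz <- v > 0
    if (any(nz)) {
      cuts <- stats::quantile(v[nz], c(1 / 3, 2 / 3), names = FALSE, type = 7)
      lev[nz] <- 1 + findInterval(v[nz], cuts, left.open = TRUE)
    }
  }
  ref <- scheme$rgb / 255
  out <- array(0, dim = c(nrow(v), ncol(v), 4))
  pick <- c("low", "medium", "high")
  for (l in 1:3) {
    sel <- lev == l
    if (!any(sel)) next
    rgb <- ref[pick[l], ]
    for (ch in 1:3) {
      plane <- out[, , ch]; plane[sel] <- rgb[ch]; out[, , ch] <- plane
    }
    aplane <- out[, , 4]; aplane[sel] <- 1; out[, , 4] <- aplane
  }
  out
}

#' Areas of interest
#'
#' An `aoi_set` holds the analyst-drawn polygons over dysmorphic facial
#' features of one stimulus. Polygons are simple (non-self-intersecting),
#' have at least 3 vertices, carry unique names, and — when image dimensions
#' are supplied — lie inside the stimulus bounds.
#'
#' @param stimulus_id stimulus the AOIs belong to.
#' @param aois named list of polygons; each polygon a two-column matrix of
#'   (x, y) vertices in 0-based pixel coordinates.
#' @param width_px,height_px optional stimulus dimensions for the bounds
#'   check.
#' @return an `aoi_set` object.
#' @export
aoi_set <- function(stimulus_id, aois, width_px = NULL, height_px = NULL) {
  if (is.null(names(aois)) || any(!nzchar(names(aois)))) {
    stop("every AOI must be named", call. = FALSE)
  }
  if (anyDuplicated(names(aois))) {
    stop("duplicate AOI name(s): ",
         paste(unique(names(aois)[duplicated(names(aois))]), collapse = ", "),
         call. = FALSE)
  }
  aois <- lapply(aois, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  for (nm in names(aois)) {
    p <- aois[[nm]]
    if (nrow(p) < 3) {
      stop("AOI '", nm, "' has fewer than 3 vertices", call. = FALSE)
    }
    if (!polygon_is_simple(p)) {
      stop("AOI '", nm, "' polygon is self-intersecting", call. = FALSE)
    }
    if (!is.null(width_px) && !is.null(height_px)) {
      if (any(p[, 1] < 0 | p[, 1] > width_px - 1 |
              p[, 2] < 0 | p[, 2] > height_px - 1)) {
        stop("AOI '", nm, "' has vertices outside the stimulus bounds",
             call. = FALSE)
      }
    }
  }
  structure(list(stimulus_id = as.character(stimulus_id), aois = aois),
            class = "aoi_set")
}

#' Read an AOI definition file
#'
#' JSON format: `{"stimulus_id": str, "aois": [{"name": str,
#' "polygon": [[x, y], ...]}]}`. Validation as in [aoi_set()].
#'
#' @param source path or connection to JSON.
#' @inheritParams aoi_set
#' @return an [aoi_set()].
#' @export
read_aoi_set <- function(source, width_px = NULL, height_px = NULL) {
  j <- jsonlite::fromJSON(source, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(j$stimulus_id) || is.null(j$aois)) {
    stop("AOI JSON must contain 'stimulus_id' and 'aois'", call. = FALSE)
  }
  polys <- lapply(j$aois, function(a) {
    do.call(rbind, lapply(a$polygon, function(v) as.numeric(v)))
  })
  names(polys) <- vapply(j$aois, function(a) as.character(a$name), "")
  aoi_set(j$stimulus_id, polys, width_px = width_px, height_px = height_px)
}

#' Write an AOI set to JSON
#'
#' @param aois an [aoi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aoi_set <- function(aois, path) {
  payload <- list(
    stimulus_id = aois$stimulus_id,
    aois = lapply(names(aois$aois), function(nm) {
      list(name = nm,
           polygon = lapply(seq_len(nrow(aois$aois[[nm]])),
                            function(i) unname(aois$aois[[nm]][i, ])))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Persist a continuous attention map
#'
#' Continuous maps are stored as 16-bit grayscale TIFF plus a JSON sidecar
#' `{"scale": max_value, "kind": kind}` mapping gray levels back to real
#' values.
#'
#' @param map an [attention_map()].
#' @param path output image path (`.tiff`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_attention_map <- function(map, path) {
  stopifnot(is_attention_map(map))
  v <- unclass(map)
  if (any(v < 0)) stop("cannot persist negative values; clip first", call. = FALSE)
  scale <- max(v)
  img <- if (scale > 0) v / scale else v
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = scale, kind = map_kind(map)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attention_map
#' @export
read_attention_map <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  attention_map(img * meta$scale, kind = meta$kind)
}
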
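# Cohort accuracy contingency analysis and AOI-based fixation timing
# metrics.

#' Read participant response records
#'
#' TSV columns: `participant_id`, `group`, `stimulus_id`, `truth`
#' (`affected`/`unaffected`), `judgment` (`affected`/`unaffected`/`missing`),
#' and optional `named_condition`.
#'
#' @param source path or connection.
#' @return data frame of response records.
#' @export
read_response_table <- function(source) {
  df <- utils::read.delim(source, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("participant_id", "group", "stimulus_id", "truth", "judgment")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("response table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"named_condition" %in% names(df)) df$named_condition <- NA_character_
  df
}

#' Build the 2x2 correct/incorrect contingency table
#'
#' A response is correct when the participant's affected/unaffected judgment
#' matches the stimulus truth. Responses with `judgment == "missing"` (or
#' `NA`) are dropped and counted in a message — eye-tracking studies rarely
#' have complete data for every participant x stimulus cell.
#'
#' @param responses data frame as from [read_response_table()].
#' @return a `contingency_table`: 2x2 integer matrix, rows `clinician` /
#'   `non_clinician`, columns `correct` / `incorrect`.
#' @export
build_contingency <- function(responses) {
  stopifnot(all(c("group", "truth", "judgment") %in% names(responses)))
  drop <- is.na(responses$judgment) | responses$judgment == "missing"
  if (any(drop)) {
    message(sum(drop), " response(s) with missing judgment dropped")
    responses <- responses[!drop, , drop = FALSE]
  }
  if (nrow(responses) == 0L) stop("no non-missing responses", call. = FALSE)
  correct <- responses$judgment == responses$truth
  counts <- matrix(0L, 2, 2,
                   dimnames = list(GROUP_LEVELS, c("correct", "incorrect")))
  for (g in GROUP_LEVELS) {
    sel <- responses$group == g
    counts[g, "correct"] <- sum(sel & correct)
    counts[g, "incorrect"] <- sum(sel & !correct)
  }
  contingency_table(counts)
}

#' @rdname build_contingency
#' @param counts 2x2 nonnegative integer matrix (rows = groups,
#'   columns = correct/incorrect).
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(GROUP_LEVELS, c("correct", "incorrect"))
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> responses by group\n")
  print(unclass(x))
  invisible(x)
}

#' Per-group accuracy percentages
#'
#' `100 * correct / (correct + incorrect)` per group, reported to one
#' decimal place.
#'
#' @param table a [contingency_table()] with positive row sums.
#' @return named numeric vector of percentages.
#' @export
accuracy <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  totals <- rowSums(table)
  if (any(totals == 0)) stop("a group has no responses", call. = FALSE)
  round(100 * table[, "correct"] / totals, 1)
}

#' Chi-square test of association between group and correctness
#'
#' Pearson chi-square on the 2x2 table, 1 degree of freedom, *without*
#' Yates continuity correction (the uncorrected statistic is the convention
#' adopted here and is what per-response cohort counts of this size call
#' for).
#'
#' @param table a [contingency_table()] with positive margins.
#' @return list with `statistic` and `p`.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ht <- stats::chisq.test(unclass(table), correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Load per-stimulus accuracy counts and sum them into a contingency table
#'
#' Reads a TSV of per-stimulus correct/incorrect counts per group (such as
#' the bundled `study_accuracy_counts.tsv`, the published cohort counts of
#' the motivating eye-tracking study) and sums the 16 rows into the 2x2
#' group x correctness table used by [accuracy()] and [chi_square()].
#'
#' @param path TSV with columns `clinician_correct`, `clinician_incorrect`,
#'   `nonclinician_correct`, `nonclinician_incorrect`; defaults to the
#'   bundled study counts.
#' @return a [contingency_table()].
#' @examples
#' tab <- summarize_accuracy_counts()
#' accuracy(tab)
#' @export
summarize_accuracy_counts <- function(path = system.file(
  "extdata", "study_accuracy_counts.tsv", package = "gazecompare")) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  required <- c("clinician_correct", "clinician_incorrect",
                "nonclinician_correct", "nonclinician_incorrect")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("counts table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contingency_table(matrix(
    c(sum(df$clinician_correct), sum(df$clinician_incorrect),
      sum(df$nonclinician_correct), sum(df$nonclinician_incorrect)),
    nrow = 2, byrow = TRUE))
}

#' AOI fixation timing metrics
#'
#' For each area of interest: total duration of fixations whose centre lies
#' inside (or on the boundary of) the AOI polygon, and the onset of the
#' first such fixation (`NA` when the AOI was never fixated).
#'
#' @param seq a [fixation_sequence()].
#' @param aois an [aoi_set()] for the same stimulus.
#' @return data frame with one row per AOI: `stimulus_id`, `aoi_name`,
#'   `participant_id`, `duration_of_fixation_ms`,
#'   `time_to_first_whole_fixation_ms`.
#' @export
aoi_metrics <- function(seq, aois) {
  stopifnot(inherits(seq, "fixation_sequence"), inherits(aois, "aoi_set"))
  if (seq$stimulus_id != aois$stimulus_id) {
    stop("stimulus mismatch: sequence is for '", seq$stimulus_id,
         "', AOIs for '", aois$stimulus_id, "'", call. = FALSE)
  }
  fx <- seq$fixations
  rows <- lapply(names(aois$aois), function(nm) {
    inside <- if (nrow(fx)) {
      point_in_polygon(fx$x_px, fx$y_px, aois$aois[[nm]])
    } else {
      logical(0)
    }
    data.frame(
      stimulus_id = seq$stimulus_id,
      aoi_name = nm,
      participant_id = seq$participant_id,
      duration_of_fixation_ms = sum(fx$duration_ms[inside]),
      time_to_first_whole_fixation_ms =
        if (any(inside)) min(fx$onset_ms[inside]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
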
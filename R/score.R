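#' Qualitative localization call for one cell
#'
#' Three-way score of chromosome association: `positive` when the CER
#' exceeds the threshold, `absent` otherwise, and `cannot_call` when the
#' cell is not scoreable — the metaphase plate is not well-defined (a DIC
#' judgment supplied as a flag) or the reporter is over/under-expressed
#' (QC window failure). The default threshold 1.6 is the lower end of the
#' published 1.6-1.7 band that separates positive from absent cohorts; the
#' boundary is strict (`cer > threshold`), so a CER of exactly 1.6 scores
#' absent.
#'
#' @param m A [quantify_cell()] measurement.
#' @param plate_defined Logical: was the metaphase plate well-defined?
#' @param cer_threshold Positivity threshold (default 1.6).
#' @return List with `call` (one of `"positive"`, `"absent"`,
#'   `"cannot_call"`) and `reason` (non-empty for cannot-call).
#' @export
classify_cell <- function(m, plate_defined = TRUE, cer_threshold = 1.6) {
  stopifnot(inherits(m, "cer_measurement"))
  if (!isTRUE(plate_defined)) {
    return(list(call = "cannot_call", reason = "ill-defined metaphase plate"))
  }
  if (!isTRUE(m$qc_pass)) {
    reason <- if (m$cell_mean > m$qc_range[2]) "overexpression" else "underexpression"
    return(list(call = "cannot_call", reason = reason))
  }
  list(call = if (m$cer > cer_threshold) "positive" else "absent", reason = "")
}

#' Box-and-whisker summary statistics
#'
#' Quartiles are Tukey hinges (median-of-halves, as computed by
#' [stats::fivenum()]); whiskers are the full range, matching the published
#' plot convention (box = 2nd and 3rd quartiles, line = median, whiskers =
#' range, diamond = mean).
#'
#' @param x Numeric vector (length >= 1).
#' @return List of class `box_stats`: `mean`, `median`, `q1`, `q3`, `min`,
#'   `max`, `n`.
#' @export
box_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  fn <- fivenum(x)
  structure(list(mean = mean(x), median = fn[3], q1 = fn[2], q3 = fn[4],
                 min = fn[1], max = fn[5], n = length(x)),
            class = "box_stats")
}

#' Summarize a construct cohort: call counts and CER distribution
#'
#' Applies [classify_cell()] to each cell and aggregates. The quantitative
#' CER distribution covers only cells eligible for the quantitative assay:
#' QC-passing AND with a well-defined metaphase plate (both conditions were
#' required of published measurements). A warning is raised when fewer than
#' 8 eligible cells remain, the published minimum cohort size.
#'
#' @param measurements List of [quantify_cell()] results.
#' @param plate_defined Logical vector (recycled if length 1).
#' @param construct Construct label.
#' @param cer_threshold Positivity threshold passed to [classify_cell()].
#' @return Object of class `cohort_summary`: counts (`n_total`,
#'   `n_positive`, `n_absent`, `n_cannot_call`), `calls`, `reasons`,
#'   `cer_values` (eligible cells), and `box` ([box_stats()] or `NULL` when
#'   no cell is eligible).
#' @export
summarize_cohort <- function(measurements, plate_defined = TRUE,
                             construct = "construct", cer_threshold = 1.6) {
  n <- length(measurements)
  if (n < 1L) stop("empty cohort")
  plate_defined <- rep_len(as.logical(plate_defined), n)
  calls <- character(n); reasons <- character(n)
  for (i in seq_len(n)) {
    cl <- classify_cell(measurements[[i]], plate_defined[i], cer_threshold)
    calls[i] <- cl$call; reasons[i] <- cl$reason
  }
  eligible <- vapply(measurements, function(m) isTRUE(m$qc_pass), logical(1)) &
    plate_defined
  cers <- vapply(measurements[eligible], `[[`, numeric(1), "cer")
  if (sum(eligible) < 8L) {
    warning(sprintf("cohort '%s': only %d QC-passing cells with a defined plate (published minimum is 8)",
                    construct, sum(eligible)))
  }
  structure(
    list(construct = construct,
         n_total = n,
         n_positive = sum(calls == "positive"),
         n_absent = sum(calls == "absent"),
         n_cannot_call = sum(calls == "cannot_call"),
         calls = calls,
         reasons = reasons,
         cer_values = cers,
         cer_threshold = cer_threshold,
         box = if (length(cers)) box_stats(cers) else NULL),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort '%s': %d cells (%d positive / %d absent / %d cannot-call)\n",
              x$construct, x$n_total, x$n_positive, x$n_absent, x$n_cannot_call))
  if (!is.null(x$box)) {
    cat(sprintf("  CER (n=%d eligible): mean %.3f, median %.3f, IQR [%.3f, %.3f], range [%.3f, %.3f]\n",
                x$box$n, x$box$mean, x$box$median, x$box$q1, x$box$q3,
                x$box$min, x$box$max))
  }
  invisible(x)
}
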
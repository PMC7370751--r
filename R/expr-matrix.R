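#' Expression matrix container
#'
#' A light container for a log2-scaled gene x time-point expression matrix
#' together with the normalization constants used to build it. Rows are genes,
#' columns hourly (or otherwise strictly increasing) time points in hours
#' after plating.
#'
#' @param values numeric matrix, genes in rows, time points in columns. All
#'   values must be finite.
#' @param times numeric vector of time points (hours), strictly increasing,
#'   one per column.
#' @param pseudocount count offset added before log2 transformation
#'   (default 8).
#' @param scale normalization constant the counts were scaled to (typically
#'   the mean library size); `NA` when unknown, e.g. for already-transformed
#'   data.
#'
#' @return An object of class `expr_matrix`: the value matrix with `times`,
#'   `pseudocount` and `scale` attributes and time-labelled columns.
#' @export
expr_matrix <- function(values, times, pseudocount = 8, scale = NA_real_) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) != ncol(values))
    stop("`times` must have one entry per column of `values`")
  if (any(!is.finite(values)))
    stop("all expression values must be finite")
  if (any(diff(times) <= 0))
    stop("`times` must be unique and strictly increasing")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- as.character(times)
  structure(values,
            times = times,
            pseudocount = pseudocount,
            scale = scale,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  tms <- em_times(x)
  cat(sprintf("expr_matrix: %d genes x %d time points (%.4g-%.4g h)\n",
              nrow(x), ncol(x), min(tms), max(tms)))
  cat(sprintf("  pseudocount %s, scale %s\n",
              format(attr(x, "pseudocount")), format(attr(x, "scale"))))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  m <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  expr_matrix(out, as.numeric(colnames(out)),
              attr(x, "pseudocount"), attr(x, "scale"))
}

#' Time points of an expression matrix
#' @param x an `expr_matrix`.
#' @return numeric vector of column time points in hours.
#' @export
em_times <- function(x) attr(x, "times")

# subset columns of an expr_matrix by a closed time interval [from, to]
em_window <- function(x, from, to) {
  tms <- em_times(x)
  keep <- tms >= from & tms <= to
  if (!any(keep)) stop(sprintf("no time points inside [%g, %g]", from, to))
  expr_matrix(unclass(x)[, keep, drop = FALSE], tms[keep],
              attr(x, "pseudocount"), attr(x, "scale"))
}

#' Time-course cycle metadata
#'
#' Describes how a larval time course is partitioned into oscillation cycles
#' C1-C4 and which window and fixed periods the classification and per-cycle
#' fits use. Defaults follow the empirically determined larval cycle
#' boundaries: C1-C4 start at 6, 14, 20 and 27 h and oscillations cease at
#' 36 h; genes are classified on the 10-25 h window with a fixed 7-h period;
#' per-cycle amplitude fits use 7 h for C2/C3 and 8.5 h for C4.
#'
#' @param cycle_starts start times (h) of cycles C1-C4, strictly increasing.
#' @param end end (h) of the last cycle.
#' @param fit_window classification window (h), length-2 closed interval.
#' @param fixed_periods named periods (h) used for per-cycle fits.
#' @param classify_period fixed period (h) for gene classification.
#'
#' @return A list of class `timecourse_meta`.
#' @export
timecourse_meta <- function(cycle_starts = c(6, 14, 20, 27), end = 36,
                            fit_window = c(10, 25),
                            fixed_periods = c(C2 = 7, C3 = 7, C4 = 8.5),
                            classify_period = 7) {
  if (any(diff(c(cycle_starts, end)) <= 0))
    stop("`cycle_starts` and `end` must be strictly increasing")
  if (length(fit_window) != 2 || fit_window[1] >= fit_window[2])
    stop("`fit_window` must be an increasing length-2 interval")
  structure(list(cycle_starts = cycle_starts, end = end,
                 fit_window = fit_window, fixed_periods = fixed_periods,
                 classify_period = classify_period),
            class = "timecourse_meta")
}

# closed [start, next_start) windows for C1..C3 and [start, end] for C4,
# returned as a named list of c(from, to) usable with em_window (the shared
# boundary column belongs to the earlier cycle's fit in the paper's usage,
# so windows here are inclusive of both ends as closed label intervals)
cycle_windows <- function(meta) {
  bounds <- c(meta$cycle_starts, meta$end)
  out <- lapply(seq_len(length(bounds) - 1L),
                function(i) c(bounds[i], bounds[i + 1L]))
  names(out) <- paste0("C", seq_along(out))
  out
}
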
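#' Pearson correlation between time-point columns
#'
#' Correlates every column (time point) of `mat_a` with every column of
#' `mat_b` over the shared genes. Following the uncentered-data convention,
#' per-gene mean centering across time is off by default (each Pearson
#' coefficient still subtracts the column means by definition); turn
#' `mean_center_genes` on to reproduce the antiphase-negative-correlation
#' behaviour of mean-centered data.
#'
#' @param mat_a an [expr_matrix()].
#' @param mat_b an [expr_matrix()] sharing genes with `mat_a`; defaults to
#'   `mat_a` (autocorrelation matrix).
#' @param mean_center_genes subtract each gene's temporal mean before
#'   correlating (default FALSE).
#'
#' @return Matrix of Pearson coefficients, rows = time points of `mat_a`,
#'   columns = time points of `mat_b`.
#' @export
correlation_matrix <- function(mat_a, mat_b = mat_a,
                               mean_center_genes = FALSE) {
  genes <- intersect(rownames(mat_a), rownames(mat_b))
  if (length(genes) < 3) stop("fewer than 3 shared genes")
  A <- unclass(mat_a)[genes, , drop = FALSE]
  B <- unclass(mat_b)[genes, , drop = FALSE]
  if (mean_center_genes) {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
  }
  stats::cor(A, B, method = "pearson")
}

#' Peaks of a correlation line by spline analysis
#'
#' A correlation line is the vector of correlations of one reference time
#' point against a time course. Peaks are located inside an analysis window
#' either from the derivative roots of a cubic interpolating spline
#' (`method = "derivative"`) or, matching the embryo-course analysis, with
#' `pracma::findpeaks(nups = 5, ndowns = 5)` on a dense spline interpolation
#' (`method = "findpeaks"`, default `dense_n = 240`). Peaks whose value does
#' not exceed the mean of the correlation line inside the window are
#' discarded.
#'
#' @param line numeric correlation coefficients.
#' @param times time points (h) of `line`.
#' @param window length-2 closed analysis window (default `c(7, 36)`).
#' @param method `"derivative"` or `"findpeaks"`.
#' @param dense_n dense interpolation grid size (default 240).
#'
#' @return Data frame with `time` and `value`, sorted by time (possibly
#'   zero rows).
#' @export
correlation_line_peaks <- function(line, times, window = c(7, 36),
                                   method = c("derivative", "findpeaks"),
                                   dense_n = 240) {
  method <- match.arg(method)
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 4) stop("window holds fewer than 4 points")
  x <- times[keep]; y <- line[keep]
  line_mean <- mean(y)
  if (method == "derivative") {
    sf <- stats::splinefun(x, y, method = "fmm")
    roots <- spline_derivative_roots(sf, range(x), max(dense_n, 512))
    vals <- sf(roots)
    is_max <- vapply(roots, function(r) sf(r, deriv = 2) < 0, logical(1))
    pk_t <- roots[is_max]; pk_v <- vals[is_max]
  } else {
    sp <- stats::spline(x, y, n = dense_n, method = "fmm")
    pk <- pracma::findpeaks(sp$y, nups = 5, ndowns = 5)
    if (is.null(pk)) pk_t <- pk_v <- numeric(0)
    else { pk_t <- sp$x[pk[, 2]]; pk_v <- pk[, 1] }
  }
  keep_pk <- pk_v > line_mean
  out <- data.frame(time = pk_t[keep_pk], value = pk_v[keep_pk])
  out[order(out$time), , drop = FALSE]
}

#' Cycle-phase map
#'
#' Maps time within each oscillation cycle linearly to degrees: the cycle
#' start is 0 degrees and the next cycle start 360 degrees, so with the
#' default larval boundaries TP14 (start of C2) is 0 degrees and TP19, the
#' last unique C2 time point, is 300 degrees.
#'
#' @param cycle_starts cycle start times (h) including the end of the last
#'   cycle as final element (default `c(6, 14, 20, 27, 36)`).
#'
#' @return A list of class `cycle_phase_map`.
#' @export
cycle_phase_map <- function(cycle_starts = c(6, 14, 20, 27, 36)) {
  if (any(diff(cycle_starts) <= 0)) stop("cycle starts must be increasing")
  structure(list(cycle_starts = cycle_starts), class = "cycle_phase_map")
}

#' Convert a time point to its phase within the oscillation cycle
#'
#' @param time time (h), inside a mapped cycle.
#' @param map a [cycle_phase_map()].
#'
#' @return Phase in degrees, [0, 360). Vectorized over `time`.
#' @export
assign_cycle_phase <- function(time, map = cycle_phase_map()) {
  cs <- map$cycle_starts
  vapply(time, function(tt) {
    if (tt < cs[1] || tt > cs[length(cs)])
      stop(sprintf("time %g lies outside all mapped cycles", tt))
    i <- findInterval(tt, cs, rightmost.closed = TRUE)
    if (i == length(cs)) i <- i - 1L  # the final boundary maps to 360 ~ 0
    360 * (tt - cs[i]) / (cs[i + 1] - cs[i])
  }, numeric(1)) %% 360
}

#' Invert a cycle-phase map within one cycle
#'
#' @param phase_deg phase in degrees, [0, 360).
#' @param cycle index of the cycle (1-based).
#' @param map a [cycle_phase_map()].
#'
#' @return Time (h) within the requested cycle.
#' @export
cycle_phase_to_time <- function(phase_deg, cycle, map = cycle_phase_map()) {
  cs <- map$cycle_starts
  if (cycle < 1 || cycle > length(cs) - 1) stop("no such cycle")
  cs[cycle] + (phase_deg %% 360) / 360 * (cs[cycle + 1] - cs[cycle])
}

#' Arrest-phase estimation from quiescent time points
#'
#' For each quiescent (non-oscillating) time point, the correlation line
#' against the oscillatory window is computed and its spline peaks are
#' mapped to cycle phase; the circular median of all peak phases is the
#' arrested-phase estimate. Mutual correlations among the quiescent columns
#' are reported as supporting evidence (high values indicate a common frozen
#' state).
#'
#' @param mat an [expr_matrix()] (oscillating genes).
#' @param quiescent_times time points (h) presumed arrested, present in
#'   `mat`.
#' @param map a [cycle_phase_map()] covering the oscillatory window.
#' @param window oscillatory analysis window (default the map's span).
#'
#' @return A list with `found`, `arrest_phase_deg`, `peaks` (data frame:
#'   query_time, peak_time, value, phase_deg) and `quiescent_correlations`
#'   (matrix).
#' @export
arrest_phase <- function(mat, quiescent_times, map = cycle_phase_map(),
                         window = NULL) {
  tms <- em_times(mat)
  if (!all(quiescent_times %in% tms))
    stop("all quiescent times must be sampled in `mat`")
  if (is.null(window)) window <- range(map$cycle_starts)
  cm <- correlation_matrix(mat, mat)
  peaks <- do.call(rbind, lapply(quiescent_times, function(q) {
    line <- cm[as.character(q), ]
    pk <- correlation_line_peaks(line, tms, window = window)
    if (nrow(pk) == 0) return(NULL)
    data.frame(query_time = q, peak_time = pk$time, value = pk$value,
               phase_deg = assign_cycle_phase(pk$time, map))
  }))
  qidx <- as.character(quiescent_times)
  qq <- cm[qidx, qidx, drop = FALSE]
  if (is.null(peaks) || nrow(peaks) == 0)
    return(list(found = FALSE, arrest_phase_deg = NA_real_,
                peaks = data.frame(), quiescent_correlations = qq))
  list(found = TRUE,
       arrest_phase_deg = circular_median_deg(peaks$phase_deg),
       peaks = peaks, quiescent_correlations = qq)
}

#' Two-regime breakpoint of the embryonic onset of oscillations
#'
#' Fits ordinary least-squares lines to the early (static) and late
#' (phase-progressing) regimes of larval-cycle peak position over embryonic
#' time and intersects them: `x* = (b1 - b2) / (a2 - a1)`. The 95% CI of
#' `x*` comes from first-order propagation of the four coefficient standard
#' errors through that expression.
#'
#' @param peak_times data frame with columns `embryo_time` (min) and
#'   `larval_peak` (h).
#' @param early_range,late_range length-2 closed intervals (min) selecting
#'   the two regimes (defaults `c(10, 230)` and `c(450, 830)`).
#' @param conf confidence level (default 0.95).
#'
#' @return A list of class `breakpoint_fit`: `a1`, `b1`, `a2`, `b2` with
#'   standard errors, `x_star`, `se`, `ci` and the two `lm` fits.
#' @export
embryo_onset_breakpoint <- function(peak_times, early_range = c(10, 230),
                                    late_range = c(450, 830), conf = 0.95) {
  sel <- function(rng) {
    d <- peak_times[peak_times$embryo_time >= rng[1] &
                    peak_times$embryo_time <= rng[2], , drop = FALSE]
    if (nrow(d) < 3) stop("fewer than 3 points in a regime window")
    stats::lm(larval_peak ~ embryo_time, data = d)
  }
  fit1 <- sel(early_range); fit2 <- sel(late_range)
  s1 <- summary(fit1)$coefficients; s2 <- summary(fit2)$coefficients
  breakpoint_intersection(a1 = s1[2, 1], b1 = s1[1, 1],
                          a2 = s2[2, 1], b2 = s2[1, 1],
                          se_a1 = s1[2, 2], se_b1 = s1[1, 2],
                          se_a2 = s2[2, 2], se_b2 = s2[1, 2],
                          conf = conf, fits = list(fit1, fit2))
}

#' Intersection of two lines with propagated uncertainty
#'
#' `x* = (b1 - b2) / (a2 - a1)`; the standard error is the first-order
#' Taylor propagation of the (independent) coefficient standard errors.
#'
#' @param a1,b1 slope and intercept of the first line.
#' @param a2,b2 slope and intercept of the second line.
#' @param se_a1,se_b1,se_a2,se_b2 standard errors (default 0).
#' @param conf confidence level for the normal-quantile interval.
#' @param fits optional underlying `lm` fits, stored unchanged.
#'
#' @return A list of class `breakpoint_fit`.
#' @export
breakpoint_intersection <- function(a1, b1, a2, b2, se_a1 = 0, se_b1 = 0,
                                    se_a2 = 0, se_b2 = 0, conf = 0.95,
                                    fits = NULL) {
  da <- a2 - a1
  if (da == 0) stop("parallel regimes: intersection undefined")
  x_star <- (b1 - b2) / da
  # gradient of (b1-b2)/(a2-a1) wrt (b1, b2, a1, a2)
  g_b1 <- 1 / da; g_b2 <- -1 / da
  g_a1 <- x_star / da; g_a2 <- -x_star / da
  se <- sqrt(g_b1^2 * se_b1^2 + g_b2^2 * se_b2^2 +
             g_a1^2 * se_a1^2 + g_a2^2 * se_a2^2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 se_a1 = se_a1, se_b1 = se_b1, se_a2 = se_a2, se_b2 = se_b2,
                 x_star = x_star, se = se,
                 ci = c(lower = x_star - z * se, upper = x_star + z * se),
                 conf = conf, fits = fits),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("two-regime breakpoint: x* = %.4g (%.0f%% CI %.4g-%.4g)\n",
              x$x_star, 100 * x$conf, x$ci[1], x$ci[2]))
  cat(sprintf("  regime 1: y = %.4g x + %.4g;  regime 2: y = %.4g x + %.4g\n",
              x$a1, x$b1, x$a2, x$b2))
  invisible(x)
}
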
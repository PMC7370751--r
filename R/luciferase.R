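#' Detect hatch in a raw luciferase luminescence trace
#'
#' Hatch is the first bin, starting from bin 4 to avoid edge effects, whose
#' raw luminescence exceeds the mean plus 5 standard deviations of the first
#' 20 bins.
#'
#' @param raw raw luminescence values (10-min bins).
#' @param baseline_bins number of leading bins defining the baseline
#'   (default 20).
#' @param start_bin first bin considered (default 4).
#' @param k threshold in baseline standard deviations (default 5).
#'
#' @return A list with `found` and `index` (NA when no bin crosses the
#'   threshold).
#' @export
detect_hatch <- function(raw, baseline_bins = 20, start_bin = 4, k = 5) {
  if (length(raw) < baseline_bins + 4) stop("trace too short")
  thr <- mean(raw[1:baseline_bins]) + k * stats::sd(raw[1:baseline_bins])
  idx <- which(raw > thr)
  idx <- idx[idx >= start_bin]
  if (length(idx) == 0) return(list(found = FALSE, index = NA_integer_))
  list(found = TRUE, index = idx[1], threshold = thr)
}

#' Trend-correct a luminescence trace
#'
#' Divides the raw trace by a running-median baseline and takes log2, so
#' slow trends (growth, substrate decay) are removed while the abrupt molt
#' troughs survive as negative excursions. A constant trace maps to zero.
#' The baseline window must be comfortably longer than a molt (default 37
#' bins = ~6 h at 10-min binning).
#'
#' @param raw raw luminescence (positive).
#' @param window odd running-median window in bins (default 37).
#'
#' @return Numeric trace of log2 ratios to baseline.
#' @export
trend_correct <- function(raw, window = 37) {
  n <- length(raw)
  if (window %% 2 == 0) stop("window must be odd")
  if (window >= n) stop("window must be shorter than the trace")
  baseline <- as.numeric(stats::runmed(raw, window, endrule = "median"))
  baseline <- pmax(baseline, .Machine$double.eps)
  log2(pmax(raw, .Machine$double.eps) / baseline)
}

#' Detect molts as low-luminescence runs
#'
#' After hatch, bins whose trend-corrected luminescence falls below a
#' threshold are grouped into runs; runs separated by at most `merge_gap`
#' bins are merged, and runs shorter than `min_duration` bins are dropped.
#' The default threshold is absolute: corrected luminescence below -1 log2
#' units, i.e. a more than 2-fold drop below the running baseline, which
#' molt troughs (several-fold drops while feeding and luciferin uptake
#' stop) clear easily while noise does not, independent of how much of the
#' trace the molts occupy. Alternatively a quantile of the post-hatch
#' corrected signal can be used via `threshold_q`.
#'
#' @param corrected trend-corrected trace from [trend_correct()].
#' @param hatch hatch bin index from [detect_hatch()].
#' @param threshold absolute log2 threshold (default -1).
#' @param min_duration minimum run length in bins (default 3, i.e. 30 min).
#' @param merge_gap maximum above-threshold gap (bins) merged into one molt
#'   (default 2, i.e. 20 min).
#' @param threshold_q optional quantile of the post-hatch corrected signal;
#'   when given it overrides `threshold`.
#'
#' @return Data frame with columns `entry`, `exit` (bin indices), possibly
#'   zero rows.
#' @export
detect_molts <- function(corrected, hatch, threshold = -1,
                         min_duration = 3, merge_gap = 2,
                         threshold_q = NULL) {
  if (min_duration <= 0 || merge_gap < 0) stop("parameters must be positive")
  n <- length(corrected)
  post <- corrected[hatch:n]
  thr <- if (is.null(threshold_q)) threshold
         else stats::quantile(post, threshold_q, names = FALSE)
  low <- which(post < thr) + hatch - 1L
  if (length(low) == 0) return(data.frame(entry = integer(0), exit = integer(0)))
  # group into runs, merging gaps <= merge_gap
  brk <- which(diff(low) > merge_gap + 1L)
  starts <- low[c(1L, brk + 1L)]
  ends <- low[c(brk, length(low))]
  keep <- (ends - starts + 1L) >= min_duration
  data.frame(entry = starts[keep], exit = ends[keep])
}

#' Molt, intermolt and larval-stage durations
#'
#' Molt duration is molt exit minus molt entry. A larval stage runs from the
#' previous molt exit (or hatch for L1) to the current molt exit, and the
#' intermolt is the stage minus its molt, so stage = molt + intermolt holds
#' identically.
#'
#' @param hatch hatch time (same units as the molt times).
#' @param molts data frame with `entry` and `exit`, ordered.
#' @param bin_h duration of one bin in hours (default `1/6`); set to 1 when
#'   `hatch`/`molts` are already in hours.
#'
#' @return Data frame: stage, molt, intermolt, stage_duration (hours).
#' @export
stage_durations <- function(hatch, molts, bin_h = 1 / 6) {
  if (nrow(molts) < 1) stop("at least one molt is required")
  if (any(molts$exit <= molts$entry)) stop("molt exit must follow entry")
  if (any(diff(as.vector(t(molts[, c("entry", "exit")]))) < 0))
    stop("overlapping molt intervals")
  prev_exit <- c(hatch, molts$exit[-nrow(molts)])
  molt_d <- (molts$exit - molts$entry) * bin_h
  stage_d <- (molts$exit - prev_exit) * bin_h
  data.frame(stage = paste0("L", seq_len(nrow(molts))),
             molt = molt_d, intermolt = stage_d - molt_d,
             stage_duration = stage_d)
}

#' Welch two-sample two-sided t-test on duration samples
#'
#' @param sample_a,sample_b numeric duration samples (each length >= 2).
#'
#' @return A list with `statistic`, `df`, `p_value`. Two degenerate samples
#'   with equal means give p = 1 by convention.
#' @export
compare_durations <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 values")
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    return(list(statistic = Inf, df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Full luciferase molt-timing analysis of one animal
#'
#' Runs hatch detection, trend correction, molt detection and stage-duration
#' quantification on one raw trace.
#'
#' @param raw raw luminescence (10-min bins).
#' @param bin_h bin width in hours (default `1/6`).
#' @param trend_window running-median window (bins) for [trend_correct()].
#' @param threshold,min_duration,merge_gap molt-call parameters, see
#'   [detect_molts()].
#'
#' @return A list with `hatch`, `molts` (bin indices), `durations` (hours)
#'   and the corrected trace; `found = FALSE` when no hatch was detected.
#' @export
analyze_luminescence <- function(raw, bin_h = 1 / 6, trend_window = 37,
                                 threshold = -1, min_duration = 3,
                                 merge_gap = 2) {
  h <- detect_hatch(raw)
  if (!h$found)
    return(list(found = FALSE, hatch = NA_integer_,
                molts = data.frame(), durations = data.frame()))
  corrected <- trend_correct(raw, trend_window)
  molts <- detect_molts(corrected, h$index, threshold, min_duration,
                        merge_gap)
  durations <- if (nrow(molts) > 0)
    stage_durations(h$index, molts, bin_h) else data.frame()
  list(found = TRUE, hatch = h$index, molts = molts, durations = durations,
       corrected = corrected)
}
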
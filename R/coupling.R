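#' Single-worm reporter trace with molt annotations
#'
#' @param times frame times in hours since hatch, equally spaced (10-min
#'   frames by default).
#' @param intensity background-subtracted reporter intensity; `NA` frames
#'   (animal not identified) are linearly interpolated before analysis.
#' @param molts data frame with columns `stage`, `entry`, `exit` (h),
#'   ordered and non-overlapping.
#' @param worm_id identifier.
#'
#' @return A list of class `worm_trace`.
#' @export
worm_trace <- function(times, intensity, molts, worm_id = "worm") {
  if (length(times) != length(intensity)) stop("times/intensity mismatch")
  if (nrow(molts) > 0) {
    if (any(molts$exit <= molts$entry)) stop("molt exit must follow entry")
    if (any(diff(as.vector(t(molts[, c("entry", "exit")]))) < 0))
      stop("molt intervals must be ordered and non-overlapping")
    if (min(molts$entry) < min(times) || max(molts$exit) > max(times))
      stop("molt annotations outside trace span")
  }
  structure(list(worm_id = worm_id, times = times, intensity = intensity,
                 molts = molts), class = "worm_trace")
}

# fill NA frames by linear interpolation (gap limit in hours)
interpolate_gaps <- function(x, times, limit_h = 10) {
  if (!anyNA(x)) return(x)
  filled <- stats::approx(times[!is.na(x)], x[!is.na(x)], xout = times,
                          rule = 2)$y
  # respect the gap limit: leave runs longer than limit_h unfilled
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && (times[ends[i]] - times[starts[i]]) > limit_h)
      filled[starts[i]:ends[i]] <- NA
  }
  filled
}

#' Oscillation phase at molt entry and exit
#'
#' Band-pass filters each worm's reporter trace (default band 1/14-1/5
#' cycles/h for 10-min frames), extracts the Hilbert instantaneous phase and
#' reads it out (wrapped and unwrapped) at each annotated molt entry and
#' exit frame. Molts falling outside the retained phase range are flagged
#' and skipped.
#'
#' @param worms list of [worm_trace()] objects.
#' @param spec a [bandpass_spec()]; default band `1/14`-`1/5` cycles/h.
#' @param trim_start,trim_end edge trims in samples (defaults 4 and 3).
#'
#' @return Data frame: worm_id, stage, event ("entry"/"exit"), time,
#'   phase (wrapped, rad), unwrapped (rad).
#' @export
molt_phases <- function(worms, spec = bandpass_spec(low = 1 / 14, high = 1 / 5),
                        trim_start = 4, trim_end = 3) {
  out <- lapply(worms, function(w) {
    dt <- stats::median(diff(w$times))
    sr <- 1 / dt
    y <- interpolate_gaps(w$intensity, w$times)
    if (anyNA(y)) {
      warning(sprintf("%s: unfillable gap, skipped", w$worm_id))
      return(NULL)
    }
    f <- bandpass_filter(y - mean(y), spec, sample_rate = sr)
    pt <- instantaneous_phase(f, times = w$times, sample_rate = sr,
                              trim_start = trim_start, trim_end = trim_end)
    ok_rng <- range(w$times[pt$retained])
    rows <- list()
    for (i in seq_len(nrow(w$molts))) {
      for (ev in c("entry", "exit")) {
        tt <- w$molts[[ev]][i]
        if (tt < ok_rng[1] || tt > ok_rng[2]) next  # outside retained range
        j <- which.min(abs(w$times - tt))
        rows[[length(rows) + 1L]] <- data.frame(
          worm_id = w$worm_id, stage = w$molts$stage[i], event = ev,
          time = tt, phase = pt$phase[j], unwrapped = pt$unwrapped[j])
      }
    }
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Expected phase dispersion under independent periods and durations
#'
#' If the molt-defining duration T (intermolt for molt entry, larval stage
#' for molt exit) and the oscillation period T_o vary independently, the
#' phase `theta = 2*pi*T/T_o` has first-order standard deviation
#' \deqn{\sigma = 2\pi \frac{\mu_T}{\mu_o}
#'   \sqrt{(\sigma_T/\mu_T)^2 + (\sigma_o/\mu_o)^2}.}
#'
#' @param duration_stats `c(mean, sd)` of the duration (h).
#' @param period_stats `c(mean, sd)` of the oscillation period (h).
#'
#' @return Expected phase standard deviation (rad).
#' @export
expected_phase_sd <- function(duration_stats, period_stats) {
  mu_t <- duration_stats[1]; sd_t <- duration_stats[2]
  mu_o <- period_stats[1]; sd_o <- period_stats[2]
  if (mu_t <= 0 || mu_o <= 0) stop("means must be positive")
  2 * pi * (mu_t / mu_o) * sqrt((sd_t / mu_t)^2 + (sd_o / mu_o)^2)
}

#' Coupling ratio sd_obs / sd_exp
#'
#' Ratio of the sample standard deviation of observed molt phases
#' (unwrapped, within one stage) to the error-propagated expected standard
#' deviation. Values near 1 indicate independent processes; values below 1
#' indicate coupling.
#'
#' @param observed_phases phase samples (rad) for one stage and event.
#' @param sigma_expected expected sd (rad) from [expected_phase_sd()].
#'
#' @return A list with `ratio`, `sd_obs`, `sd_exp` and logical `infinite`
#'   (TRUE when `sigma_expected` is 0 with nonzero observed spread).
#' @export
coupling_ratio <- function(observed_phases, sigma_expected) {
  if (length(observed_phases) < 3) stop("need at least 3 phase samples")
  sd_obs <- stats::sd(observed_phases)
  if (sigma_expected == 0 && sd_obs > 0)
    return(list(ratio = Inf, sd_obs = sd_obs, sd_exp = 0, infinite = TRUE))
  list(ratio = sd_obs / sigma_expected, sd_obs = sd_obs,
       sd_exp = sigma_expected, infinite = FALSE)
}

#' Cohort coupling analysis for one stage
#'
#' Convenience wrapper: extracts molt phases, estimates the duration and
#' period statistics from the cohort itself, and returns the coupling ratio
#' for the requested stage and event. The per-worm oscillation period is
#' taken as the mean instantaneous period over the retained range; the
#' duration is intermolt (previous molt exit, or hatch for L1, to molt
#' entry) for `event = "entry"` and the full larval stage for
#' `event = "exit"`.
#'
#' @param worms list of [worm_trace()] objects.
#' @param stage stage label to analyse (e.g. `"L2"`).
#' @param event `"entry"` or `"exit"`.
#' @param spec a [bandpass_spec()].
#'
#' @return A list with the coupling ratio elements plus the duration and
#'   period statistics used.
#' @export
stage_coupling <- function(worms, stage = "L2", event = c("entry", "exit"),
                           spec = bandpass_spec(low = 1 / 14, high = 1 / 5)) {
  event <- match.arg(event)
  ph <- molt_phases(worms, spec)
  ev <- ph[ph$stage == stage & ph$event == event, , drop = FALSE]
  # observed phase is the unwrapped phase accumulated over the stage (from
  # the previous molt exit), the measured analogue of 2*pi*T/T_o
  stages <- unique(unlist(lapply(worms, function(w) w$molts$stage)))
  i_stage <- match(stage, stages)
  if (is.na(i_stage) || i_stage < 2)
    stop("stage must have a preceding molt exit (L2 or later)")
  prev <- ph[ph$stage == stages[i_stage - 1] & ph$event == "exit",
             c("worm_id", "unwrapped")]
  names(prev)[2] <- "unwrapped_prev"
  ev <- merge(ev, prev, by = "worm_id")
  ev$theta <- ev$unwrapped - ev$unwrapped_prev
  durs <- vapply(worms, function(w) {
    i <- match(stage, w$molts$stage)
    if (is.na(i)) return(NA_real_)
    start <- if (i == 1) min(w$times) else w$molts$exit[i - 1]
    if (event == "entry") w$molts$entry[i] - start else w$molts$exit[i] - start
  }, numeric(1))
  periods <- vapply(worms, function(w) {
    dt <- stats::median(diff(w$times))
    y <- interpolate_gaps(w$intensity, w$times)
    f <- bandpass_filter(y - mean(y), spec, sample_rate = 1 / dt)
    pt <- instantaneous_phase(f, times = w$times, sample_rate = 1 / dt)
    mean(pt$period[pt$retained])
  }, numeric(1))
  sd_exp <- expected_phase_sd(c(mean(durs, na.rm = TRUE),
                                stats::sd(durs, na.rm = TRUE)),
                              c(mean(periods), stats::sd(periods)))
  c(coupling_ratio(ev$theta, sd_exp),
    list(duration_stats = c(mean = mean(durs, na.rm = TRUE),
                            sd = stats::sd(durs, na.rm = TRUE)),
         period_stats = c(mean = mean(periods), sd = stats::sd(periods))))
}

#' Correlate time-to-phase with molt timing across a cohort
#'
#' For every worm, finds the first time its unwrapped oscillation phase
#' reaches `target_unwrapped_phase` (e.g. 11 rad for L2, 18 rad for L3) and
#' pairs it with the absolute time of a molt event; reports the Pearson
#' correlation and the least-squares slope through the origin with a 95% CI.
#'
#' @param worms list of [worm_trace()] objects.
#' @param target_unwrapped_phase target unwrapped phase (rad).
#' @param stage stage of the molt event.
#' @param event `"entry"` or `"exit"`.
#' @param spec a [bandpass_spec()].
#'
#' @return A list with `data` (worm_id, t_phase, t_molt), `r`, `slope`,
#'   `slope_ci` and `n`; worms never reaching the target phase are excluded
#'   with a warning.
#' @export
time_to_phase_vs_molt <- function(worms, target_unwrapped_phase,
                                  stage = "L2", event = c("entry", "exit"),
                                  spec = bandpass_spec(low = 1 / 14,
                                                       high = 1 / 5)) {
  event <- match.arg(event)
  rows <- lapply(worms, function(w) {
    dt <- stats::median(diff(w$times))
    y <- interpolate_gaps(w$intensity, w$times)
    f <- bandpass_filter(y - mean(y), spec, sample_rate = 1 / dt)
    pt <- instantaneous_phase(f, times = w$times, sample_rate = 1 / dt)
    rel <- pt$unwrapped - pt$unwrapped[pt$retained[1]]
    hit <- which(rel >= target_unwrapped_phase)
    i <- match(stage, w$molts$stage)
    if (length(hit) == 0 || is.na(i)) {
      warning(sprintf("%s: target phase or stage not reached, excluded",
                      w$worm_id))
      return(NULL)
    }
    data.frame(worm_id = w$worm_id, t_phase = w$times[hit[1]],
               t_molt = w$molts[[event]][i])
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 3) stop("fewer than 3 usable worms")
  fit <- stats::lm(t_molt ~ t_phase + 0, data = d)
  ci <- stats::confint(fit, level = 0.95)
  list(data = d, r = stats::cor(d$t_phase, d$t_molt),
       slope = unname(stats::coef(fit)[1]),
       slope_ci = c(lower = ci[1, 1], upper = ci[1, 2]), n = nrow(d))
}
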
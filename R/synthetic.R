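# Synthetic-data generators with known ground truth for every analysis
# stage.  Each generator is deterministic given its spec (which includes a
# seed); the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic larval population time course
#'
#' The defaults emulate the structure of a 48-h hourly log2 expression
#' course of a synchronized larval population: about a quarter of genes
#' oscillate with log2 amplitudes of at least 0.7 and uniformly distributed
#' peak phases; the common phase advances with a 7-h period from oscillation
#' onset (5 h) through cycle C3, lengthens to 8.5 h in C4 (from 27 h), and
#' freezes at the arrest phase (300 degrees of the cycle) before onset and
#' from ~34 h onward (so the adult plateau from 37 h is fully arrested);
#' a fraction of oscillating genes additionally shifts its mean level in C4
#' (L4-deviating genes); noise is additive Gaussian in log2 space.
#'
#' @param n_genes total genes (default 2000).
#' @param fraction_oscillating fraction oscillating (default 0.25).
#' @param amplitude_range log2 amplitude range, sampled uniformly
#'   (default `c(0.7, 2)`).
#' @param mean_range log2 mean expression range, sampled uniformly
#'   (default `c(6, 10)`).
#' @param times sampling times in hours (default `1:48`).
#' @param onset oscillation onset (default 5 h).
#' @param period_early,period_late periods before/after the C4 boundary
#'   (defaults 7 and 8.5 h).
#' @param c4_start start of the last cycle (default 27 h).
#' @param cycle_anchor time anchored to cycle phase 0 (default 6 h, the C1
#'   start).
#' @param arrest_phase_deg phase at which the oscillator arrests
#'   (default 300).
#' @param arrest_after latest allowed arrest time; the hold starts at the
#'   last crossing of the arrest phase before this (default 37 h).
#' @param trend_fraction fraction of oscillating genes given an L4 mean
#'   shift (default 0.1).
#' @param trend_shift log2 shift applied in C4 to trend genes (default 5).
#' @param noise_sd additive log2 noise sd (default 0.2).
#' @param seed RNG seed (default 1).
#'
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_genes = 2000, fraction_oscillating = 0.25,
                            amplitude_range = c(0.7, 2),
                            mean_range = c(6, 10), times = 1:48,
                            onset = 5, period_early = 7, period_late = 8.5,
                            c4_start = 27, cycle_anchor = 6,
                            arrest_phase_deg = 300, arrest_after = 37,
                            trend_fraction = 0.1, trend_shift = 5,
                            noise_sd = 0.2, seed = 1) {
  stopifnot(fraction_oscillating >= 0, fraction_oscillating <= 1,
            period_early > 0, period_late > 0)
  structure(as.list(environment()), class = "population_spec")
}

# unwrapped global phase (rad) of the population oscillator at times t,
# anchored so that cycle phase 0 falls at `cycle_anchor`; flat before onset
# and after the arrest hold time.  Returns list(phi, t_arrest, cycle_starts).
population_phase <- function(spec, t) {
  w1 <- 2 * pi / spec$period_early
  w2 <- 2 * pi / spec$period_late
  phi_of <- function(tt) {
    tt <- pmax(tt, spec$onset)
    ifelse(tt <= spec$c4_start,
           (tt - spec$cycle_anchor) * w1,
           (spec$c4_start - spec$cycle_anchor) * w1 +
             (tt - spec$c4_start) * w2)
  }
  # last crossing of the arrest phase at or before arrest_after
  target <- spec$arrest_phase_deg * pi / 180
  phi_end <- phi_of(spec$arrest_after)
  k <- floor((phi_end - target) / (2 * pi))
  phi_hold <- target + 2 * pi * k
  # invert phi_of for the hold time
  phi_c4 <- phi_of(spec$c4_start)
  t_arrest <- if (phi_hold <= phi_c4)
    spec$cycle_anchor + phi_hold / w1
  else spec$c4_start + (phi_hold - phi_c4) / w2
  phi <- phi_of(t)
  phi <- pmin(phi, phi_hold)
  # generative cycle boundaries (phase multiples of 2*pi) inside the course
  ks <- 0:floor(phi_hold / (2 * pi))
  cyc <- ifelse(2 * pi * ks <= phi_c4,
                spec$cycle_anchor + 2 * pi * ks / w1,
                spec$c4_start + (2 * pi * ks - phi_c4) / w2)
  list(phi = phi, t_arrest = t_arrest, cycle_starts = cyc,
       phi_hold = phi_hold)
}

#' Generate a synthetic larval population time course
#'
#' @param spec a [population_spec()].
#'
#' @return A list with `mat` (an [expr_matrix()]), `truth` (per-gene data
#'   frame: gene, oscillating, amplitude, peak_phase_deg, mean, trend),
#'   `t_arrest` (hold start, h), `cycle_starts` (generative cycle
#'   boundaries, h) and `spec`.
#' @export
make_population_timecourse <- function(spec = population_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_genes
    n_osc <- round(n * spec$fraction_oscillating)
    osc <- seq_len(n) <= n_osc  # first block oscillates; order is arbitrary
    amp <- ifelse(osc, stats::runif(n, spec$amplitude_range[1],
                                    spec$amplitude_range[2]), 0)
    peak <- ifelse(osc, stats::runif(n, 0, 360), NA_real_)
    mu <- stats::runif(n, spec$mean_range[1], spec$mean_range[2])
    trend <- osc & (stats::runif(n) < spec$trend_fraction)
    pp <- population_phase(spec, spec$times)
    peak_rad <- ifelse(osc, peak * pi / 180, 0)
    # [i, j] = cos(phi_j - peak_i), scaled per gene by its amplitude
    vals <- mu + amp * cos(outer(-peak_rad, pp$phi, "+"))
    if (any(trend)) {
      late <- spec$times >= spec$c4_start
      vals[trend, late] <- vals[trend, late] + spec$trend_shift
    }
    vals <- vals + matrix(stats::rnorm(n * length(spec$times), 0,
                                       spec$noise_sd), n)
    rownames(vals) <- sprintf("g%04d", seq_len(n))
    truth <- data.frame(gene = rownames(vals), oscillating = osc,
                        amplitude = amp, peak_phase_deg = peak,
                        mean = mu, trend = trend)
    list(mat = expr_matrix(vals, spec$times), truth = truth,
         t_arrest = pp$t_arrest, cycle_starts = pp$cycle_starts,
         spec = spec)
  })
}

#' Specification of a synthetic embryonic time course
#'
#' Emulates the two-regime embryonic expression of larval oscillating
#' genes: before the breakpoint the expression pattern approaches a fixed
#' oscillator-phase state with growing amplitude (correlation to one larval
#' time point grows, its position stays put); after the breakpoint the phase
#' advances so the best-correlating larval time point moves linearly. The
#' default regime lines are y = 5.312e-4 x + 13.98 (early) and
#' y = 0.0108 x + 10.07 (late), intersecting at ~380 min.
#'
#' @param times embryo sampling times in minutes (default `seq(10, 830,
#'   by = 20)`).
#' @param t_star breakpoint (default 380 min).
#' @param a1,b1 early-regime slope (larval h per embryonic min) and
#'   intercept (larval h).
#' @param a2,b2 late-regime slope and intercept.
#' @param n_genes number of oscillating genes (default 400).
#' @param amplitude_range,mean_range as in [population_spec()].
#' @param ramp_floor pre-breakpoint starting amplitude fraction
#'   (default 0.2).
#' @param noise_sd additive log2 noise sd (default 0.2).
#' @param larval_period larval oscillation period (default 7 h) used for the
#'   companion larval course.
#' @param seed RNG seed.
#'
#' @return A list of class `embryo_spec`.
#' @export
embryo_spec <- function(times = seq(10, 830, by = 20), t_star = 380,
                        a1 = 5.312e-4, b1 = 13.98, a2 = 0.0108, b2 = 10.07,
                        n_genes = 400, amplitude_range = c(0.7, 2),
                        mean_range = c(6, 10), ramp_floor = 0.2,
                        noise_sd = 0.2, larval_period = 7, seed = 1) {
  stopifnot(t_star > min(times), t_star < max(times))
  structure(as.list(environment()), class = "embryo_spec")
}

#' Generate a synthetic embryonic time course with matched larval course
#'
#' @param spec an [embryo_spec()].
#'
#' @return A list with `embryo` (an [expr_matrix()], columns in minutes),
#'   `larval` (an [expr_matrix()] of the same genes over larval hours 7-36),
#'   and `truth` (t_star, regime coefficients, per-gene parameters,
#'   `larval_peak(t)` target positions).
#' @export
make_embryo_timecourse <- function(spec = embryo_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_genes
    amp <- stats::runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
    peak <- stats::runif(n, 0, 360)
    mu <- stats::runif(n, spec$mean_range[1], spec$mean_range[2])
    genes <- sprintf("g%04d", seq_len(n))
    # larval companion: phase anchored at 6 h, 7-h period, hours 7-36
    lt <- 7:36
    lphi <- 2 * pi * (lt - 6) / spec$larval_period
    lvals <- mu + outer(amp, rep(1, length(lt))) *
      cos(matrix(lphi, n, length(lt), byrow = TRUE) - peak * pi / 180) +
      matrix(stats::rnorm(n * length(lt), 0, 0.05), n)
    rownames(lvals) <- genes
    # embryo course: target larval peak position per embryonic time
    et <- spec$times
    target_tp <- ifelse(et <= spec$t_star, spec$b1 + spec$a1 * et,
                        spec$b2 + spec$a2 * et)
    tphi <- 2 * pi * (target_tp - 6) / spec$larval_period
    s <- ifelse(et <= spec$t_star,
                spec$ramp_floor + (1 - spec$ramp_floor) * et / spec$t_star, 1)
    evals <- mu + outer(amp, s) *
      cos(matrix(tphi, n, length(et), byrow = TRUE) - peak * pi / 180) +
      matrix(stats::rnorm(n * length(et), 0, spec$noise_sd), n)
    rownames(evals) <- genes
    list(embryo = expr_matrix(evals, et),
         larval = expr_matrix(lvals, lt),
         truth = list(t_star = spec$t_star, a1 = spec$a1, b1 = spec$b1,
                      a2 = spec$a2, b2 = spec$b2, target_tp = target_tp,
                      amplitude = amp, peak_phase_deg = peak, mean = mu))
  })
}

#' Specification of a synthetic single-worm reporter cohort
#'
#' Each worm carries a sinusoidal nuclear reporter with its own oscillation
#' period (default Normal(7, 0.3) h) sampled at 10-min frames. In the
#' coupled mode, molt entries and exits occur at fixed oscillator phases
#' plus a small residual (so stage durations scale with the worm's period);
#' in the uncoupled mode, intermolt and molt durations are drawn
#' independently of the period with matched marginals.
#'
#' @param n_worms cohort size (default 40).
#' @param coupled logical (default TRUE).
#' @param period_mean,period_sd oscillation period distribution (h).
#' @param intermolt_mean,intermolt_sd intermolt duration distribution (h),
#'   used directly in the uncoupled mode and matched implicitly in the
#'   coupled mode.
#' @param molt_mean,molt_sd molt (lethargus) duration distribution (h).
#' @param n_stages number of larval stages (default 4).
#' @param frame_h frame interval (default `1/6` h = 10 min).
#' @param coupled_phase_sd residual phase noise at locked molts (rad,
#'   default 0.1).
#' @param reporter_amplitude,reporter_mean,noise_sd trace shape parameters.
#' @param seed RNG seed.
#'
#' @return A list of class `worm_cohort_spec`.
#' @export
worm_cohort_spec <- function(n_worms = 40, coupled = TRUE,
                             period_mean = 7, period_sd = 0.3,
                             intermolt_mean = 6, intermolt_sd = 0.4,
                             molt_mean = 2, molt_sd = 0.2, n_stages = 4,
                             frame_h = 1 / 6, coupled_phase_sd = 0.1,
                             reporter_amplitude = 1, reporter_mean = 5,
                             noise_sd = 0.1, seed = 1) {
  stopifnot(n_worms >= 1, period_mean > 0, frame_h > 0)
  structure(as.list(environment()), class = "worm_cohort_spec")
}

#' Generate a synthetic single-worm reporter cohort
#'
#' @param spec a [worm_cohort_spec()].
#'
#' @return A list with `worms` (list of [worm_trace()]) and `truth`
#'   (per-worm period and molt schedule).
#' @export
make_worm_cohort <- function(spec = worm_cohort_spec()) {
  with_seed(spec$seed, {
    stage_h <- spec$intermolt_mean + spec$molt_mean
    worms <- vector("list", spec$n_worms)
    truth <- vector("list", spec$n_worms)
    for (i in seq_len(spec$n_worms)) {
      T_o <- stats::rnorm(1, spec$period_mean, spec$period_sd)
      if (spec$coupled) {
        # lock events to oscillator phase: nominal event times for a
        # period_mean worm, converted to phases, rescaled by this worm's
        # period, plus a small residual
        entry_nom <- (seq_len(spec$n_stages) - 1) * stage_h +
          spec$intermolt_mean
        exit_nom <- entry_nom + spec$molt_mean
        ph_entry <- 2 * pi * entry_nom / spec$period_mean +
          stats::rnorm(spec$n_stages, 0, spec$coupled_phase_sd)
        ph_exit <- 2 * pi * exit_nom / spec$period_mean +
          stats::rnorm(spec$n_stages, 0, spec$coupled_phase_sd)
        entry <- ph_entry * T_o / (2 * pi)
        exit <- ph_exit * T_o / (2 * pi)
      } else {
        im <- stats::rnorm(spec$n_stages, spec$intermolt_mean,
                           spec$intermolt_sd)
        ml <- stats::rnorm(spec$n_stages, spec$molt_mean, spec$molt_sd)
        exit <- cumsum(im + ml)
        entry <- exit - ml
      }
      end <- max(exit) + 3
      tms <- seq(0, end, by = spec$frame_h)
      intensity <- spec$reporter_mean +
        spec$reporter_amplitude * cos(2 * pi * tms / T_o) +
        stats::rnorm(length(tms), 0, spec$noise_sd)
      molts <- data.frame(stage = paste0("L", seq_len(spec$n_stages)),
                          entry = entry, exit = exit)
      worms[[i]] <- worm_trace(tms, intensity, molts,
                               worm_id = sprintf("w%03d", i))
      truth[[i]] <- data.frame(worm_id = sprintf("w%03d", i), T_o = T_o)
    }
    list(worms = worms, truth = do.call(rbind, truth))
  })
}

#' Specification of synthetic luciferase luminescence traces
#'
#' Emulates single-animal luciferase assays binned at 10 min: a low
#' pre-hatch baseline, an abrupt jump at hatch, slow exponential growth of
#' the signal, deep troughs during molts and additive noise.
#'
#' @param n_animals number of traces (default 12).
#' @param total_h trace length (default 42 h, ending a few hours after M4).
#' @param bin_h bin width (default `1/6` h).
#' @param hatch_mean,hatch_sd hatch time distribution (h).
#' @param molt_entry_h,molt_exit_h molt schedule relative to hatch (h).
#' @param schedule_jitter_sd per-animal jitter of molt boundaries (h).
#' @param baseline,signal luminescence levels before/after hatch (a.u.).
#' @param trough_frac luminescence during molts as a fraction of the trend
#'   (default 0.2).
#' @param growth_rate exponential signal growth per hour (default 0.015).
#' @param noise_sd additive noise sd (a.u., default 1).
#' @param seed RNG seed.
#'
#' @return A list of class `luminescence_spec`.
#' @export
luminescence_spec <- function(n_animals = 12, total_h = 42, bin_h = 1 / 6,
                              hatch_mean = 5, hatch_sd = 0.5,
                              molt_entry_h = c(10, 17, 24, 31),
                              molt_exit_h = c(12, 19, 26, 33),
                              schedule_jitter_sd = 0.2,
                              baseline = 10, signal = 100,
                              trough_frac = 0.2, growth_rate = 0.015,
                              noise_sd = 1, seed = 1) {
  stopifnot(all(molt_exit_h > molt_entry_h))
  structure(as.list(environment()), class = "luminescence_spec")
}

#' Generate synthetic luciferase luminescence traces
#'
#' @param spec a [luminescence_spec()].
#'
#' @return A list with `traces` (list of numeric vectors), `truth` (per
#'   animal: hatch bin, molt entry/exit bins) and `bin_h`.
#' @export
make_luminescence <- function(spec = luminescence_spec()) {
  with_seed(spec$seed, {
    n_bins <- round(spec$total_h / spec$bin_h)
    tms <- (seq_len(n_bins) - 0.5) * spec$bin_h
    traces <- vector("list", spec$n_animals)
    truth <- vector("list", spec$n_animals)
    for (i in seq_len(spec$n_animals)) {
      hatch_t <- stats::rnorm(1, spec$hatch_mean, spec$hatch_sd)
      jit <- stats::rnorm(length(spec$molt_entry_h), 0,
                          spec$schedule_jitter_sd)
      entry_t <- hatch_t + spec$molt_entry_h + jit
      exit_t <- hatch_t + spec$molt_exit_h + jit
      level <- ifelse(tms < hatch_t, spec$baseline,
                      spec$signal * exp(spec$growth_rate * (tms - hatch_t)))
      in_molt <- rep(FALSE, n_bins)
      for (k in seq_along(entry_t))
        in_molt <- in_molt | (tms >= entry_t[k] & tms < exit_t[k])
      level[in_molt] <- level[in_molt] * spec$trough_frac
      raw <- pmax(level + stats::rnorm(n_bins, 0, spec$noise_sd), 0.1)
      traces[[i]] <- raw
      truth[[i]] <- data.frame(
        animal = i, hatch_bin = which(tms >= hatch_t)[1],
        entry_bin = I(list(vapply(entry_t, function(x) which(tms >= x)[1],
                                  integer(1)))),
        exit_bin = I(list(vapply(exit_t, function(x) max(which(tms < x)),
                                 integer(1)))))
    }
    list(traces = traces, truth = do.call(rbind, truth), bin_h = spec$bin_h,
         times = tms)
  })
}
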
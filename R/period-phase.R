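#' Band-pass filter specification
#'
#' @param low,high pass-band edges in cycles per hour. Defaults 0.1 and 0.2
#'   (10-h and 5-h periods) suit hourly RNA-seq courses; use `1/14` and
#'   `1/5` for 10-min single-worm traces.
#' @param order Butterworth filter order (default 1).
#'
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low = 0.1, high = 0.2, order = 1) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  structure(list(low = low, high = high, order = order),
            class = "bandpass_spec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies an order-`spec$order` Butterworth band-pass forward and backward
#' (zero phase distortion) with constant (edge-value) padding, the digital
#' analogue of filtering with `padtype = "constant"`. A constant input maps
#' to approximately zero.
#'
#' @param trace numeric signal (mean-normalized log2 expression or reporter
#'   intensity).
#' @param spec a [bandpass_spec()].
#' @param sample_rate samples per hour (default 1 for hourly data).
#'
#' @return Filtered numeric vector, same length as `trace`.
#' @export
bandpass_filter <- function(trace, spec = bandpass_spec(), sample_rate = 1) {
  if (any(!is.finite(trace))) stop("trace must be finite")
  nyq <- sample_rate / 2
  if (spec$high >= nyq) stop("band edges must lie inside (0, Nyquist)")
  n <- length(trace)
  if (n <= 3 * spec$order) stop("trace too short for the filter order")
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  b <- bf$b; a <- bf$a
  padlen <- min(3L * max(length(a), length(b)), n - 1L)
  x <- c(rep(trace[1], padlen), trace, rep(trace[n], padlen))
  y <- lfilter_zi(b, a, x)
  y <- rev(lfilter_zi(b, a, rev(y)))
  as.numeric(y[(padlen + 1):(padlen + n)])
}

# direct-form-II-transposed IIR filter started from the steady-state
# initial conditions for a step of the first sample's height, so a constant
# input produces the filter's DC response from sample one (no startup
# transient); this is what makes forward-backward filtering with constant
# padding exactly offset-invariant
lfilter_zi <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  # zi solves (I - A^T) zi = b[-1] - a[-1] * b[1] with A the companion
  # matrix of a
  comp <- matrix(0, m - 1, m - 1)
  comp[1, ] <- -a[-1]
  if (m > 2) comp[cbind(2:(m - 1), 1:(m - 2))] <- 1
  zi <- solve(diag(m - 1) - t(comp), b[-1] - a[-1] * b[1])
  z <- zi * x[1]
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z[1]
    if (m > 2) {
      z[1:(m - 2)] <- b[2:(m - 1)] * x[i] + z[2:(m - 1)] - a[2:(m - 1)] * y[i]
    }
    z[m - 1] <- b[m] * x[i] - a[m] * y[i]
  }
  y
}

# analytic signal via the FFT one-sided spectrum doubling; x should be
# (approximately) zero-mean
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase, angular velocity and period of a filtered signal
#'
#' Takes the argument of the analytic signal (Hilbert transform), unwraps it,
#' differentiates the unwrapped phase (central differences, one-sided at the
#' ends) to get the angular velocity, and reports the instantaneous period
#' as `2*pi / velocity`. The first `trim_start` and last `trim_end` samples
#' are excluded from the retained range to avoid edge effects (defaults 4
#' and 3: an hourly course entered at 5-39 h retains 9-36 h).
#'
#' @param filtered band-pass filtered (approximately zero-mean) signal.
#' @param times sampling times (h); defaults to `0:(n-1) / sample_rate`.
#' @param sample_rate samples per hour (default 1).
#' @param trim_start,trim_end leading/trailing samples excluded from the
#'   retained range (defaults 4 and 3).
#'
#' @return A list of class `phase_trace`: `times`, `phase` ((-pi, pi]),
#'   `unwrapped` (rad), `velocity` (rad/h), `period` (h) and `retained`
#'   (integer index range).
#' @export
instantaneous_phase <- function(filtered, times = NULL, sample_rate = 1,
                                trim_start = 4, trim_end = 3) {
  n <- length(filtered)
  if (all(filtered == 0)) stop("all-zero input: phase undefined")
  if (is.null(times)) times <- (seq_len(n) - 1) / sample_rate
  z <- analytic_signal(filtered - mean(filtered))
  phase <- Arg(z)
  unwrapped <- signal::unwrap(phase)
  dt <- 1 / sample_rate
  vel <- numeric(n)
  if (n >= 3) {
    vel[2:(n - 1)] <- (unwrapped[3:n] - unwrapped[1:(n - 2)]) / (2 * dt)
  }
  vel[1] <- (unwrapped[2] - unwrapped[1]) / dt
  vel[n] <- (unwrapped[n] - unwrapped[n - 1]) / dt
  retained <- seq.int(trim_start + 1L, n - trim_end)
  if (length(retained) < 1) stop("trimming removes all samples")
  structure(list(times = times, phase = phase, unwrapped = unwrapped,
                 velocity = vel, period = 2 * pi / vel, retained = retained),
            class = "phase_trace")
}

#' @export
print.phase_trace <- function(x, ...) {
  r <- x$retained
  cat(sprintf("phase trace: %d samples, retained %d-%d (t = %.4g-%.4g h), mean period %.4g h\n",
              length(x$phase), min(r), max(r), x$times[min(r)], x$times[max(r)],
              mean(x$period[r])))
  invisible(x)
}

#' Band-pass + Hilbert period quantification for a matrix of genes
#'
#' Convenience pipeline: mean-normalizes each gene across time, band-pass
#' filters it and extracts the instantaneous phase trace.
#'
#' @param mat an [expr_matrix()] (typically restricted to oscillating,
#'   non-L4-deviating genes over an analysis window such as 5-39 h).
#' @param spec a [bandpass_spec()].
#' @param trim_start,trim_end edge trims passed to [instantaneous_phase()].
#'
#' @return A list of `phase_trace` objects, one per gene.
#' @export
phase_traces <- function(mat, spec = bandpass_spec(), trim_start = 4,
                         trim_end = 3) {
  tms <- em_times(mat)
  sr <- 1 / stats::median(diff(tms))
  lapply(seq_len(nrow(mat)), function(i) {
    y <- unclass(mat)[i, ]
    f <- bandpass_filter(y - mean(y), spec, sample_rate = sr)
    instantaneous_phase(f, times = tms, sample_rate = sr,
                        trim_start = trim_start, trim_end = trim_end)
  })
}

#' Mean instantaneous-period profile across genes
#'
#' @param traces list of `phase_trace` objects sharing one retained grid.
#'
#' @return Data frame with `time` (h), `mean_period` (h) and
#'   `mean_velocity` (rad/h) on the retained range.
#' @export
mean_period_profile <- function(traces) {
  if (length(traces) == 0) stop("empty trace collection")
  r <- traces[[1]]$retained
  for (tr in traces)
    if (!identical(tr$retained, r)) stop("traces must share the retained grid")
  per <- sapply(traces, function(tr) tr$period[r])
  vel <- sapply(traces, function(tr) tr$velocity[r])
  data.frame(time = traces[[1]]$times[r],
             mean_period = rowMeans(per),
             mean_velocity = rowMeans(vel))
}

#' Reconstruct a unit-amplitude oscillation from a mean angular velocity
#'
#' `sin(cumsum(velocity * dt))`: the sine of the accumulated phase.
#'
#' @param mean_velocity angular velocity series (rad/h).
#' @param dt sampling interval (h, default 1).
#'
#' @return Numeric vector in [-1, 1].
#' @export
reconstruct_oscillation <- function(mean_velocity, dt = 1) {
  if (any(!is.finite(mean_velocity))) stop("velocity must be finite")
  sin(cumsum(mean_velocity * dt))
}

#' First expression peak of a trace via spline interpolation
#'
#' Interpolates the trace inside a window (default 3-13 h) with a cubic
#' interpolating spline, finds the zeros of its derivative and returns the
#' root with the highest spline value. A window without any derivative root
#' yields a typed "no peak" result rather than an error.
#'
#' @param trace numeric expression values.
#' @param times sampling times (h).
#' @param window length-2 closed search interval (default `c(3, 13)`).
#' @param dense_n dense evaluation grid size (default 512).
#'
#' @return A list with `found` (logical), `time` and `value` (NA when no
#'   peak).
#' @export
first_peak_time <- function(trace, times, window = c(3, 13), dense_n = 512) {
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 4) stop("window holds fewer than 4 points")
  x <- times[keep]; y <- trace[keep]
  sf <- stats::splinefun(x, y, method = "fmm")
  roots <- spline_derivative_roots(sf, range(x), dense_n)
  if (length(roots) == 0)
    return(list(found = FALSE, time = NA_real_, value = NA_real_))
  vals <- sf(roots)
  best <- which.max(vals)
  list(found = TRUE, time = roots[best], value = vals[best])
}

# zeros of the first derivative of a splinefun on [lo, hi], located by sign
# changes on a dense grid and refined with uniroot
spline_derivative_roots <- function(sf, rng, dense_n = 512) {
  xs <- seq(rng[1], rng[2], length.out = dense_n)
  d <- sf(xs, deriv = 1)
  sgn <- sign(d)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(t) sf(t, deriv = 1), c(xs[i], xs[i + 1]),
                   tol = 1e-9)$root
  }, numeric(1))
  exact <- xs[d == 0]
  sort(unique(c(roots, exact)))
}
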
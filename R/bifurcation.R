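#' Parameters of the two-parameter oscillator model
#'
#' The model
#' \deqn{dx/dt = x(\beta - x^2 - y^2) - 2\pi y(1 - \lambda y)}
#' \deqn{dy/dt = y(\beta - x^2 - y^2) + 2\pi x(1 - \lambda y)}
#' supports a supercritical Hopf bifurcation in `beta` (limit cycle of radius
#' `sqrt(beta)` for `beta > 0`) and a SNIC bifurcation in `lambda` (for
#' `|lambda * r| >= 1` a fixed point appears on the cycle at `theta = pi/2`).
#' On the limit cycle the period is `T = 1/sqrt(1 - beta*lambda^2)`.
#' Parameters may be ramped linearly in time: `beta(t) = beta + k_beta*t`,
#' capped at 1 when ramped upward, and `lambda(t) = lambda + k_lam*t`,
#' floored at 0.
#'
#' @param beta Hopf parameter (default 1).
#' @param lam SNIC parameter (default 0; clamped to be non-negative).
#' @param k_beta,k_lam linear ramp rates per time unit (default 0, i.e.
#'   constant parameters).
#' @param noise_sd additive white-noise scale for stochastic runs
#'   (default 0 = deterministic).
#' @param dt Euler-Maruyama step for stochastic runs (default 1e-3).
#' @param phi_reach limit-cycle reach threshold (default 0.01).
#'
#' @return A list of class `bif_params`.
#' @export
bif_params <- function(beta = 1, lam = 0, k_beta = 0, k_lam = 0,
                       noise_sd = 0, dt = 1e-3, phi_reach = 0.01) {
  if (dt <= 0) stop("dt must be positive")
  if (phi_reach <= 0) stop("phi_reach must be positive")
  structure(list(beta = beta, lam = max(lam, 0), k_beta = k_beta,
                 k_lam = k_lam, noise_sd = noise_sd, dt = dt,
                 phi_reach = phi_reach),
            class = "bif_params")
}

beta_at <- function(p, t) {
  b <- p$beta + p$k_beta * t
  if (p$k_beta > 0) pmin(b, 1) else b
}

lam_at <- function(p, t) pmax(p$lam + p$k_lam * t, 0)

#' Simulate the oscillator in Cartesian coordinates
#'
#' Deterministic runs (`noise_sd = 0`) use an adaptive explicit integrator
#' (deSolve, tolerance 1e-8); stochastic runs use the Euler-Maruyama method
#' with additive white noise of equal scale on both state variables.
#'
#' @param params a [bif_params()].
#' @param init initial state `c(x, y)`.
#' @param horizon total simulated time.
#' @param sample_dt output sampling interval (default 0.01).
#'
#' @return An object of class `osc_trajectory`: data frame with `time`,
#'   `x`, `y`, `r`, `theta`, `beta`, `lam`; attributes `diverged` and
#'   `params`. If the radius exceeds 1e3 the trajectory is truncated and
#'   flagged.
#' @export
simulate_cartesian <- function(params, init = c(1, 0), horizon = 30,
                               sample_dt = 0.01) {
  if (horizon <= params$dt) stop("horizon must exceed dt")
  if (params$noise_sd < 0) stop("noise_sd must be >= 0")
  if (params$noise_sd == 0) {
    deriv <- function(t, state, parms) {
      b <- beta_at(params, t); l <- lam_at(params, t)
      x <- state[1]; y <- state[2]
      rr <- x^2 + y^2
      list(c(x * (b - rr) - 2 * pi * y * (1 - l * y),
             y * (b - rr) + 2 * pi * x * (1 - l * y)))
    }
    tms <- seq(0, horizon, by = sample_dt)
    sol <- deSolve::lsoda(init, tms, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-8)
    x <- sol[, 2]; y <- sol[, 3]; tms <- sol[, 1]
  } else {
    n <- ceiling(horizon / params$dt)
    thin <- max(1L, round(sample_dt / params$dt))
    keep <- seq(1L, n + 1L, by = thin)
    x_all <- numeric(length(keep)); y_all <- numeric(length(keep))
    xx <- init[1]; yy <- init[2]; ki <- 1L
    sq <- params$noise_sd * sqrt(params$dt)
    for (i in 0:n) {
      if (i %% thin == 0L) { x_all[ki] <- xx; y_all[ki] <- yy; ki <- ki + 1L }
      t <- i * params$dt
      b <- beta_at(params, t); l <- lam_at(params, t)
      rr <- xx^2 + yy^2
      dx <- xx * (b - rr) - 2 * pi * yy * (1 - l * yy)
      dy <- yy * (b - rr) + 2 * pi * xx * (1 - l * yy)
      xx <- xx + dx * params$dt + sq * stats::rnorm(1)
      yy <- yy + dy * params$dt + sq * stats::rnorm(1)
      if (xx^2 + yy^2 > 1e6) break
    }
    x <- x_all[seq_len(ki - 1L)]; y <- y_all[seq_len(ki - 1L)]
    tms <- (keep[seq_len(ki - 1L)] - 1L) * params$dt
  }
  make_trajectory(tms, x, y, params)
}

#' Simulate the oscillator in polar coordinates
#'
#' Integrates `dr/dt = r(beta - r^2)`, `dtheta/dt = 2*pi*(1 - lambda*r*
#' sin(theta))` with the same ramp, noise and integrator conventions as
#' [simulate_cartesian()]; deterministic paths from matched initial
#' conditions agree with the Cartesian integrator after coordinate
#' conversion.
#'
#' @inheritParams simulate_cartesian
#' @param init initial state `c(r, theta)` with `r >= 0`.
#'
#' @return An `osc_trajectory` (see [simulate_cartesian()]).
#' @export
simulate_polar <- function(params, init = c(1, pi / 2), horizon = 30,
                           sample_dt = 0.01) {
  if (init[1] < 0) stop("initial radius must be >= 0")
  if (horizon <= params$dt) stop("horizon must exceed dt")
  if (params$noise_sd == 0) {
    deriv <- function(t, state, parms) {
      b <- beta_at(params, t); l <- lam_at(params, t)
      r <- state[1]; th <- state[2]
      list(c(r * (b - r^2), 2 * pi * (1 - l * r * sin(th))))
    }
    tms <- seq(0, horizon, by = sample_dt)
    sol <- deSolve::lsoda(init, tms, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-8)
    r <- sol[, 2]; th <- sol[, 3]; tms <- sol[, 1]
  } else {
    n <- ceiling(horizon / params$dt)
    thin <- max(1L, round(sample_dt / params$dt))
    keep <- seq(1L, n + 1L, by = thin)
    r_all <- numeric(length(keep)); th_all <- numeric(length(keep))
    r <- init[1]; th <- init[2]; ki <- 1L
    sq <- params$noise_sd * sqrt(params$dt)
    for (i in 0:n) {
      if (i %% thin == 0L) { r_all[ki] <- r; th_all[ki] <- th; ki <- ki + 1L }
      t <- i * params$dt
      b <- beta_at(params, t); l <- lam_at(params, t)
      r <- r + r * (b - r^2) * params$dt + sq * stats::rnorm(1)
      th <- th + 2 * pi * (1 - l * r * sin(th)) * params$dt +
        sq * stats::rnorm(1)
      r <- max(r, 0)
      if (r > 1e3) break
    }
    r <- r_all[seq_len(ki - 1L)]; th <- th_all[seq_len(ki - 1L)]
    tms <- (keep[seq_len(ki - 1L)] - 1L) * params$dt
  }
  make_trajectory(tms, r * cos(th), r * sin(th), params,
                  unwrapped_theta = th)
}

make_trajectory <- function(tms, x, y, params, unwrapped_theta = NULL) {
  r <- sqrt(x^2 + y^2)
  diverged <- any(r > 1e3)
  if (diverged) {
    cut <- which(r > 1e3)[1]
    tms <- tms[1:cut]; x <- x[1:cut]; y <- y[1:cut]; r <- r[1:cut]
    if (!is.null(unwrapped_theta)) unwrapped_theta <- unwrapped_theta[1:cut]
  }
  d <- data.frame(time = tms, x = x, y = y, r = r,
                  theta = atan2(y, x),
                  beta = beta_at(params, tms), lam = lam_at(params, tms))
  if (!is.null(unwrapped_theta)) d$theta_unwrapped <- unwrapped_theta
  structure(d, diverged = diverged, params = params,
            class = c("osc_trajectory", "data.frame"))
}

#' @export
print.osc_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("oscillator trajectory: %d samples over t = 0-%.4g (noise sd %g)%s\n",
              nrow(x), max(x$time), p$noise_sd,
              if (attr(x, "diverged")) " [DIVERGED, truncated]" else ""))
  cat(sprintf("  final state: r = %.4g, theta = %.4g rad; beta = %.4g, lambda = %.4g\n",
              x$r[nrow(x)], x$theta[nrow(x)], x$beta[nrow(x)], x$lam[nrow(x)]))
  invisible(x)
}

#' @export
plot.osc_trajectory <- function(x, which = c("time", "phase"), ...) {
  which <- match.arg(which)
  if (which == "time") {
    graphics::plot(x$time, x$x, type = "l", xlab = "time", ylab = "x", ...)
    graphics::lines(x$time, x$r, col = "red3")
    graphics::legend("topright", c("x", "r"), col = c("black", "red3"),
                     lty = 1, bty = "n")
  } else {
    graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
  }
  invisible(x)
}

#' Closed-form limit-cycle period
#'
#' `T = 1 / sqrt(1 - beta * lambda^2)` for `beta > 0` and
#' `beta * lambda^2 < 1`; on the SNIC side (`beta * lambda^2 >= 1`) there is
#' no oscillation and `NA` is returned.
#'
#' @param beta Hopf parameter (> 0).
#' @param lam SNIC parameter.
#'
#' @return The period, or `NA_real_` when the fixed point on the cycle
#'   exists (no oscillation).
#' @export
limit_cycle_period <- function(beta, lam) {
  if (beta <= 0) stop("beta must be positive for a limit cycle")
  if (beta * lam^2 >= 1) return(NA_real_)
  1 / sqrt(1 - beta * lam^2)
}

#' First time a ramped-beta trajectory reaches the limit cycle
#'
#' The amplitude of a slowly ramped supercritical Hopf system tracks the
#' moving limit cycle only after a delayed jump; the cycle counts as reached
#' at the first sample where `|dr/dt - k_beta| < phi_reach`, with `dr/dt`
#' estimated by central differences on the sampled radius.
#'
#' @param traj an `osc_trajectory` from a ramped-beta run.
#' @param k_beta ramp rate used for the run (default taken from the
#'   trajectory's parameters).
#' @param phi_reach threshold (default from the parameters, 0.01).
#'
#' @return A list with `reached` and `time` (NA when never satisfied).
#' @export
reach_time <- function(traj, k_beta = NULL, phi_reach = NULL) {
  p <- attr(traj, "params")
  if (is.null(k_beta)) k_beta <- p$k_beta
  if (is.null(phi_reach)) phi_reach <- p$phi_reach
  n <- nrow(traj)
  drdt <- numeric(n)
  dt <- diff(traj$time)
  drdt[2:(n - 1)] <- (traj$r[3:n] - traj$r[1:(n - 2)]) /
    (traj$time[3:n] - traj$time[1:(n - 2)])
  drdt[1] <- (traj$r[2] - traj$r[1]) / dt[1]
  drdt[n] <- (traj$r[n] - traj$r[n - 1]) / dt[n - 1]
  hit <- which(abs(drdt - k_beta) < phi_reach)
  if (length(hit) == 0) return(list(reached = FALSE, time = NA_real_))
  list(reached = TRUE, time = traj$time[hit[1]])
}

#' Per-cycle period and amplitude of a simulated trajectory
#'
#' Cycles are delimited by successive upward zero crossings of `x` (linearly
#' interpolated); the period is the crossing-to-crossing interval and the
#' amplitude the maximum radius within the cycle.
#'
#' @param traj an `osc_trajectory`.
#' @param after ignore crossings before this time (default 0).
#'
#' @return A list with `found` and, when at least two crossings exist, a
#'   data frame `cycles` (start, period, amplitude).
#' @export
measure_cycles <- function(traj, after = 0) {
  x <- traj$x; tms <- traj$time
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  cross <- tms[up] + (tms[up + 1] - tms[up]) * (-x[up]) / (x[up + 1] - x[up])
  cross <- cross[cross >= after]
  if (length(cross) < 2) return(list(found = FALSE, cycles = NULL))
  cycles <- data.frame(start = cross[-length(cross)],
                       period = diff(cross))
  cycles$amplitude <- vapply(seq_len(nrow(cycles)), function(i) {
    inb <- tms >= cycles$start[i] & tms < cycles$start[i] + cycles$period[i]
    max(traj$r[inb])
  }, numeric(1))
  list(found = TRUE, cycles = cycles)
}
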
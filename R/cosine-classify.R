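#' Fixed-period cosine regression of a log2 expression trace
#'
#' Fits `intercept + A*cos(wt) - B*sin(wt)` by ordinary least squares at a
#' fixed angular frequency `w = 2*pi/period`. A cosine
#' `C*cos(wt + phi)` satisfies `A = C*cos(phi)` and `B = C*sin(phi)`, so the
#' amplitude is `C = sqrt(A^2 + B^2)` and the phase `phi = atan2(B, A)`.
#' The peak phase reported is `(360 - phi) mod 360` so that genes peaking
#' later in the cycle get larger peak phases; its 0-degree origin is
#' arbitrary.
#'
#' @param trace numeric log2 expression values.
#' @param times sampling times (h), at least 4 distinct values.
#' @param period fixed period (h), default 7.
#'
#' @return A list of class `cosine_fit`: coefficients `A`, `B`, standard
#'   errors `seA`, `seB`, amplitude `C`, phase `phi_deg`, `peak_phase_deg`,
#'   `omega`, `period`, residual degrees of freedom `df`, `intercept` and
#'   `sigma`.
#' @export
fit_cosine <- function(trace, times, period = 7) {
  if (length(trace) != length(times)) stop("trace/times length mismatch")
  if (length(times) < 4) stop("at least 4 time points are required")
  if (period <= 0) stop("period must be positive")
  f <- cosine_fit_matrix(matrix(trace, nrow = 1), times, period)
  out <- lapply(f, function(x) unname(x[1]))
  out$omega <- 2 * pi / period
  out$period <- period
  structure(out, class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf(
    "cosine fit (period %.3g h, df %d): amplitude %.4g (A %.4g, B %.4g), peak phase %.1f deg\n",
    x$period, x$df, x$C, x$A, x$B, x$peak_phase_deg))
  invisible(x)
}

# Vectorized least-squares cosine fit: Y is a gene x time matrix, one shared
# design.  Returns per-gene coefficients, SEs, amplitude and phases.
# Identical to per-gene lm(y ~ cos(wt) + I(-sin(wt))) but solved once.
cosine_fit_matrix <- function(Y, times, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), -sin(w * times))
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient cosine design (period aliases the sampling grid)")
  coefs <- qr.coef(qrX, t(Y))            # 3 x n_genes
  fitted <- X %*% coefs
  res <- t(Y) - fitted
  df <- length(times) - 3L
  rss <- colSums(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  A <- coefs[2, ]; B <- coefs[3, ]
  seA <- sqrt(sigma2 * XtXinv[2, 2])
  seB <- sqrt(sigma2 * XtXinv[3, 3])
  C <- sqrt(A^2 + B^2)
  phi <- (atan2(B, A) * 180 / pi) %% 360
  phi <- ifelse(abs(phi - 360) < 1e-9, 0, phi)  # snap the wrap boundary
  peak <- (360 - phi) %% 360
  peak <- ifelse(abs(peak - 360) < 1e-9, 0, peak)
  list(A = A, B = B, seA = seA, seB = seB, C = C,
       phi_deg = phi, peak_phase_deg = peak,
       intercept = coefs[1, ], sigma = sqrt(sigma2), df = df)
}

#' First-order (Taylor) confidence interval for the cosine amplitude
#'
#' Propagates the standard errors of the cosine coefficients A and B to the
#' amplitude `C = sqrt(A^2 + B^2)` assuming independent errors:
#' `seC = sqrt(A^2*seA^2 + B^2*seB^2) / C`, with a normal-quantile interval
#' `C +/- z(1 - alpha/2) * seC`.
#'
#' @param fit a `cosine_fit`, or a list with elements `A`, `B`, `seA`, `seB`,
#'   `C` (vectors allowed).
#' @param alpha significance level (default 0.01 for a 99% CI).
#'
#' @return A list with `se`, `lower`, `upper` and logical `degenerate`
#'   (TRUE where C = 0 and the first-order expansion is undefined; the
#'   interval is then reported as [0, 0]).
#' @export
propagate_amplitude_ci <- function(fit, alpha = 0.01) {
  if (any(fit$seA < 0) || any(fit$seB < 0)) stop("standard errors must be >= 0")
  C <- fit$C
  degenerate <- C == 0
  se <- ifelse(degenerate, NA_real_,
               sqrt(fit$A^2 * fit$seA^2 + fit$B^2 * fit$seB^2) / C)
  z <- stats::qnorm(1 - alpha / 2)
  list(se = se,
       lower = ifelse(degenerate, 0, C - z * se),
       upper = ifelse(degenerate, 0, C + z * se),
       degenerate = degenerate)
}

#' Classify genes as oscillating by fixed-period cosine regression
#'
#' Each gene is fitted over the classification window (default 10-25 h) at a
#' fixed period (default 7 h). A gene is labelled oscillating when its
#' amplitude is at least `amp_threshold` (default 0.5 log2 units, a 2-fold
#' peak-to-trough change) and the lower bound of the `1 - alpha` amplitude
#' confidence interval is non-negative (default alpha 0.01, i.e. P <= 0.01).
#'
#' @param mat an [expr_matrix()] of log2 values.
#' @param meta a [timecourse_meta()] providing the fit window and period.
#' @param amp_threshold amplitude cut-off in log2 units (default 0.5,
#'   inclusive).
#' @param alpha CI significance level (default 0.01).
#'
#' @return An object of class `osc_class`: a list with a per-gene data frame
#'   `fits` (gene, A, B, seA, seB, amplitude, peak_phase_deg, ci_lower,
#'   ci_upper, oscillating) plus the thresholds and window used.
#' @export
classify_genes <- function(mat, meta = timecourse_meta(),
                           amp_threshold = 0.5, alpha = 0.01) {
  wmat <- em_window(mat, meta$fit_window[1], meta$fit_window[2])
  tms <- em_times(wmat)
  if (length(tms) < 4) stop("classification window holds fewer than 4 points")
  f <- cosine_fit_matrix(unclass(wmat), tms, meta$classify_period)
  ci <- propagate_amplitude_ci(f, alpha)
  osc <- f$C >= amp_threshold & !ci$degenerate & ci$lower >= 0
  fits <- data.frame(gene = rownames(mat),
                     A = f$A, B = f$B, seA = f$seA, seB = f$seB,
                     amplitude = f$C, phi_deg = f$phi_deg,
                     peak_phase_deg = f$peak_phase_deg,
                     ci_lower = ci$lower, ci_upper = ci$upper,
                     oscillating = osc, row.names = NULL)
  structure(list(fits = fits, amp_threshold = amp_threshold, alpha = alpha,
                 window = meta$fit_window, period = meta$classify_period,
                 df = f$df),
            class = "osc_class")
}

#' @export
print.osc_class <- function(x, ...) {
  n <- nrow(x$fits); k <- sum(x$fits$oscillating)
  cat(sprintf("oscillating-gene classification (cosine fit, period %.3g h, window %g-%g h, df %d)\n",
              x$period, x$window[1], x$window[2], x$df))
  cat(sprintf("  cut-offs: amplitude >= %.3g log2, %d%% CI lower bound >= 0\n",
              x$amp_threshold, round(100 * (1 - x$alpha))))
  cat(sprintf("  %d / %d genes (%.1f%%) classified as oscillating\n",
              k, n, 100 * k / n))
  invisible(x)
}

#' @export
summary.osc_class <- function(object, ...) {
  f <- object$fits
  out <- list(n = nrow(f), n_oscillating = sum(f$oscillating),
              amplitude = summary(f$amplitude),
              peak_phase = summary(f$peak_phase_deg[f$oscillating]))
  class(out) <- "summary.osc_class"
  out
}

#' @export
print.summary.osc_class <- function(x, ...) {
  cat(sprintf("%d genes, %d oscillating (%.1f%%)\n", x$n, x$n_oscillating,
              100 * x$n_oscillating / x$n))
  cat("amplitude (log2):\n"); print(x$amplitude)
  cat("peak phase of oscillating genes (deg):\n"); print(x$peak_phase)
  invisible(x)
}

#' @export
coef.osc_class <- function(object, ...) {
  object$fits[, c("gene", "A", "B", "amplitude", "peak_phase_deg")]
}

#' @export
plot.osc_class <- function(x, ...) {
  f <- x$fits
  graphics::plot(f$amplitude, f$ci_lower,
                 col = ifelse(f$oscillating, "dodgerblue3", "grey40"),
                 pch = 16, cex = 0.5, xlab = "amplitude (log2)",
                 ylab = "99% CI lower bound", ...)
  graphics::abline(v = x$amp_threshold, h = 0, lty = 2)
  invisible(x)
}

#' Per-cycle cosine amplitudes and their cross-cycle relationship
#'
#' Fits each gene separately within cycles C2-C4 at the cycle's fixed period
#' (7 h for C2/C3, 8.5 h for C4) and summarizes how amplitudes relate across
#' cycle pairs by a least-squares slope and Pearson correlation.
#'
#' @param mat an [expr_matrix()] restricted to the genes of interest
#'   (oscillating, L4-deviating genes excluded).
#' @param meta a [timecourse_meta()].
#'
#' @return A list with `amplitudes` (gene x cycle matrix), `fits` (per-cycle
#'   coefficient data frames) and `pairs` (data frame: cycle_a, cycle_b,
#'   slope, intercept, r).
#' @export
per_cycle_amplitudes <- function(mat, meta = timecourse_meta()) {
  wins <- cycle_windows(meta)[names(meta$fixed_periods)]
  fits <- list(); amps <- NULL
  for (cy in names(wins)) {
    sub <- em_window(mat, wins[[cy]][1], wins[[cy]][2])
    tms <- em_times(sub)
    if (length(tms) < 4)
      stop(sprintf("cycle %s window holds fewer than 4 points", cy))
    f <- cosine_fit_matrix(unclass(sub), tms, meta$fixed_periods[[cy]])
    fits[[cy]] <- data.frame(gene = rownames(mat), A = f$A, B = f$B,
                             amplitude = f$C,
                             peak_phase_deg = f$peak_phase_deg,
                             row.names = NULL)
    amps <- cbind(amps, f$C)
  }
  colnames(amps) <- names(wins); rownames(amps) <- rownames(mat)
  cmb <- utils::combn(names(wins), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- amps[, cmb[1, i]]; b <- amps[, cmb[2, i]]
    co <- stats::coef(stats::lm(b ~ a))
    data.frame(cycle_a = cmb[1, i], cycle_b = cmb[2, i],
               slope = unname(co[2]), intercept = unname(co[1]),
               r = stats::cor(a, b))
  }))
  list(amplitudes = amps, fits = fits, pairs = pairs)
}

#' Circular agreement between two sets of peak-phase calls
#'
#' Differences are computed as `(a - b + 360) mod 360`. The mean offset is
#' the circular mean of the differences. The coefficient of determination
#' follows the phase-comparison convention `R^2 = 1 - SSres/SStot` with
#' `SStot` the sum of squares of the reference phases `phases_a` and
#' `SSres` the sum of squared circular differences (mapped to
#' (-180, 180] so that identical vectors give R^2 = 1).
#'
#' @param phases_a,phases_b equal-length phase vectors in degrees, [0, 360).
#'
#' @return A list with `diff_deg` (in [0, 360)), `mean_offset_deg` (circular
#'   mean, [0, 360)) and `r_squared`.
#' @export
phase_agreement <- function(phases_a, phases_b) {
  if (length(phases_a) != length(phases_b)) stop("phase vectors differ in length")
  d <- (phases_a - phases_b + 360) %% 360
  mean_off <- circular_mean_deg(d)
  d_signed <- ifelse(d > 180, d - 360, d)
  r2 <- 1 - sum(d_signed^2) / sum(phases_a^2)
  list(diff_deg = d, mean_offset_deg = mean_off, r_squared = r2)
}

#' Tissue enrichment among oscillating genes
#'
#' Restricts the annotation to tissue-specific genes (expression ratio above
#' `ratio_min` and q-value below `q_max`), then compares the tissue
#' composition of the oscillating subset with the full tissue-specific
#' background: fold enrichment is the ratio of tissue shares, significance a
#' one-sided exact binomial test at the background share (alternative
#' "greater" for fold >= 1, otherwise "less").
#'
#' @param result an `osc_class` from [classify_genes()], or a character
#'   vector of oscillating gene ids.
#' @param annot data frame with columns `gene`, `tissue`, `ratio`, `qvalue`.
#' @param ratio_min minimum max/second tissue expression ratio (default 5,
#'   exclusive).
#' @param q_max maximum q-value (default 0.05, exclusive).
#'
#' @return Data frame: tissue, n_background, n_oscillating, fold, p_value.
#' @export
tissue_enrichment <- function(result, annot, ratio_min = 5, q_max = 0.05) {
  osc_genes <- if (inherits(result, "osc_class"))
    result$fits$gene[result$fits$oscillating] else as.character(result)
  spec <- annot[annot$ratio > ratio_min & annot$qvalue < q_max, , drop = FALSE]
  if (nrow(spec) == 0) stop("no tissue-specific genes pass the filters")
  spec_osc <- spec[spec$gene %in% osc_genes, , drop = FALSE]
  tissues <- sort(unique(spec$tissue))
  n_bg_tot <- nrow(spec); n_osc_tot <- nrow(spec_osc)
  out <- do.call(rbind, lapply(tissues, function(tt) {
    K <- sum(spec$tissue == tt)
    if (K == 0) return(NULL)
    k <- sum(spec_osc$tissue == tt)
    bg_share <- K / n_bg_tot
    fold <- (k / n_osc_tot) / bg_share
    alt <- if (fold >= 1) "greater" else "less"
    p <- stats::binom.test(k, n_osc_tot, p = bg_share, alternative = alt)$p.value
    data.frame(tissue = tt, n_background = K, n_oscillating = k,
               fold = fold, p_value = p)
  }))
  rownames(out) <- NULL
  out
}

#' Kernel density of peak phases on the circle
#'
#' Replicates the sample at +/-360 degrees before kernel density estimation
#' so the estimate is correct at the 0/360 wrap, then evaluates on [0, 360].
#'
#' @param phases peak phases in degrees, [0, 360).
#' @param bw kernel bandwidth in degrees (default 20).
#' @param n number of evaluation points (default 512).
#'
#' @return A list with `x` (degrees), `y` (density integrating to 1 over one
#'   turn).
#' @export
circular_phase_density <- function(phases, bw = 20, n = 512) {
  if (length(phases) == 0) stop("empty phase vector")
  rep3 <- c(phases - 360, phases, phases + 360)
  d <- stats::density(rep3, bw = bw, from = 0, to = 360, n = n)
  list(x = d$x, y = d$y * 3)  # one third of the replicated mass lies per turn
}

# circular mean of angles in degrees, result in [0, 360)
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

# circular median in degrees: the sample angle minimizing summed circular
# distance, result in [0, 360)
circular_median_deg <- function(deg) {
  deg <- deg %% 360
  cost <- vapply(deg, function(a) {
    d <- abs((deg - a + 180) %% 360 - 180)
    sum(d)
  }, numeric(1))
  deg[which.min(cost)]
}
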
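---
title: "Methods: quantifying the C. elegans larval gene-expression oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the C. elegans larval gene-expression oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvosc)
```

`larvosc` analyses the rhythmic transcriptional program of *C. elegans*
larval development: a massive oscillation involving roughly a quarter of
expressed genes, with a common ~7-h period, peak phases spread around the
full cycle, onset a few hours after hatching, period lengthening to
~8.5 h in the final larval stage, and arrest at a specific oscillator
phase in adulthood. This vignette documents the models the package
implements, the parameters that matter, the numerical choices, what the
synthetic-data generators do and do not emulate, and known limitations.

## Expression preprocessing

Raw counts are scaled per sample by total library size and rescaled to
the *mean* library size across samples, so values stay on the raw-count
scale and the pseudocount keeps its meaning; then a pseudocount of 8 is
added and the data are log2-transformed. The scale target after
library-size division is recorded in the returned object (`scale`
attribute) so it is auditable; counts-per-mean-depth was chosen over
counts-per-million because an 8-count offset is only interpretable on
the count scale.

Lowly expressed genes are dropped when width-adjusted maximum expression
`max_t y − (log2 w − mean(log2 w))` is ≤ 6 (gene width `w` in bp). Two
overlapping courses are fused by taking columns up to and including the
seam (13 h) from the early course and later columns from the late one,
on the intersection of their gene sets; the seam column belongs to the
early course. For per-cycle analyses, genes whose mean level shifts
between the L2 (C2, 14–20 h) and L4 (C4, 27–36 h) windows by more than
0.25 of their average, `|m₂−m₄|/(0.5(m₂+m₄))`, are excluded as
L4-deviating.

## Classification by fixed-period cosine regression

Each gene's log2 trace over 10–25 h (when the period is most stable) is
regressed on `cos(ωt)` and `−sin(ωt)` at fixed `ω = 2π/7 h⁻¹`, leaving
13 residual degrees of freedom for 16 hourly samples. With
`A = C cos φ` and `B = C sin φ`, amplitude and phase are
`C = √(A²+B²)`, `φ = atan2(B, A)`. Because only the coefficient standard
errors enter the published propagation procedure, the 99% CI on `C`
uses the independent-error first-order formula
`se(C) = √(A² se_A² + B² se_B²)/C` with normal quantiles. The
coefficient covariance is ignored; on near-complete-cycle hourly designs
the two regressors are essentially orthogonal, so cov(A, B) ≈ 0 and the
approximation is benign (the package's Monte-Carlo cross-check agrees
within 5% for `C/se(C) ≥ 3`). At `C = 0` the expansion is undefined and
the interval is flagged degenerate.

A gene is *oscillating* iff `C ≥ 0.5` (inclusive; a 2-fold linear
peak-to-trough change) **and** the CI lower bound is ≥ 0 (P ≤ 0.01).
Under pure noise the amplitude cut dominates and the pass rate is far
below the nominal 1%.

Two phase conventions coexist deliberately. The fitted `φ` is the
argument in `C cos(ωt + φ)`; the reported *peak phase* is
`(360 − φ) mod 360`, so genes peaking later in the cycle get larger peak
phases. The 0° origin is arbitrary; all phase comparisons are circular
(`(a − b + 360) mod 360`), and the agreement statistic
`R² = 1 − SSres/SStot` uses the squared circular differences against the
sum of squares of the reference phases — a convention, not the usual
regression `R²`.

Per-cycle amplitude fits use 7 h in C2/C3 and 8.5 h in C4. Tissue
enrichment restricts to tissue-specific genes (max/second expression
ratio > 5, q < 0.05) and tests each tissue's share among oscillating
tissue-specific genes against its background share with a one-sided
exact binomial test (alternative = enrichment for fold ≥ 1, otherwise
the complementary side). Peak-phase densities replicate the sample at
±360° before kernel estimation so the density is correct at the wrap.

## Instantaneous period and phase

Mean-normalized traces over 5–39 h are band-pass filtered with an
order-1 Butterworth (0.1–0.2 cycles/h, i.e. 10-h to 5-h periods) applied
forward and backward for zero phase distortion. Padding is constant
(edge value), and each pass starts from the steady-state filter initial
conditions for a step of the first sample's height — this makes the
output exactly offset-invariant and a constant input map to zero. The
instantaneous phase is the argument of the FFT-based analytic signal
(implemented here directly on `stats::fft`, the standard one-sided
spectrum doubling), unwrapped; the angular velocity is its central
difference (one-sided at the ends) and the instantaneous period
`2π/velocity`. The first 4 and last 3 samples are discarded (a 5–39 h
hourly course retains 9–36 h). A mean angular-velocity profile can be
re-integrated into a unit oscillation via `sin(cumsum(velocity·dt))`.

The band-pass/Hilbert estimate is a *smoothed* period readout: at the
C3→C4 transition the profile ramps over ±2–3 h rather than stepping, so
the package reports the C4 period as the profile's plateau (maximum)
inside C4 — on the default synthetic population this recovers 8.5 h
within 5% while mid-transition values are intermediate by construction.
Single-worm reporter traces (10-min frames) use the band 1/14–1/5
cycles/h; missing frames are linearly interpolated (gap limit 10 h).

First expression peaks in early L1 are located inside a 3–13 h window as
the derivative root of a cubic interpolating spline with the highest
spline value; a windowed trace without any derivative root returns a
typed "no peak" outcome so batch runs continue. Cubic interpolating
splines (`stats::splinefun`, `fmm`) stand in for quartic ones, which
base R does not provide; they reproduce the package's worked examples
(mid-point peaks at equal adjacent values, exact parabola peaks) at the
stated tolerances, and peak positions are refined by `uniroot` on the
spline derivative rather than read off a grid.

## Correlation structure, cycle phase and arrest

Time-point correlation matrices are Pearson correlations of log2
expression columns *without* per-gene mean centering (each coefficient
still centers the columns by definition); uncentered correlations of
positive-valued data stay in [0, 1] and are robust to expression trends.
Per-gene centering is available to demonstrate the expected negative
correlation of antiphase time points. Correlation-line peaks are spline
derivative roots above the window mean of the line; for embryo courses
the dense-interpolation variant (240 points, peaks requiring 5 rising
and 5 falling interpolated points, via `pracma::findpeaks`) is used.

Cycle phase maps each cycle linearly onto 0–360°: the cycle start is 0°
and the next start 360°, so in the default larval map TP14 = 0° and
TP19 = 300°. C4 uses its own longer span so 0°→360° stays anchored to
cycle boundaries. The arrested phase of quiescent samples (adults,
pre-onset larvae, dauer) is estimated by mapping each quiescent time
point's correlation peaks into degrees and taking the circular median;
the 1-h sampling limits resolution to about one map interval, and the
estimate is reported together with the mutual correlations among
quiescent columns (near-identical frozen states correlate > 0.8).

The embryonic onset of oscillations is a two-regime breakpoint: ordinary
least squares on the early (static peak position) and late (progressing)
regimes, intersected at `x* = (b₁−b₂)/(a₂−a₁)`, with the 95% CI from
first-order propagation of the four coefficient standard errors through
that expression (gradient `(1, −1, x*, −x*)/(a₂−a₁)`). The regime
windows are parameters, since which points fall in the inflection zone
is dataset-specific; a parametric-bootstrap cross-check of the CI agrees
within 10% for well-separated regimes, and on generated embryo courses
the true breakpoint falls inside the CI in ≥ 90% of replicates.

## Molting–oscillation coupling

Reporter phases at molt entry and exit are defined per stage:
`θ_entry = 2π·T_IM/T_o` and `θ_exit = 2π·T_L/T_o` with `T_IM` the
intermolt, `T_L` the stage duration, `T_o` the oscillation period.
The measured analogue is the Hilbert unwrapped phase accumulated since
the previous molt exit, which avoids the 0/2π ambiguity of wrapped
phases (the estimator the original analysis used is unstated; unwrapped
within-stage phase is the assumption here). Under independence, the
expected dispersion is `σ = 2π(μ_T/μ_o)√((σ_T/μ_T)²+(σ_o/μ_o)²)`; the
coupling ratio `sd_obs/σ` converges to 1 on independent cohorts and
falls below 1 when molts are phase-locked (on locked synthetic cohorts
it converges to the injected residual noise fraction). L2 and L3 are the
default stages for the ratio, keeping clear of hatch and adult edge
effects. Time-to-phase analysis pairs each worm's time to reach a target
unwrapped phase (e.g. 11 rad late in L2, 18 rad late in L3) with its
molt time; coupled cohorts give Pearson r > 0.9 and an origin-forced
slope near 1.

## Luciferase molt timing

Hatch is the first bin (from bin 4, avoiding edge effects) whose raw
luminescence exceeds the mean + 5 sd of the first 20 bins. Trend
correction divides by a running-median baseline and takes log2; the
default window is 6 h (37 bins at 10-min binning) so that 1–2.5-h molt
troughs are not absorbed into the baseline — a 2-h window would track
the troughs themselves. The prior art's exact trend-correction and
molt-call rules are not public, so this module's rule is a deliberately
simple, fully parameterized stand-in: molts are maximal post-hatch runs
below an *absolute* threshold of −1 log2 (a > 2-fold drop below
baseline, which multi-fold lethargus troughs clear easily while noise
does not, independent of molt occupancy), with runs ≥ 30 min and gaps
≤ 20 min merged; a quantile threshold is available as an option.
Durations follow the exit-to-exit convention: stage = current molt exit
− previous molt exit (hatch for L1), intermolt = stage − molt, so
stage = molt + intermolt holds identically. Distribution comparisons use
Welch's two-sample two-sided t-test.

## The bifurcation model

The two-variable model
`dx/dt = x(β−x²−y²) − 2πy(1−λy)`, `dy/dt = y(β−x²−y²) + 2πx(1−λy)`
(polar: `dr/dt = r(β−r²)`, `dθ/dt = 2π(1−λr sinθ)`) oscillates for
β > 0 and |λr| < 1, with limit-cycle radius √β and period
`T = 1/√(1−βλ²)`. Raising λ toward 1 slows the phase near θ = π/2 until
a fixed point is born *on* the cycle (SNIC): the period diverges while
the amplitude stays put, and the arrested state is a specific phase —
the dynamical signature matching the expression oscillator's arrest.
Lowering β through 0 instead kills the oscillation by amplitude decay at
constant period (supercritical Hopf). Defaults are β = 1, λ = 0.

Numerical choices: deterministic paths use `deSolve::lsoda` at
rtol = atol = 1e-8; stochastic paths use Euler–Maruyama with dt = 1e-3
and additive white noise of equal, user-set sd on both state variables
(the noise amplitude is a free parameter; 0.05 is used in the package's
stochastic contrasts). Ramps are linear with clipping: β(t) is capped at
1 when ramped upward and λ(t) floored at 0. Slowly ramped Hopf runs
start at r = 10⁻⁵ (deterministic) or r = 0 (stochastic), θ₀ = π/2, and
the limit cycle counts as reached when |dr/dt − k_β| < φ with φ = 0.01;
SNIC ramps start on the cycle at r₀ = 1, θ₀ = π/2. Periods and
amplitudes are measured from interpolated upward zero crossings of x and
the per-cycle maximum radius. Near the SNIC point the approach to the
bottleneck is algebraic (~1/t), so "halt" assertions use long horizons
and finite tolerances. Across seeds, stochastic Hopf onsets reach the
cycle at circularly dispersed phases while stochastic SNIC onsets resume
rotation concentrated near θ = π/2 — the package asserts this contrast
statistically over 100 seeds per scenario.

## Synthetic data: what it emulates, and what not

All generators are pure functions of a spec that includes the seed, and
they restore the caller's RNG state.

The **population generator** drives every oscillating gene from one
global phase Φ(t): angular velocity 2π/7 rad/h from onset (5 h) to 27 h,
2π/8.5 rad/h in C4, zero before onset and after the arrest hold; the
hold starts at the last crossing of the 300° cycle phase before 37 h
(~34.1 h with the defaults), so the pre-onset and adult plateaus sit at
the arrest phase. Genes get uniform peak phases, log2 amplitudes uniform
on [0.7, 2], means uniform on [6, 10], i.i.d. Gaussian log2 noise
(sd 0.2), 25% oscillating among 2000 genes, and 10% of oscillating genes
carry a +5 log2 mean shift in C4 (the L4-deviating class). These
defaults are the study conditions for all calibration checks.

The **embryo generator** produces columns whose expression state tracks
a larval target time point: nearly constant (≈14 h) with linearly
growing amplitude before the 380-min breakpoint, then progressing at the
late-regime slope; the regime lines default to the worked-example
coefficients. The **worm-cohort generator** gives each worm its own
period (Normal(7, 0.3²) h) and either locks molt events to oscillator
phases plus a 0.1-rad residual (coupled) or draws intermolt/molt
durations independently with matched marginals (uncoupled: intermolt
Normal(6, 0.4²) h, molt Normal(2, 0.2²) h). The **luminescence
generator** emulates a 42-h assay at 10-min bins: baseline 10 a.u.,
hatch step to 100 a.u. at ~5 h (hatch must fall beyond the 20-bin
baseline window for the detection rule to be meaningful), 1.5%/h
exponential growth, 5-fold troughs during four scheduled molts, additive
noise.

What passing tests on these data do **not** show: the generators are
sinusoidal with i.i.d. Gaussian noise in log2 space — real expression
oscillations are non-sinusoidal for many genes, noise is
heteroskedastic and count-based, population synchrony decays over time,
and real cohorts contain missing frames, arrests and outlier animals.
Recovery of ground truth here validates the *implementations*, not the
biological detection power on real data; dataset-dependent headline
numbers (absolute gene counts, tissue folds, real-data correlation
levels) require the deposited expression datasets and are out of scope.

## Problem sizes and runtime

The shipped tests use 300–2000-gene populations, 30-worm cohorts,
12-animal luminescence sets, 20-replicate breakpoint coverage and
100-seed stochastic contrasts; the full suite runs in about a minute on
one CPU, and `scripts/acceptance.R` (10,000-gene noise calibration,
200×1000-worm null, 100-trace period pipeline) in seconds.

## Known limitations

* The amplitude CI ignores coefficient covariance and uses normal (not
  t) quantiles, exactly mirroring the stated propagation procedure.
* The Hilbert period profile smooths period transitions (see above); the
  C4 readout is the plateau value, and values within ±2–3 h of a regime
  change are intermediate.
* The arrest-phase estimate inherits the 1-h sampling resolution.
* The luciferase molt caller is a documented stand-in with tunable
  parameters, not a reproduction of the cited prior algorithm.
* `phase_agreement`'s R² follows the phase-comparison convention of the
  field and is not comparable to a regression R².
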
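# shared helpers and tiny independent oracles used across test files

circ_var <- function(th) 1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)

circ_mean_rad <- function(th) atan2(mean(sin(th)), mean(cos(th)))

# Monte-Carlo propagation oracle for the amplitude standard error:
# draw (A, B) from independent normals and take the sd of sqrt(A^2 + B^2)
mc_amplitude_sd <- function(A, B, seA, seB, n = 1e5) {
  a <- stats::rnorm(n, A, seA)
  b <- stats::rnorm(n, B, seB)
  stats::sd(sqrt(a^2 + b^2))
}

# direct wrapped-Gaussian-kernel density oracle on the circle (degrees)
wrapped_kernel_density <- function(phases, at, bw) {
  sapply(at, function(x) {
    d <- abs((phases - x + 180) %% 360 - 180)
    mean(stats::dnorm(d, 0, bw))
  })
}
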
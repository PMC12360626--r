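# shared fixtures built in code

# a sweep set holding pure noise-free kernels at known onsets (ms re flash)
kernel_sweeps <- function(onsets_ms, amplitudes, tau_rise = 0.5,
                          tau_decay = 5, sample_rate = 20000,
                          sweep_duration = 0.12, stim_time = 0.055,
                          n_sweeps = 1) {
  n <- round(sweep_duration * sample_rate)
  t_ms <- ((seq_len(n) - 1) / sample_rate - stim_time) * 1000
  sweep <- numeric(n)
  for (j in seq_along(onsets_ms)) {
    sweep <- sweep + epsc_kernel(t_ms - onsets_ms[j], amplitudes[j],
                                 tau_rise, tau_decay)
  }
  sweep_set(replicate(n_sweeps, sweep, simplify = FALSE),
            sample_rate = sample_rate, stim_time = stim_time)
}

flat_sweeps <- function(level = 0, n_sweeps = 2, n = 2000,
                        sample_rate = 20000, stim_time = 0.055) {
  sweep_set(matrix(level, n_sweeps, n), sample_rate, stim_time)
}

# closed-form derivative of the Gaussian-filtered dual-exponential kernel:
# the filtered exponential step exp(-t/tau) H(t) * N(0, sigma) is
# 0.5 exp(sigma^2/(2 tau^2) - t/tau) erfc((sigma/tau - t/sigma)/sqrt(2))
filtered_kernel_deriv <- function(t, amplitude, tau_rise = 0.5,
                                  tau_decay = 5, cutoff = 1000) {
  sig <- sqrt(log(2)) / (2 * pi * cutoff) * 1000    # ms
  erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  fexp <- function(t, tau) {
    0.5 * exp(sig^2 / (2 * tau^2) - t / tau) *
      erfc((sig / tau - t / sig) / sqrt(2))
  }
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  eta <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  -(amplitude / eta) *
    (fexp(t, tau_rise) / tau_rise - fexp(t, tau_decay) / tau_decay)
}

# latencies drawn from a two-Gaussian mixture (equal weights)
mixture_latencies <- function(n, mu = c(2.5, 6.5), sigma = c(0.7, 1.5),
                              w = 0.5) {
  comp <- stats::rbinom(n, 1, 1 - w) + 1
  stats::rnorm(n, mu[comp], sigma[comp])
}

# brute-force minimum of an equal-weight normal mixture density on [mu1, mu2]
mixture_min <- function(mu = c(2.5, 6.5), sigma = c(0.7, 1.5), w = 0.5) {
  grid <- seq(mu[1], mu[2], by = 1e-4)
  dens <- w * stats::dnorm(grid, mu[1], sigma[1]) +
    (1 - w) * stats::dnorm(grid, mu[2], sigma[2])
  grid[which.min(dens)]
}
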
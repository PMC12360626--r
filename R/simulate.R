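#' Dual-exponential EPSC kernel
#'
#' The canonical synaptic current waveform
#' `k(t) = -A (exp(-t/tau_decay) - exp(-t/tau_rise)) / eta` for `t >= 0`
#' (0 before onset), normalised by `eta` so the minimum is exactly `-A`.
#' `kernel_peak_time()` gives the closed-form time of that minimum,
#' `tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`;
#' `kernel_derivative()` is the closed-form first derivative in pA/ms, and
#' `kernel_peak_slope()` its extremum magnitude `A (1/tau_r - 1/tau_d)/eta`,
#' attained at onset. These closed forms serve as independent oracles for
#' the detection pipeline.
#'
#' @param t Times in ms relative to event onset.
#' @param amplitude Peak amplitude A in pA (magnitude; the waveform is
#'   inward, i.e. negative).
#' @param tau_rise,tau_decay Rise and decay time constants in ms;
#'   `tau_decay > tau_rise > 0`.
#' @return `epsc_kernel()` and `kernel_derivative()` return numeric vectors
#'   (pA and pA/ms); the others return scalars (ms, pA/ms).
#' @examples
#' kernel_peak_time(0.5, 5)          # ~1.279 ms
#' epsc_kernel(kernel_peak_time(0.5, 5), 100, 0.5, 5)  # -100
#' @export
epsc_kernel <- function(t, amplitude, tau_rise = 0.5, tau_decay = 5) {
  check_taus(tau_rise, tau_decay)
  eta <- kernel_norm(tau_rise, tau_decay)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- -amplitude *
    (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / eta
  out
}

check_taus <- function(tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    abort("Need tau_decay > tau_rise > 0.")
  }
}

kernel_norm <- function(tau_rise, tau_decay) {
  tp <- kernel_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' @rdname epsc_kernel
#' @export
kernel_peak_time <- function(tau_rise = 0.5, tau_decay = 5) {
  check_taus(tau_rise, tau_decay)
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' @rdname epsc_kernel
#' @export
kernel_derivative <- function(t, amplitude, tau_rise = 0.5, tau_decay = 5) {
  check_taus(tau_rise, tau_decay)
  eta <- kernel_norm(tau_rise, tau_decay)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- -amplitude *
    (exp(-t[pos] / tau_rise) / tau_rise - exp(-t[pos] / tau_decay) / tau_decay) / eta
  out
}

#' @rdname epsc_kernel
#' @export
kernel_peak_slope <- function(amplitude, tau_rise = 0.5, tau_decay = 5) {
  check_taus(tau_rise, tau_decay)
  amplitude * (1 / tau_rise - 1 / tau_decay) / kernel_norm(tau_rise, tau_decay)
}

#' Simulation configuration
#'
#' Full parameterisation of the synthetic claustrocortical compound-oEPSC
#' generator. Defaults emulate the recorded circuit's baseline statistics:
#' 20 kHz sampling, a 1 ms-resolvable dual-exponential kernel (rise 0.5 ms,
#' decay 5 ms), a stimulus-locked monosynaptic event (release probability
#' 0.9, latency 2.5 +/- 0.4 ms, ~600 pA) and a recurrent polysynaptic
#' Poisson barrage (base rate 2.1 events/sweep coupled to realised
#' monosynaptic drive, latency 6.5 +/- 1.5 ms, ~150 pA per event), so the
#' expected ground-truth rate is about 2.8 events/episode. Drug scaling is
#' receptor-specific: `mono_scale` multiplies the monosynaptic release
#' probability (kappa-opioid action on the direct input, which silences the
#' coupled recurrent drive with it) and `poly_scale` multiplies the
#' recurrent rate (mu/delta action). Condition presets: `"ttx"` removes all
#' events; `"ttx_4ap"` removes recurrent events and scales monosynaptic
#' amplitude by `restoration` (default 0.3, partial recovery of the direct
#' response).
#'
#' @param sample_rate Hz.
#' @param sweep_duration Sweep length in s.
#' @param stim_time Flash time in s from sweep start.
#' @param n_sweeps Number of sweeps (episodes).
#' @param kernel List: `tau_rise`, `tau_decay` (ms).
#' @param mono List: `prob`, `amp_mean`, `amp_sd` (pA), `latency_mean`,
#'   `latency_sd` (ms re flash).
#' @param poly List: `rate` (mean events/sweep at unit drive), `amp_mean`,
#'   `amp_sd`, `latency_mean`, `latency_sd`, `coupling` (exponent linking
#'   realised monosynaptic drive to the recurrent rate).
#' @param noise List: `sd` (pA), `pink_fraction` (share of noise power with
#'   a 1/f spectrum; 0 disables).
#' @param drug List: `receptor` (`"none"`, `"KOR"`, `"MOR"`, `"DOR"`),
#'   `mono_scale`, `poly_scale` in `[0, 1]`.
#' @param condition_preset `"baseline"`, `"agonist"`, `"ttx"`, `"ttx_4ap"`.
#' @param restoration Monosynaptic amplitude fraction retained under
#'   `"ttx_4ap"`.
#' @param seed Integer seed; all randomness flows from it through one
#'   deterministic per-sweep stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(sample_rate = 20000,
                       sweep_duration = 0.12,
                       stim_time = 0.055,
                       n_sweeps = 20,
                       kernel = list(),
                       mono = list(),
                       poly = list(),
                       noise = list(),
                       drug = list(),
                       condition_preset = c("baseline", "agonist",
                                            "ttx", "ttx_4ap"),
                       restoration = 0.3,
                       seed = 1L) {
  condition_preset <- match.arg(condition_preset)
  kernel <- modifyList(list(tau_rise = 0.5, tau_decay = 5), kernel)
  mono <- modifyList(list(prob = 0.9, amp_mean = 600, amp_sd = 150,
                          latency_mean = 2.5, latency_sd = 0.4), mono)
  poly <- modifyList(list(rate = 2.1, amp_mean = 150, amp_sd = 60,
                          latency_mean = 6.5, latency_sd = 1.5,
                          coupling = 1), poly)
  noise <- modifyList(list(sd = 5, pink_fraction = 0), noise)
  drug <- modifyList(list(receptor = "none", mono_scale = 1, poly_scale = 1),
                     drug)
  check_taus(kernel$tau_rise, kernel$tau_decay)
  stopifnot(mono$prob >= 0, mono$prob <= 1,
            drug$mono_scale >= 0, drug$mono_scale <= 1,
            drug$poly_scale >= 0, drug$poly_scale <= 1,
            poly$rate >= 0, noise$sd >= 0,
            noise$pink_fraction >= 0, noise$pink_fraction <= 1,
            n_sweeps >= 1, sample_rate > 0,
            stim_time > 0, stim_time < sweep_duration,
            restoration >= 0, restoration <= 1)
  if (!drug$receptor %in% c("none", "KOR", "MOR", "DOR")) {
    abort("`drug$receptor` must be one of none, KOR, MOR, DOR.")
  }
  structure(list(sample_rate = sample_rate, sweep_duration = sweep_duration,
                 stim_time = stim_time, n_sweeps = n_sweeps, kernel = kernel,
                 mono = mono, poly = poly, noise = noise, drug = drug,
                 condition_preset = condition_preset,
                 restoration = restoration, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-sweep seed stream, kept below 2^31
sweep_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 16807) %% 2147483647
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
    tries <- tries + 1L
  }
  out[out < lower] <- lower
  out
}

pink_noise <- function(n) {
  spec <- stats::fft(rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a compound-oEPSC sweep set
#'
#' Draws stimulus-locked monosynaptic and recurrent polysynaptic events per
#' sweep under the configured condition and drug scaling, renders each as a
#' dual-exponential kernel, adds recording noise, and returns both the
#' [sweep_set()] and the injected ground truth. Monosynaptic latencies are
#' truncated at 0.5 ms and polysynaptic events always follow the sweep's
#' monosynaptic event, so no event is acausal. The recurrent Poisson rate
#' is `rate * poly_scale * (realised mono amplitude / amp_mean)^coupling`,
#' zero on sweeps without a monosynaptic event — recurrent excitation needs
#' the direct input to fire. The same seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @param cell_id Label for the generated cell.
#' @param condition,drug_label Labels stamped on the sweep set; defaults
#'   follow the preset and receptor.
#' @return List with `sweeps` (a `sweep_set`) and `truth` (tibble:
#'   `sweep_index`, `pathway`, `onset_ms` re flash, `amplitude` pA,
#'   `peak_slope` pA/ms from the closed-form kernel derivative).
#' @export
simulate_sweeps <- function(config, cell_id = "sim",
                            condition = NULL, drug_label = "none") {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  n <- round(config$sweep_duration * fs)
  t_ms <- ((seq_len(n) - 1) / fs - config$stim_time) * 1000
  kr <- config$kernel$tau_rise; kd <- config$kernel$tau_decay
  mono <- config$mono; poly <- config$poly; drug <- config$drug
  preset <- config$condition_preset

  mono_prob <- mono$prob * drug$mono_scale
  mono_amp_scale <- 1
  poly_on <- TRUE
  if (preset == "ttx") { mono_prob <- 0; poly_on <- FALSE }
  if (preset == "ttx_4ap") {
    mono_prob <- mono$prob              # direct release restored by 4-AP
    mono_amp_scale <- config$restoration
    poly_on <- FALSE                    # spiking still blocked
  }

  sim_one <- function(k) {
    withr::with_seed(sweep_seed(config$seed, k), {
      ev <- list()
      mono_amp_real <- 0
      mono_lat <- Inf
      if (runif(1) < mono_prob) {
        mono_lat <- rnorm_trunc(1, mono$latency_mean, mono$latency_sd, 0.5)
        amp <- rnorm_trunc(1, mono$amp_mean, mono$amp_sd,
                           0.1 * mono$amp_mean)
        mono_amp_real <- amp
        ev[[length(ev) + 1L]] <-
          tibble(pathway = "mono", onset_ms = mono_lat,
                 amplitude = amp * mono_amp_scale)
      }
      if (poly_on && mono_amp_real > 0) {
        drive <- (mono_amp_real / mono$amp_mean)^poly$coupling
        n_poly <- rpois(1, poly$rate * drug$poly_scale * drive)
        if (n_poly > 0) {
          lats <- rnorm_trunc(n_poly, poly$latency_mean, poly$latency_sd,
                              mono_lat + 0.1)
          amps <- rnorm_trunc(n_poly, poly$amp_mean, poly$amp_sd,
                              0.1 * poly$amp_mean)
          ev[[length(ev) + 1L]] <-
            tibble(pathway = "poly", onset_ms = lats, amplitude = amps)
        }
      }
      truth <- if (length(ev)) bind_rows(ev) else
        tibble(pathway = character(), onset_ms = numeric(),
               amplitude = numeric())
      sweep <- numeric(n)
      if (nrow(truth) > 0) {
        for (j in seq_len(nrow(truth))) {
          sweep <- sweep + epsc_kernel(t_ms - truth$onset_ms[j],
                                       truth$amplitude[j], kr, kd)
        }
      }
      if (config$noise$sd > 0) {
        pf <- config$noise$pink_fraction
        white <- rnorm(n)
        nz <- if (pf > 0) {
          sqrt(1 - pf) * white + sqrt(pf) * pink_noise(n)
        } else white
        sweep <- sweep + config$noise$sd * nz
      }
      list(sweep = sweep, truth = truth)
    })
  }

  sims <- lapply(seq_len(config$n_sweeps), sim_one)
  rs0 <- withr::with_seed(sweep_seed(config$seed, 0L),
                          runif(1, 4, 8))
  rs <- rs0 * (1 + seq(0, 0.03, length.out = config$n_sweeps))
  if (is.null(condition)) {
    condition <- switch(preset, baseline = "baseline", agonist = "agonist",
                        ttx = "ttx", ttx_4ap = "ttx_4ap")
  }
  sweeps <- sweep_set(lapply(sims, `[[`, "sweep"),
                      sample_rate = fs, stim_time = config$stim_time,
                      cell_id = cell_id, condition = condition,
                      drug = drug_label, series_resistance = rs)
  truth <- bind_rows(lapply(seq_along(sims), function(k) {
    tr <- sims[[k]]$truth
    if (nrow(tr) == 0) return(NULL)
    tr$sweep_index <- k
    tr
  }))
  if (is.null(truth) || nrow(truth) == 0) {
    truth <- tibble(sweep_index = integer(), pathway = character(),
                    onset_ms = numeric(), amplitude = numeric())
  }
  truth$peak_slope <- kernel_peak_slope(truth$amplitude, kr, kd)
  list(sweeps = sweeps,
       truth = truth[c("sweep_index", "pathway", "onset_ms",
                       "amplitude", "peak_slope")])
}

receptor_drug <- c(KOR = "U69", MOR = "DAMGO", DOR = "DPDPE")

#' Simulate a cohort of cells for one receptor
#'
#' Generates `n_cells` baseline/agonist sweep-set pairs with cell-level
#' random effects. KOR cohorts are uniformly monosynaptically dominated
#' (`mono_scale = 0.2` under agonist, matching the observed ~80%
#' suppression of the direct input); MOR and DOR cohorts scale only the
#' recurrent rate (`poly_scale` 0.55) and include a subset of cells with
#' predominantly late (recurrent-driven) responses, so baseline onset
#' latency — and with it the drug's leverage on the peak — varies across
#' cells.
#'
#' @param n_cells Number of cells (>= 3).
#' @param receptor `"KOR"`, `"MOR"` or `"DOR"`.
#' @param seed Integer seed.
#' @param n_sweeps Sweeps per condition per cell.
#' @param noise_sd Recording noise (pA).
#' @return Tibble with one row per cell: `cell_id`, `receptor`,
#'   `mono_weight` (the cell's direct-input weight in (0, 1]), and
#'   list-columns `baseline`, `drug` (sweep sets), `truth_baseline`,
#'   `truth_drug`.
#' @export
preset_cohort <- function(n_cells, receptor = c("KOR", "MOR", "DOR"),
                          seed = 1L, n_sweeps = 30, noise_sd = 5) {
  receptor <- match.arg(receptor)
  if (n_cells < 3) abort("`n_cells` must be at least 3.")
  cell_par <- withr::with_seed(sweep_seed(seed, 10L + n_cells), {
    w <- if (receptor == "KOR") {
      runif(n_cells, 0.85, 1)
    } else {
      # half early-dominated, half late-dominated for latency support
      ifelse(seq_len(n_cells) %% 2 == 0,
             runif(n_cells, 0.6, 1), runif(n_cells, 0.12, 0.3))
    }
    tibble(mono_weight = w,
           amp_re = exp(rnorm(n_cells, sd = 0.2)),
           lat_re = rnorm(n_cells, sd = 0.2))
  })
  scales <- switch(receptor,
                   KOR = list(mono_scale = 0.2, poly_scale = 1),
                   MOR = list(mono_scale = 1, poly_scale = 0.45),
                   DOR = list(mono_scale = 1, poly_scale = 0.5))

  one_cell <- function(i) {
    w <- cell_par$mono_weight[i]
    base_cfg <- function(preset, drug_scales) {
      sim_config(
        n_sweeps = n_sweeps,
        mono = list(prob = 0.9,
                    amp_mean = 600 * w^2 * cell_par$amp_re[i],
                    latency_mean = 2.5 + cell_par$lat_re[i]),
        poly = list(rate = 2.1 * (1.6 - 0.6 * w),
                    amp_mean = 150 * cell_par$amp_re[i] * (2 - w),
                    latency_mean = 6.5 + cell_par$lat_re[i] + (1 - w)),
        noise = list(sd = noise_sd),
        drug = drug_scales,
        condition_preset = preset,
        seed = sweep_seed(seed, 1000L + i * 7L +
                            (preset == "agonist") * 3L))
    }
    id <- sprintf("%s_cell%02d", tolower(receptor), i)
    b <- simulate_sweeps(base_cfg("baseline",
                                  list(receptor = "none")), cell_id = id)
    d <- simulate_sweeps(
      base_cfg("agonist", c(list(receptor = receptor), scales)),
      cell_id = id, drug_label = unname(receptor_drug[receptor]))
    tibble(cell_id = id, receptor = receptor, mono_weight = w,
           baseline = list(b$sweeps), drug = list(d$sweeps),
           truth_baseline = list(b$truth), truth_drug = list(d$truth))
  }
  bind_rows(lapply(seq_len(n_cells), one_cell))
}
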
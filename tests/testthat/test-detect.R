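test_that("central-difference derivative matches slope arithmetic and the closed form", {
  fs <- 20000
  expect_equal(unique(differentiate(flat_sweeps(-30))$current[[1]]), 0)

  # ramp of -1 pA per sample at 20 kHz = -20 pA/ms
  ramp <- sweep_set(list(-(1:400)), fs, 0.001)
  d <- differentiate(ramp)$current[[1]]
  expect_equal(d[2:399], rep(-20, 398))

  # kernel derivative matches the analytic derivative away from onset
  x <- kernel_sweeps(2.5, 300)
  d <- differentiate(x)$current[[1]]
  t_ms <- (sweep_times(x) - stim_time(x)) * 1000 - 2.5   # re kernel onset
  sel <- which(t_ms > 0.3 & t_ms < 20)
  expect_equal(d[sel], kernel_derivative(t_ms[sel], 300),
               tolerance = 0.01)

  expect_error(differentiate(sweep_set(matrix(0, 1, 2), 20000, 1e-5)),
               "3 samples")
})

test_that("a single noise-free kernel yields one event at the right time and slope", {
  A <- 300
  x <- kernel_sweeps(2.5, A)
  ev <- detect_events(differentiate(x))
  expect_equal(nrow(ev), 1)
  dt_ms <- 1000 / sample_rate(x)
  # true argmax of |k'| is the onset; detected within one sample
  expect_lte(abs(ev$latency - 2.5), dt_ms + 1e-12)
  # slope agrees with the closed-form derivative at the detected offset
  expect_equal(ev$max_slope,
               abs(kernel_derivative(ev$latency - 2.5, A)),
               tolerance = 0.01)
  expect_true(all(ev$max_slope >= 50))
  # capture window is attached
  expect_s3_class(ev$capture[[1]], "data.frame")
})

test_that("separated kernels are counted as distinct events", {
  x2 <- kernel_sweeps(c(2.5, 6.5), c(300, 300))
  ev2 <- detect_events(differentiate(x2))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$latency, c(2.5, 6.5), tolerance = 0.1)

  # merging: a large minimum separation folds them into one event
  ev1 <- detect_events(differentiate(x2),
                       detection_settings(min_event_separation = 10))
  expect_equal(nrow(ev1), 1)
})

test_that("detection is translation-equivariant and monotone in amplitude", {
  ev_a <- detect_events(differentiate(kernel_sweeps(c(2.5, 7), c(250, 120),
                                                    stim_time = 0.055)))
  ev_b <- detect_events(differentiate(kernel_sweeps(c(2.5, 7), c(250, 120),
                                                    stim_time = 0.035)))
  expect_equal(ev_a$latency, ev_b$latency)
  expect_equal(ev_a$max_slope, ev_b$max_slope, tolerance = 1e-9)

  # scaling up never loses events
  base <- kernel_sweeps(c(2.5, 7), c(40, 35))
  scaled <- sweep_set(lapply(base$current, `*`, 5), sample_rate(base),
                      stim_time(base))
  n0 <- nrow(detect_events(differentiate(base)))
  n1 <- nrow(detect_events(differentiate(scaled)))
  expect_gte(n1, n0)
})

test_that("pure noise at 10x below threshold rarely triggers events", {
  # slope-noise SD = |threshold|/10: white current noise whose central
  # difference has SD 5 pA/ms at 20 kHz
  fs <- 20000; dt_ms <- 1000 / fs
  sd_current <- 5 * sqrt(2) * dt_ms
  withr::with_seed(99, {
    n_ev <- vapply(1:200, function(i) {
      x <- sweep_set(list(rnorm(2400, sd = sd_current)), fs, 0.055)
      nrow(detect_events(differentiate(x), keep_capture = FALSE))
    }, numeric(1))
  })
  expect_gte(mean(n_ev == 0), 0.99)
})

test_that("detection recovers ground truth at high SNR", {
  cfg <- sim_config(n_sweeps = 60, noise = list(sd = 1),
                    mono = list(amp_mean = 600, amp_sd = 100),
                    poly = list(amp_mean = 200, amp_sd = 40,
                                latency_sd = 2.5, rate = 1),
                    seed = 314)
  s <- simulate_sweeps(cfg)
  ev <- s$sweeps |> lowpass_gaussian() |> differentiate() |>
    detect_events(keep_capture = FALSE)
  truth <- s$truth
  # match detected to true events within 1 ms
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(ev$sweep_index == truth$sweep_index[i] &
          abs(ev$latency - truth$onset_ms[i]) < 1)
  }, logical(1))
  recall <- mean(matched)
  precision <- mean(vapply(seq_len(nrow(ev)), function(i) {
    any(truth$sweep_index == ev$sweep_index[i] &
          abs(truth$onset_ms - ev$latency[i]) < 1)
  }, logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.95)
})

test_that("events per episode is count over sweeps", {
  x <- kernel_sweeps(c(2.5, 6.5), c(300, 300), n_sweeps = 10)
  ev <- detect_events(differentiate(x), keep_capture = FALSE)
  expect_equal(nrow(ev), 20)
  expect_equal(events_per_episode(ev), 2)
  expect_equal(events_per_episode(ev, window = c(0, 4)), 1)
  none <- ev[0, ]
  expect_equal(events_per_episode(none, n_episodes = 10), 0)
  expect_error(events_per_episode(none, n_episodes = 0), "zero")
})

test_that("settings invariants are enforced", {
  expect_error(detection_settings(threshold = 50), "negative")
  expect_error(detection_settings(capture_length = 0), "positive")
  expect_error(detection_settings(detection_window = c(10, 50)),
               "containing 0")
})
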
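test_that("histogram binning is left-closed, right-open with a closed final bin", {
  h <- build_histogram(c(1.0, 1.2, 6.0), bin_width = 0.5)
  expect_equal(h$count[h$bin_left == 1.0], 2)
  expect_equal(h$count[h$bin_left == 6.0], 1)
  expect_equal(sum(h$count), 3)

  empty <- build_histogram(numeric(0))
  expect_true(all(empty$count == 0))

  # the range limit itself lands in the final bin
  h10 <- build_histogram(c(10, 0, 9.99))
  expect_equal(h10$count[length(h10$count)], 2)
  expect_equal(h10$count[1], 1)

  # conservation: in-range latencies are all counted, the rest logged
  withr::with_seed(7, lat <- mixture_latencies(474))
  h474 <- build_histogram(lat)
  expect_equal(sum(h474$count), sum(lat >= 0 & lat <= 10))
  expect_equal(attr(h474, "n_dropped"), sum(lat < 0 | lat > 10))
})

test_that("double-Gaussian fit recovers exact and sampled mixtures", {
  # counts generated exactly from a known double Gaussian
  mids <- seq(0.25, 9.75, by = 0.5)
  p <- list(a1 = 60, mu1 = 2.4, sigma1 = 0.6, a2 = 35, mu2 = 6.8,
            sigma2 = 1.3)
  counts <- p$a1 * exp(-(mids - p$mu1)^2 / (2 * p$sigma1^2)) +
    p$a2 * exp(-(mids - p$mu2)^2 / (2 * p$sigma2^2))
  h <- build_histogram(rep(mids, times = round(counts * 10)))
  h$count <- counts                      # exact, noise-free ordinates
  m <- fit_double_gaussian(h)
  expect_equal(m$mu1, p$mu1, tolerance = 1e-3)
  expect_equal(m$mu2, p$mu2, tolerance = 1e-3)
  expect_equal(m$sigma1, p$sigma1, tolerance = 1e-3)
  expect_equal(m$a2, p$a2, tolerance = 1e-2)
  expect_true(m$mu1 < m$trough && m$trough < m$mu2)

  # sampled well-separated equal components: means within 0.1 ms
  withr::with_seed(11, {
    lat <- mixture_latencies(500, mu = c(2, 7), sigma = c(0.6, 0.6))
  })
  ms <- fit_double_gaussian(build_histogram(lat))
  expect_equal(ms$mu1, 2, tolerance = 0.1)
  expect_equal(ms$mu2, 7, tolerance = 0.1)
})

test_that("unimodal and under-sampled histograms are rejected", {
  withr::with_seed(3, uni <- rnorm(400, 5, 0.8))
  expect_error(fit_double_gaussian(build_histogram(uni)), "bimodality")
  expect_error(fit_double_gaussian(build_histogram(c(2, 2.2, 6, 6.3))),
               "at least 30")
})

test_that("the trough sits at the symmetry point for equal components", {
  mids <- seq(0.25, 9.75, by = 0.5)
  mk_model <- function(a1, a2) {
    counts <- a1 * exp(-(mids - 2)^2 / (2 * 0.6^2)) +
      a2 * exp(-(mids - 7)^2 / (2 * 0.6^2))
    h <- build_histogram(rep(2, 50))
    h$count <- counts
    fit_double_gaussian(h)
  }
  sym <- mk_model(50, 50)
  expect_equal(sym$trough, 4.5, tolerance = 1e-3)

  # heavier early component pushes the trough later than the midpoint;
  # brute-force grid minimum as the oracle
  skew <- mk_model(100, 50)
  grid <- seq(skew$mu1, skew$mu2, by = 1e-4)
  fv <- skew$a1 * exp(-(grid - skew$mu1)^2 / (2 * skew$sigma1^2)) +
    skew$a2 * exp(-(grid - skew$mu2)^2 / (2 * skew$sigma2^2))
  expect_gt(skew$trough, 4.5)
  expect_equal(skew$trough, grid[which.min(fv)], tolerance = 1e-3)
})

test_that("overlapped components give a no-trough error", {
  m <- structure(list(a1 = 50, mu1 = 5, sigma1 = 2, a2 = 50, mu2 = 5.5,
                      sigma2 = 2), class = "latency_split")
  expect_error(find_trough(m), "no trough")
})

test_that("classification splits at the trough with ties going late", {
  expect_equal(classify_latency(c(2.0, 6.0), 4.72), c("early", "late"))
  expect_equal(classify_latency(4.25, 4.25), "late")
  expect_equal(classify_latency(c(1, 2, 3), 4.72),
               rep("early", 3))
  # partition: every latency gets exactly one label
  withr::with_seed(5, lat <- mixture_latencies(200))
  lab <- classify_latency(lat, 4.5)
  expect_equal(sum(lab == "early") + sum(lab == "late"), 200)

  # event-tibble form fills the label column
  ev <- tibble::tibble(latency = c(2, 6), label = "unassigned")
  expect_equal(classify_latency(ev, 4.72)$label, c("early", "late"))
})

test_that("trough recovery tracks the analytic mixture minimum", {
  true_min <- mixture_min()
  withr::with_seed(2024, seeds <- sample.int(1e6, 25))
  errs <- vapply(seeds, function(s) {
    withr::with_seed(s, lat <- mixture_latencies(400))
    m <- tryCatch(fit_double_gaussian(build_histogram(lat)),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    abs(m$trough - true_min)
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.5)
})

test_that("tidy, glance and binning sensitivity expose the fit", {
  withr::with_seed(10, lat <- mixture_latencies(600))
  m <- fit_double_gaussian(build_histogram(lat))
  td <- tidy(m)
  expect_equal(td$term, c("a1", "mu1", "sigma1", "a2", "mu2", "sigma2"))
  gl <- glance(m)
  expect_equal(gl$trough, m$trough)

  sens <- trough_sensitivity(lat)
  expect_equal(nrow(sens), 3)
  finite <- sens$trough[!is.na(sens$trough)]
  expect_gte(length(finite), 2)
  expect_lt(max(finite) - min(finite), 1)
})
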
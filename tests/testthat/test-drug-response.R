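test_that("condition summaries aggregate classified events per episode", {
  x <- kernel_sweeps(c(2.5, 6.5), c(400, 300), n_sweeps = 10)
  ev <- detect_events(differentiate(lowpass_gaussian(x)),
                      keep_capture = FALSE)
  s <- summarize_condition(x, ev, trough = 4.72)
  expect_equal(s$n_episodes, 10)
  expect_equal(s$events_per_episode_early, 1)
  expect_equal(s$events_per_episode_late, 1)
  expect_gt(s$mean_slope_early, s$mean_slope_late)
  expect_gt(s$peak_amplitude, 0)

  # no events: zero rates and undefined slope markers
  none <- ev[0, ]
  s0 <- summarize_condition(x, none, trough = 4.72)
  expect_equal(s0$events_per_episode_early, 0)
  expect_true(is.na(s0$mean_slope_early))
})

test_that("effect table pairs each drug condition with its baseline", {
  mk_sum <- function(cell, cond, drug, peak, onset = 2.5,
                     early = 1, late = 1) {
    tibble::tibble(cell_id = cell, condition = cond, drug = drug,
                   peak_amplitude = peak, onset_latency = onset,
                   events_per_episode_early = early,
                   events_per_episode_late = late,
                   mean_slope_early = 300, mean_slope_late = 150,
                   n_events_early = 10, n_events_late = 10,
                   n_episodes = 10)
  }
  sums <- dplyr::bind_rows(
    mk_sum("c1", "baseline", "none", 800),
    mk_sum("c1", "agonist", "U69", 160, early = 0.2, late = 0.2),
    mk_sum("c2", "baseline", "none", 500, onset = 5.5),
    mk_sum("c2", "agonist", "DAMGO", 500))
  eff <- effect_table(sums)
  expect_equal(nrow(eff), 2)
  expect_equal(eff$pct_reduction[eff$cell_id == "c1"], 80)
  expect_equal(eff$pct_reduction[eff$cell_id == "c2"], 0)
  expect_equal(eff$onset_latency[eff$cell_id == "c2"], 5.5)
  expect_equal(eff$delta_early_rate[eff$cell_id == "c1"], -0.8)

  # antagonist row missing for c2 is fine; missing baseline is not
  expect_error(effect_table(dplyr::filter(sums, condition != "baseline")),
               "baseline")
})

test_that("event ECDFs step correctly and end at 1", {
  ev <- tibble::tibble(condition = "baseline", latency = c(1, 2, 3))
  e <- ecdf_events(ev, n_episodes = 3)
  expect_equal(e$ecdf, c(1, 2, 3) / 3)
  expect_equal(e$cum_events_per_episode, c(1, 2, 3) / 3)

  dup <- tibble::tibble(condition = "baseline", latency = c(2, 2, 5))
  expect_equal(max(ecdf_events(dup, 1)$ecdf), 1)
  expect_error(ecdf_events(dup[0, ]), "No events")

  two <- tibble::tibble(condition = rep(c("baseline", "agonist"), c(4, 2)),
                        latency = c(1, 2, 3, 4, 1.5, 2.5))
  e2 <- ecdf_events(two, n_episodes = c(baseline = 2, agonist = 2))
  expect_equal(dplyr::summarise(dplyr::group_by(e2, condition),
                                top = max(ecdf))$top, c(1, 1))
})

test_that("latency-effect regression matches closed-form OLS cases", {
  d <- tibble::tibble(onset_latency = c(1, 2, 3, 4),
                      pct_reduction = 10 * c(1, 2, 3, 4) + 5)
  r <- suppressWarnings(latency_effect_regression(d))  # exact fit
  expect_equal(r$slope, 10)
  expect_equal(r$intercept, 5)
  expect_equal(r$r_squared, 1)

  flat <- tibble::tibble(onset_latency = c(1, 2, 3, 4),
                         pct_reduction = rep(20, 4))
  rf <- latency_effect_regression(flat)
  expect_equal(rf$slope, 0)
  expect_equal(rf$r_squared, 0)

  expect_error(latency_effect_regression(d[1:2, ]), "3 cells")
  same <- tibble::tibble(onset_latency = rep(2, 5),
                         pct_reduction = rnorm(5))
  expect_error(latency_effect_regression(same), "variance")
})

test_that("Kruskal-Wallis H matches brute-force ranks and kruskal.test", {
  # identical groups: H ~ 0, p ~ 1
  same <- rank_compare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(same$h, 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  # brute-force rank computation on well-separated groups (no ties)
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12))
  rc <- rank_compare(g)
  r <- rank(unlist(g)); n <- 6
  h_brute <- 12 / (n * (n + 1)) *
    (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * (n + 1)
  expect_equal(rc$h, h_brute)

  # independent oracle with ties: stats::kruskal.test
  withr::with_seed(21, {
    v <- round(c(rnorm(8), rnorm(9, 1), rnorm(7, 2)), 1)   # forces ties
    grp <- rep(c("x", "y", "z"), c(8, 9, 7))
  })
  rc2 <- rank_compare(v, grp)
  kt <- kruskal.test(v, factor(grp))
  expect_equal(rc2$h, unname(kt$statistic), tolerance = 1e-12)
  expect_equal(rc2$p_value, kt$p.value, tolerance = 1e-12)

  # Dunn pairwise table covers all pairs with adjusted p-values
  expect_equal(nrow(rc2$pairwise), 3)
  expect_true(all(rc2$pairwise$p_adjusted >= rc2$pairwise$p_value))
  expect_true(all(rc2$pairwise$p_adjusted <= 1))

  expect_error(rank_compare(list(a = c(1, 1), b = c(1, 1))), "identical")
  expect_error(rank_compare(list(a = 1, b = c(1, 2))), "at least two")
})

test_that("null rank comparisons reject at the nominal rate", {
  withr::with_seed(1234, {
    rej <- vapply(1:400, function(i) {
      v <- rnorm(30)
      rank_compare(v, rep(c("a", "b", "c"), each = 10))$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("permuted latency-reduction pairs give uniform p-values", {
  withr::with_seed(77, {
    lat <- runif(16, 2, 7)
    red <- 8 * lat + rnorm(16, sd = 8)
    ps <- vapply(1:300, function(i) {
      latency_effect_regression(
        tibble::tibble(onset_latency = lat,
                       pct_reduction = sample(red)))$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
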
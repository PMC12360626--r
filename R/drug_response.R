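#' Summarise one cell-condition
#'
#' Runs the averaged-trace metrics (peak amplitude, 10%-rise onset latency)
#' and the classified-event statistics (early/late events per episode and
#' mean maximum slopes) for one [sweep_set()] and its detected events. The
#' averaged trace is built filter-then-average with the condition's default
#' leading-sweep omission; events are classified against `trough` and
#' counted within `classification_window`.
#'
#' @param sweeps A [sweep_set()].
#' @param events Event tibble from [detect_events()] on these sweeps.
#' @param trough Early/late boundary in ms (e.g. from
#'   [fit_double_gaussian()]).
#' @param classification_window Latency window (ms) for event counting,
#'   default `c(0, 20)`.
#' @param cutoff Low-pass cutoff (Hz) for the averaged-trace metrics.
#' @param omit_leading Passed to [average_condition()].
#' @return One-row tibble: `cell_id`, `condition`, `drug`,
#'   `peak_amplitude` (pA), `onset_latency` (ms), `events_per_episode_early`
#'   / `_late`, `mean_slope_early` / `_late` (pA/ms; `NA` when a class has
#'   no events), `n_events_early` / `_late`, `n_episodes`.
#' @export
summarize_condition <- function(sweeps, events, trough,
                                classification_window = c(0, 20),
                                cutoff = 1000, omit_leading = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (n_sweeps(sweeps) == 0) abort("Zero episodes; nothing to summarise.")
  trace <- sweeps %>%
    baseline_subtract() %>%
    lowpass_gaussian(cutoff = cutoff) %>%
    average_condition(omit_leading = omit_leading)
  pk <- peak_amplitude(trace)
  onset <- tryCatch(onset_latency(trace), error = function(e) NA_real_)

  ev <- events %>%
    filter(.data$latency >= classification_window[1],
           .data$latency <= classification_window[2]) %>%
    classify_latency(trough)
  n_ep <- n_sweeps(sweeps)
  cls_stats <- function(lbl) {
    sub <- ev[ev$label == lbl, ]
    list(rate = nrow(sub) / n_ep,
         slope = if (nrow(sub)) mean(sub$max_slope) else NA_real_,
         n = nrow(sub))
  }
  e <- cls_stats("early"); l <- cls_stats("late")
  tibble(cell_id = cell_id(sweeps), condition = condition_of(sweeps),
         drug = drug_of(sweeps),
         peak_amplitude = pk$amplitude, onset_latency = onset,
         events_per_episode_early = e$rate, events_per_episode_late = l$rate,
         mean_slope_early = e$slope, mean_slope_late = l$slope,
         n_events_early = e$n, n_events_late = l$n, n_episodes = n_ep)
}

#' Per-cell drug-effect table
#'
#' Joins each cell's drug (and antagonist) condition rows to its baseline
#' row and computes the percent oEPSC reduction from the per-cell peak
#' amplitudes, the baseline onset latency, and the early/late
#' events-per-episode deltas. Percent reduction is computed per cell and
#' never from pooled traces; cells missing an antagonist row are kept
#' (recordings lost during washout are the norm), cells missing a baseline
#' are an error.
#'
#' @param summaries Tibble of [summarize_condition()] rows across cells and
#'   conditions.
#' @return Tibble with one row per cell x non-baseline condition:
#'   `cell_id`, `condition`, `drug`, `pct_reduction`, `onset_latency`
#'   (baseline), `delta_early_rate`, `delta_late_rate`,
#'   `early_rate_baseline`, `late_rate_baseline`.
#' @export
effect_table <- function(summaries) {
  need <- c("cell_id", "condition", "peak_amplitude")
  if (!all(need %in% names(summaries))) {
    abort("`summaries` must contain summarize_condition() rows.")
  }
  base <- summaries %>% filter(.data$condition == "baseline")
  others <- summaries %>% filter(.data$condition != "baseline")
  missing_base <- setdiff(unique(others$cell_id), base$cell_id)
  if (length(missing_base) > 0) {
    abort(sprintf("Cells without a baseline condition: %s",
                  paste(missing_base, collapse = ", ")))
  }
  base_cols <- base %>%
    select("cell_id",
           baseline_peak = "peak_amplitude",
           onset_latency_baseline = "onset_latency",
           early_rate_baseline = "events_per_episode_early",
           late_rate_baseline = "events_per_episode_late")
  others %>%
    left_join(base_cols, by = "cell_id") %>%
    mutate(pct_reduction = 100 * (1 - .data$peak_amplitude /
                                    .data$baseline_peak),
           delta_early_rate = .data$events_per_episode_early -
             .data$early_rate_baseline,
           delta_late_rate = .data$events_per_episode_late -
             .data$late_rate_baseline) %>%
    select("cell_id", "condition", "drug", "pct_reduction",
           onset_latency = "onset_latency_baseline",
           "delta_early_rate", "delta_late_rate",
           "early_rate_baseline", "late_rate_baseline")
}

#' Cumulative distributions of event latency by condition
#'
#' Right-continuous empirical CDF of event latency per condition, plus the
#' per-episode cumulative count curve (events accumulated per sweep as a
#' function of latency), the form used to compare drug conditions.
#'
#' @param events Event tibble (possibly several conditions bound together)
#'   with columns `condition`, `latency`.
#' @param n_episodes Named vector (or single number) of episode counts per
#'   condition; defaults to the attribute recorded by [detect_events()].
#' @return Tibble: `condition`, `latency`, `ecdf`,
#'   `cum_events_per_episode`, sorted by latency within condition.
#' @export
ecdf_events <- function(events, n_episodes = NULL) {
  if (nrow(events) == 0) abort("No events; ECDF undefined.")
  n_episodes <- n_episodes %||% attr(events, "n_episodes")
  events %>%
    group_by(.data$condition) %>%
    arrange(.data$latency, .by_group = TRUE) %>%
    mutate(ecdf = row_number() / n(),
           cum_events_per_episode = if (is.null(n_episodes)) NA_real_ else {
             nep <- if (length(n_episodes) > 1)
               n_episodes[[.data$condition[1]]] else n_episodes
             row_number() / nep
           }) %>%
    ungroup() %>%
    select("condition", "latency", "ecdf", "cum_events_per_episode")
}

#' Latency-inhibition regression
#'
#' Ordinary least squares of per-cell percent oEPSC reduction on per-cell
#' baseline onset latency, the test separating receptors acting on the
#' direct input (no latency dependence) from receptors acting on recurrent
#' excitation (inhibition grows with latency). The p-value is the
#' two-sided t test on the slope.
#'
#' @param data Data frame with one row per cell.
#' @param latency_col,reduction_col Column names (strings) for onset
#'   latency (ms) and percent reduction.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
latency_effect_regression <- function(data, latency_col = "onset_latency",
                                      reduction_col = "pct_reduction") {
  x <- data[[latency_col]]
  y <- data[[reduction_col]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 cells for the regression.")
  if (var(x) == 0) abort("Zero latency variance; regression undefined.")
  if (var(y) == 0) {
    # constant response: flat line explains nothing and everything
    return(tibble(slope = 0, intercept = y[1], r_squared = 0,
                  p_value = 1, n = length(x)))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = length(x))
}

#' Analyse a simulated cohort end to end
#'
#' Convenience wrapper running the full per-cell analysis over a
#' [preset_cohort()] tibble: filter, differentiate and detect events in
#' each condition, summarise against the supplied early/late boundary,
#' build the per-cell effect table, and fit the latency-inhibition
#' regression.
#'
#' @param cohort Tibble from [preset_cohort()].
#' @param trough Early/late boundary in ms (default 4.72, the event-level
#'   boundary of the claustrocortical dataset this package models).
#' @param settings [detection_settings()] for event detection.
#' @param cutoff Low-pass cutoff in Hz.
#' @return List with `summaries` (per cell x condition), `effects`
#'   (per-cell drug rows from [effect_table()]), and `regression` (from
#'   [latency_effect_regression()]).
#' @export
analyze_cohort <- function(cohort, trough = 4.72,
                           settings = detection_settings(), cutoff = 1000) {
  summaries <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    one <- function(sw) {
      ev <- sw %>% baseline_subtract() %>% lowpass_gaussian(cutoff) %>%
        differentiate() %>% detect_events(settings, keep_capture = FALSE)
      summarize_condition(sw, ev, trough, cutoff = cutoff)
    }
    bind_rows(one(cohort$baseline[[i]]), one(cohort$drug[[i]]))
  })
  effects <- effect_table(summaries)
  list(summaries = summaries, effects = effects,
       regression = latency_effect_regression(effects))
}

#' Rank-based omnibus and pairwise comparisons
#'
#' Kruskal-Wallis H with tie correction, computed from the rank formulas:
#' `H = [12 / (N(N+1)) * sum(R_g^2 / n_g) - 3(N+1)] / C` with
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups, referred to a
#' chi-squared distribution on `g - 1` degrees of freedom. Pairwise Dunn z
#' statistics use the pooled mean ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt(S * (1/n_i + 1/n_j))` with
#' `S = (N(N+1)/12 - sum(t^3 - t)/(12(N-1)))`, with Bonferroni-adjusted
#' two-sided p-values.
#'
#' @param values Numeric vector of observations, or a list of numeric
#'   vectors (one per group, in which case `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @return A `rank_compare` object: list with `h`, `df`, `p_value`,
#'   `n`, and `pairwise` (tibble: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @examples
#' rank_compare(list(a = c(1, 2, 3), b = c(10, 11, 12)))
#' @export
rank_compare <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    nm <- names(values) %||% paste0("g", seq_along(values))
    groups <- rep(nm, lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2) abort("Need at least two groups.")
  if (any(tab < 2)) abort("Every group needs at least two observations.")
  if (length(unique(values)) == 1L) {
    abort("All values identical; rank statistic degenerate.")
  }
  n_tot <- length(values)
  r <- rank(values)                       # midranks for ties
  glev <- names(tab)
  rank_sums <- vapply(glev, function(g) sum(r[groups == g]), numeric(1))
  n_g <- as.numeric(tab[glev])

  h_raw <- 12 / (n_tot * (n_tot + 1)) * sum(rank_sums^2 / n_g) -
    3 * (n_tot + 1)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  correction <- 1 - tie_sum / (n_tot^3 - n_tot)
  h <- h_raw / correction
  df <- length(glev) - 1L
  p <- pchisq(h, df, lower.tail = FALSE)

  mean_ranks <- rank_sums / n_g
  s2 <- n_tot * (n_tot + 1) / 12 - tie_sum / (12 * (n_tot - 1))
  pairs <- utils::combn(seq_along(glev), 2)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z <- (mean_ranks[i] - mean_ranks[j]) /
      sqrt(s2 * (1 / n_g[i] + 1 / n_g[j]))
    pz <- 2 * pnorm(abs(z), lower.tail = FALSE)
    tibble(group1 = glev[i], group2 = glev[j], z = unname(z),
           p_value = pz, p_adjusted = min(1, pz * n_pairs))
  })
  structure(list(h = h, df = df, p_value = p, n = n_tot,
                 mean_ranks = setNames(mean_ranks, glev),
                 pairwise = pairwise),
            class = "rank_compare")
}

#' @export
print.rank_compare <- function(x, ...) {
  cat(sprintf("<rank_compare> Kruskal-Wallis H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$h, x$df, x$p_value, x$n))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.rank_compare <- function(x, ...) x$pairwise

#' @export
glance.rank_compare <- function(x, ...) {
  tibble(h = x$h, df = x$df, p_value = x$p_value, n = x$n)
}
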
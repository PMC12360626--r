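#' Construct a sweep set
#'
#' A `sweep_set` holds one cell's voltage-clamp sweeps for one recording
#' condition, together with the acquisition metadata every downstream stage
#' needs: the sampling rate, the light-stimulus time, and per-sweep series
#' resistance. It is a tibble with one row per sweep (columns `sweep`,
#' `current` — a list-column of numeric vectors in pA, inward negative —
#' and `series_resistance` in megaohms), so it pipes through dplyr verbs,
#' while the shared scalars live in attributes.
#'
#' Row order is acquisition order; the first-sweeps omission rule of
#' [average_condition()] and the series-resistance increase rule of
#' [qc_series_resistance()] both depend on it.
#'
#' @param sweeps Numeric matrix (`n_sweeps x n_samples`), list of
#'   equal-length numeric vectors, or a data frame with a `current`
#'   list-column. Current in pA, inward currents negative.
#' @param sample_rate Sampling rate in Hz.
#' @param stim_time Light-flash time in seconds from sweep start.
#' @param cell_id Opaque cell identifier.
#' @param condition One of `"baseline"`, `"agonist"`, `"antagonist"`,
#'   `"ttx"`, `"ttx_4ap"`, `"custom"`.
#' @param drug One of `"U69"`, `"DAMGO"`, `"DPDPE"`, `"nor-BNI"`, `"CTAP"`,
#'   `"TIPPpsi"`, `"none"`.
#' @param series_resistance Optional per-sweep series resistance (megaohms).
#' @param inter_sweep_interval Seconds between stimuli (metadata; 30 s
#'   in the standard protocol).
#' @param holding_potential Holding potential in mV (metadata; nominally -65).
#'
#' @return A `sweep_set` tibble.
#' @examples
#' x <- sweep_set(matrix(rnorm(3 * 200), nrow = 3),
#'                sample_rate = 20000, stim_time = 0.005)
#' n_sweeps(x)
#' @export
sweep_set <- function(sweeps, sample_rate, stim_time,
                      cell_id = "cell",
                      condition = c("baseline", "agonist", "antagonist",
                                    "ttx", "ttx_4ap", "custom"),
                      drug = c("none", "U69", "DAMGO", "DPDPE",
                               "nor-BNI", "CTAP", "TIPPpsi"),
                      series_resistance = NULL,
                      inter_sweep_interval = 30,
                      holding_potential = -65) {
  condition <- match.arg(condition)
  drug <- match.arg(drug)

  if (is.matrix(sweeps)) {
    current <- lapply(seq_len(nrow(sweeps)), function(i) as.numeric(sweeps[i, ]))
  } else if (is.data.frame(sweeps)) {
    if (!"current" %in% names(sweeps)) {
      abort("`sweeps` data frame must have a `current` list-column.")
    }
    current <- lapply(sweeps$current, as.numeric)
    if (is.null(series_resistance) && "series_resistance" %in% names(sweeps)) {
      series_resistance <- sweeps$series_resistance
    }
  } else if (is.list(sweeps)) {
    current <- lapply(sweeps, as.numeric)
  } else {
    abort("`sweeps` must be a matrix, list of numeric vectors, or data frame.")
  }
  if (length(current) == 0L) abort("A sweep set needs at least one sweep.")

  lens <- vapply(current, length, integer(1))
  if (length(unique(lens)) != 1L) {
    abort("All sweeps must have identical length (ragged sweep lengths).")
  }
  if (any(vapply(current, function(v) anyNA(v), logical(1)))) {
    abort("Sweeps must not contain missing samples.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  duration <- lens[1] / sample_rate
  if (!is.numeric(stim_time) || length(stim_time) != 1L ||
      stim_time < 0 || stim_time >= duration) {
    abort(sprintf(
      "`stim_time` (%.4g s) must lie within the sweep duration (%.4g s).",
      stim_time, duration))
  }
  if (!is.null(series_resistance)) {
    series_resistance <- as.numeric(series_resistance)
    if (length(series_resistance) != length(current)) {
      abort("`series_resistance` must have one value per sweep.")
    }
  } else {
    series_resistance <- rep(NA_real_, length(current))
  }

  new_sweep_set(
    tibble(sweep = seq_along(current), current = current,
           series_resistance = series_resistance),
    sample_rate = sample_rate, stim_time = stim_time, cell_id = cell_id,
    condition = condition, drug = drug,
    inter_sweep_interval = inter_sweep_interval,
    holding_potential = holding_potential)
}

new_sweep_set <- function(df, sample_rate, stim_time, cell_id, condition,
                          drug, inter_sweep_interval = 30,
                          holding_potential = -65, units = "pA") {
  structure(df,
            class = c("sweep_set", class(tibble())),
            sample_rate = sample_rate, stim_time = stim_time,
            cell_id = cell_id, condition = condition, drug = drug,
            inter_sweep_interval = inter_sweep_interval,
            holding_potential = holding_potential, units = units)
}

# rebuild a sweep_set around new current traces, keeping metadata
replace_current <- function(x, current) {
  df <- tibble(sweep = x$sweep, current = current,
               series_resistance = x$series_resistance)
  new_sweep_set(df, sample_rate(x), stim_time(x), cell_id(x),
                condition_of(x), drug_of(x),
                attr(x, "inter_sweep_interval"),
                attr(x, "holding_potential"),
                units = attr(x, "units") %||% "pA")
}

#' Sweep-set accessors
#'
#' Small helpers reading the shared metadata of a [sweep_set()].
#'
#' @param x A `sweep_set`.
#' @return A scalar (`sample_rate()` in Hz, `stim_time()` in s, labels for
#'   `cell_id()`, `condition_of()`, `drug_of()`, counts for `n_sweeps()` and
#'   `n_samples()`), a numeric matrix for `sweep_matrix()`, or the vector of
#'   sample times in seconds for `sweep_times()`.
#' @name sweep-accessors
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' @rdname sweep-accessors
#' @export
stim_time <- function(x) attr(x, "stim_time")

#' @rdname sweep-accessors
#' @export
cell_id <- function(x) attr(x, "cell_id")

#' @rdname sweep-accessors
#' @export
condition_of <- function(x) attr(x, "condition")

#' @rdname sweep-accessors
#' @export
drug_of <- function(x) attr(x, "drug")

#' @rdname sweep-accessors
#' @export
n_sweeps <- function(x) nrow(x)

#' @rdname sweep-accessors
#' @export
n_samples <- function(x) length(x$current[[1]])

#' @rdname sweep-accessors
#' @export
sweep_matrix <- function(x) do.call(rbind, x$current)

#' @rdname sweep-accessors
#' @export
sweep_times <- function(x) (seq_len(n_samples(x)) - 1) / sample_rate(x)

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> cell %s | %s%s | %d sweeps x %d samples @ %g kHz | stim %g ms\n",
    cell_id(x), condition_of(x),
    if (drug_of(x) != "none") paste0(" (", drug_of(x), ")") else "",
    n_sweeps(x), n_samples(x), sample_rate(x) / 1000, stim_time(x) * 1000))
  invisible(x)
}

#' Series-resistance quality control
#'
#' Applies the whole-cell recording inclusion rule: every sweep's series
#' resistance must stay below `rs_max` and must not rise more than
#' `increase_max` relative to the reference sweep. The relative increase is
#' `(max Rs - reference Rs) / reference Rs`; the reference defaults to the
#' first sweep (acquisition order). When series resistance was not recorded
#' the cell is reported as not assessable rather than passed.
#'
#' @param x A [sweep_set()].
#' @param rs_max Absolute ceiling in megaohms (default 10).
#' @param increase_max Maximum tolerated relative increase (default 0.20).
#' @param reference_sweep Index of the sweep whose Rs anchors the relative
#'   increase (default 1, the first sweep).
#' @return A `qc_report`: a list with `per_sweep` (tibble of `sweep`, `rs`,
#'   `pass`), `max_rs`, `relative_increase`, `assessable`, and `pass`.
#' @examples
#' x <- sweep_set(matrix(0, 3, 100), 20000, 0.002,
#'                series_resistance = c(6, 6, 7.5))
#' qc_series_resistance(x)
#' @export
qc_series_resistance <- function(x, rs_max = 10, increase_max = 0.20,
                                 reference_sweep = 1L) {
  stopifnot(inherits(x, "sweep_set"))
  rs <- x$series_resistance
  if (anyNA(rs)) {
    rep <- list(per_sweep = tibble(sweep = x$sweep, rs = rs,
                                   pass = NA),
                max_rs = NA_real_, relative_increase = NA_real_,
                assessable = FALSE, pass = NA,
                rs_max = rs_max, increase_max = increase_max)
    class(rep) <- "qc_report"
    return(rep)
  }
  if (any(rs <= 0)) abort("Series resistance values must be positive.")
  if (reference_sweep < 1L || reference_sweep > length(rs)) {
    abort("`reference_sweep` out of range.")
  }
  ref <- rs[reference_sweep]
  rel_inc <- (max(rs) - ref) / ref
  per_pass <- rs < rs_max
  pass <- all(per_pass) && rel_inc <= increase_max
  rep <- list(per_sweep = tibble(sweep = x$sweep, rs = rs, pass = per_pass),
              max_rs = max(rs), relative_increase = rel_inc,
              assessable = TRUE, pass = pass,
              rs_max = rs_max, increase_max = increase_max)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  if (!x$assessable) {
    cat("<qc_report> not assessable (series resistance missing)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<qc_report> %s | max Rs %.2f MOhm (limit %g) | increase %.1f%% (limit %g%%)\n",
    if (x$pass) "PASS" else "FAIL", x$max_rs, x$rs_max,
    100 * x$relative_increase, 100 * x$increase_max))
  invisible(x)
}

#' Subtract the pre-stimulus baseline from every sweep
#'
#' Subtracts, per sweep, the mean current over a pre-stimulus window, so the
#' quiescent level sits at 0 pA. The default window is the 50 ms ending 1 ms
#' before the flash (clipped to the sweep start when the pre-stimulus
#' segment is shorter).
#'
#' @param x A [sweep_set()].
#' @param window Length-2 numeric, window in seconds from sweep start. Must
#'   lie within the sweep and end at or before `stim_time`.
#' @return A `sweep_set` whose sweeps have zero mean over `window`.
#' @export
baseline_subtract <- function(x, window = NULL) {
  stopifnot(inherits(x, "sweep_set"))
  st <- stim_time(x)
  if (is.null(window)) {
    hi <- max(st - 0.001, 0)
    window <- c(max(hi - 0.05, 0), hi)
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be an increasing length-2 interval (seconds).")
  }
  if (window[2] > st) {
    abort("Baseline window must end at or before the stimulus time.")
  }
  fs <- sample_rate(x)
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n_samples(x), ceiling(window[2] * fs))
  if (i1 < i0) abort("Baseline window contains no samples.")
  current <- lapply(x$current, function(v) v - mean(v[i0:i1]))
  replace_current(x, current)
}
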
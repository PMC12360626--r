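#' Event-detection settings
#'
#' Bundles the derivative-threshold detector's parameters. Only
#' `threshold`, `min_event_separation`, the capture window and
#' `detection_window` change the results; `time_to_peak` and
#' `peak_measurement_interval` are template metadata carried for provenance
#' with the acquisition software's settings and logged verbatim by
#' [run_pipeline()].
#'
#' @param threshold Derivative threshold in pA/ms (numerically equal to
#'   nA/s); must be negative. Default -50.
#' @param min_event_separation Minimum gap between consecutive events (ms).
#'   0 means any re-crossing opens a new event.
#' @param capture_baseline Milliseconds of pre-crossing context attached to
#'   each event's capture window.
#' @param capture_length Milliseconds of post-crossing capture.
#' @param time_to_peak,peak_measurement_interval Template metadata (ms); no
#'   effect on detection.
#' @param detection_window Length-2 window in ms relative to the flash
#'   within which events are kept. Default `c(-50, 50)`.
#' @return A `detection_settings` list.
#' @export
detection_settings <- function(threshold = -50,
                               min_event_separation = 0,
                               capture_baseline = 1,
                               capture_length = 5,
                               time_to_peak = 0.8,
                               peak_measurement_interval = 0,
                               detection_window = c(-50, 50)) {
  if (!is.numeric(threshold) || threshold >= 0) {
    abort("`threshold` must be negative (inward slope, pA/ms).")
  }
  if (capture_length <= 0) abort("`capture_length` must be positive.")
  if (capture_baseline < 0) abort("`capture_baseline` must be >= 0.")
  if (min_event_separation < 0) abort("`min_event_separation` must be >= 0.")
  if (length(detection_window) != 2L ||
      detection_window[1] >= detection_window[2] ||
      detection_window[1] > 0 || detection_window[2] < 0) {
    abort("`detection_window` must be an increasing interval containing 0.")
  }
  structure(list(threshold = threshold,
                 min_event_separation = min_event_separation,
                 capture_baseline = capture_baseline,
                 capture_length = capture_length,
                 time_to_peak = time_to_peak,
                 peak_measurement_interval = peak_measurement_interval,
                 detection_window = detection_window),
            class = "detection_settings")
}

#' First temporal derivative of every sweep
#'
#' Central-difference derivative scaled to pA/ms (numerically identical to
#' nA/s), with one-sided differences at the endpoints; length is preserved.
#' Run this on filtered sweeps: the standard workflow is filter, then
#' differentiate, then threshold-detect.
#'
#' @param x A [sweep_set()].
#' @return A `sweep_set` whose traces are derivatives in pA/ms.
#' @export
differentiate <- function(x) {
  stopifnot(inherits(x, "sweep_set"))
  if (n_samples(x) < 3L) abort("Need at least 3 samples to differentiate.")
  dt_ms <- 1000 / sample_rate(x)
  deriv1 <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
    d[1] <- (v[2] - v[1]) / dt_ms
    d[n] <- (v[n] - v[n - 1]) / dt_ms
    d
  }
  out <- replace_current(x, lapply(x$current, deriv1))
  attr(out, "units") <- "pA/ms"
  out
}

#' Detect synaptic events by derivative thresholding
#'
#' Scans each derivative trace within the detection window. An event opens
#' when the derivative crosses below `threshold` and closes when it returns
#' above it; below-threshold runs separated by less than
#' `min_event_separation` merge into one event. Each event's latency is the
#' time of its most negative derivative sample relative to the flash, its
#' `max_slope` is that value's magnitude, and a capture window from
#' `capture_baseline` before to `capture_length` after the opening crossing
#' is attached for plotting. Events whose extremum falls outside the
#' detection window are discarded.
#'
#' @param derivs A derivative `sweep_set` from [differentiate()].
#' @param settings A [detection_settings()] object.
#' @param keep_capture Attach per-event capture windows as a list-column?
#'   Set `FALSE` for large simulations.
#' @return Tibble of events: `cell_id`, `condition`, `drug`, `sweep_index`,
#'   `latency` (ms re flash), `max_slope` (pA/ms, magnitude), `label`
#'   (initially `"unassigned"`), and optionally `capture` (list of tibbles
#'   with `time_ms`, `deriv`).
#' @export
detect_events <- function(derivs, settings = detection_settings(),
                          keep_capture = TRUE) {
  stopifnot(inherits(derivs, "sweep_set"),
            inherits(settings, "detection_settings"))
  fs <- sample_rate(derivs)
  dt_ms <- 1000 / fs
  st <- stim_time(derivs)
  n <- n_samples(derivs)
  t_ms <- ((seq_len(n) - 1) / fs - st) * 1000   # ms relative to flash
  win <- settings$detection_window
  in_win <- which(t_ms >= win[1] & t_ms <= win[2])
  if (length(in_win) == 0L) abort("Detection window is outside the sweep.")
  scan0 <- in_win[1]; scan1 <- in_win[length(in_win)]

  one_sweep <- function(v, sweep_index) {
    seg <- v[scan0:scan1]
    below <- seg < settings$threshold
    if (!any(below)) return(NULL)
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev_start <- starts[r$values]
    ev_end <- ends[r$values]
    # merge runs closer than the minimum separation
    if (settings$min_event_separation > 0 && length(ev_start) > 1L) {
      gap_ms <- (ev_start[-1] - ev_end[-length(ev_end)] - 1L) * dt_ms
      grp <- cumsum(c(TRUE, gap_ms >= settings$min_event_separation))
      ev_start <- tapply(ev_start, grp, min)
      ev_end <- tapply(ev_end, grp, max)
    }
    rows <- lapply(seq_along(ev_start), function(k) {
      ii <- ev_start[k]:ev_end[k]
      imin <- ii[which.min(seg[ii])]
      lat <- t_ms[scan0 + imin - 1L]
      if (lat < win[1] || lat > win[2]) return(NULL)
      cap <- NULL
      if (keep_capture) {
        c0 <- max(1L, scan0 + ev_start[k] - 1L -
                    round(settings$capture_baseline / dt_ms))
        c1 <- min(n, scan0 + ev_start[k] - 1L +
                    round(settings$capture_length / dt_ms))
        cap <- tibble(time_ms = t_ms[c0:c1], deriv = v[c0:c1])
      }
      list(sweep_index = sweep_index, latency = lat,
           max_slope = abs(min(seg[ii])), capture = cap)
    })
    rows[!vapply(rows, is.null, logical(1))]
  }

  evs <- purrr::flatten(purrr::map2(derivs$current, derivs$sweep, one_sweep))
  out <- tibble(
    cell_id = cell_id(derivs),
    condition = condition_of(derivs),
    drug = drug_of(derivs),
    sweep_index = vapply(evs, `[[`, numeric(1), "sweep_index"),
    latency = vapply(evs, `[[`, numeric(1), "latency"),
    max_slope = vapply(evs, `[[`, numeric(1), "max_slope"),
    label = rep("unassigned", length(evs)))
  if (keep_capture) out$capture <- lapply(evs, `[[`, "capture")
  attr(out, "n_episodes") <- n_sweeps(derivs)
  attr(out, "settings") <- settings
  out
}

#' Events per episode
#'
#' Mean number of detected events per stimulation sweep, counting events
#' whose latency falls in `window` and dividing by the number of sweeps
#' that contributed to detection.
#'
#' @param events Event tibble from [detect_events()].
#' @param n_episodes Number of sweeps scanned. Defaults to the count
#'   recorded on `events`; pass the source [sweep_set()] instead if the
#'   tibble has been rebuilt.
#' @param window Latency window in ms (default the full detection window
#'   recorded on `events`, else `c(-50, 50)`).
#' @return Events/episode (scalar).
#' @export
events_per_episode <- function(events, n_episodes = NULL, window = NULL) {
  if (inherits(n_episodes, "sweep_set")) n_episodes <- n_sweeps(n_episodes)
  n_episodes <- n_episodes %||% attr(events, "n_episodes")
  if (is.null(n_episodes) || n_episodes <= 0) {
    abort("Number of episodes is missing or zero.")
  }
  if (is.null(window)) {
    s <- attr(events, "settings")
    window <- if (!is.null(s)) s$detection_window else c(-50, 50)
  }
  sum(events$latency >= window[1] & events$latency <= window[2]) / n_episodes
}
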
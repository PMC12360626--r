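#' Low-pass Gaussian filter
#'
#' Convolves every sweep with a Gaussian kernel whose -3 dB frequency is
#' `cutoff`. For a Gaussian impulse response with time-domain standard
#' deviation `sigma`, the transfer magnitude is `exp(-(2*pi*f*sigma)^2/2)`;
#' it equals `1/sqrt(2)` (half power) at `f = cutoff` when
#' `sigma = sqrt(log(2)) / (2*pi*cutoff)`. The discrete kernel is truncated
#' at four standard deviations and renormalised to unit sum, so DC gain is
#' exactly 1; edges are handled by reflection and the output length is
#' unchanged.
#'
#' @param x A [sweep_set()].
#' @param cutoff -3 dB cutoff frequency in Hz (default 1000). Must be below
#'   the Nyquist frequency.
#' @return The filtered `sweep_set`.
#' @export
lowpass_gaussian <- function(x, cutoff = 1000) {
  stopifnot(inherits(x, "sweep_set"))
  fs <- sample_rate(x)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    abort("`cutoff` must be positive and below the Nyquist frequency.")
  }
  kern <- gaussian_kernel(cutoff, fs)
  replace_current(x, lapply(x$current, convolve_reflect, kern = kern))
}

# discrete Gaussian FIR kernel for a -3 dB cutoff (Hz) at sample rate fs
gaussian_kernel <- function(cutoff, fs) {
  sigma_t <- sqrt(log(2)) / (2 * pi * cutoff)   # seconds
  sigma_n <- sigma_t * fs
  half <- max(1L, ceiling(4 * sigma_n))
  k <- dnorm(seq(-half, half), sd = sigma_n)
  k / sum(k)
}

convolve_reflect <- function(v, kern) {
  half <- (length(kern) - 1L) / 2L
  n <- length(v)
  pad <- c(v[(half + 1L):2L], v, v[(n - 1L):(n - half)])
  out <- stats::filter(pad, kern, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Average a condition's sweeps
#'
#' Pointwise mean of the retained sweeps. For agonist and antagonist
#' conditions the first four sweeps are omitted by default so the drug has
#' equilibrated in (or washed out of) the tissue; baseline and other
#' conditions keep every sweep.
#'
#' @param x A [sweep_set()].
#' @param omit_leading Number of leading sweeps to drop before averaging.
#'   Default: 4 for `agonist`/`antagonist` conditions, 0 otherwise.
#' @return An `averaged_trace`: list with `samples` (pA), `sample_rate`,
#'   `stim_time`, `n_sweeps_averaged`, `omitted_leading_sweeps`, and the
#'   source labels.
#' @export
average_condition <- function(x, omit_leading = NULL) {
  stopifnot(inherits(x, "sweep_set"))
  if (is.null(omit_leading)) {
    omit_leading <- if (condition_of(x) %in% c("agonist", "antagonist")) 4L else 0L
  }
  omit_leading <- as.integer(omit_leading)
  if (omit_leading < 0L) abort("`omit_leading` must be non-negative.")
  if (n_sweeps(x) <= omit_leading) {
    abort(sprintf("Cannot omit %d leading sweeps from a %d-sweep set.",
                  omit_leading, n_sweeps(x)))
  }
  keep <- x$current[(omit_leading + 1L):n_sweeps(x)]
  samples <- Reduce(`+`, keep) / length(keep)
  structure(list(samples = samples,
                 sample_rate = sample_rate(x),
                 stim_time = stim_time(x),
                 n_sweeps_averaged = length(keep),
                 omitted_leading_sweeps = omit_leading,
                 cell_id = cell_id(x),
                 condition = condition_of(x),
                 drug = drug_of(x)),
            class = "averaged_trace")
}

#' @export
print.averaged_trace <- function(x, ...) {
  cat(sprintf(
    "<averaged_trace> cell %s | %s%s | mean of %d sweeps (%d omitted)\n",
    x$cell_id, x$condition,
    if (x$drug != "none") paste0(" (", x$drug, ")") else "",
    x$n_sweeps_averaged, x$omitted_leading_sweeps))
  invisible(x)
}

#' @export
as_tibble.averaged_trace <- function(x, ...) {
  tibble(time_s = (seq_along(x$samples) - 1) / x$sample_rate,
         current_pa = x$samples)
}

default_peak_window <- function(trace) {
  c(trace$stim_time, min(trace$stim_time + 0.05,
                         length(trace$samples) / trace$sample_rate))
}

window_indices <- function(trace, window) {
  fs <- trace$sample_rate
  n <- length(trace$samples)
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n, ceiling(window[2] * fs) + 1L)
  if (i1 < i0) abort("Search window contains no samples.")
  i0:i1
}

#' Peak amplitude of an averaged trace
#'
#' Finds the inward (most negative) current within a post-stimulus search
#' window and reports its magnitude in pA, with the time of the peak.
#'
#' @param trace An `averaged_trace` from [average_condition()].
#' @param search_window Length-2 interval in seconds from sweep start;
#'   default `stim_time` to `stim_time + 50 ms`.
#' @return One-row tibble with `amplitude` (pA, magnitude) and
#'   `peak_time_s`.
#' @export
peak_amplitude <- function(trace, search_window = NULL) {
  stopifnot(inherits(trace, "averaged_trace"))
  search_window <- search_window %||% default_peak_window(trace)
  if (search_window[1] < trace$stim_time) {
    abort("`search_window` must start at or after the stimulus.")
  }
  idx <- window_indices(trace, search_window)
  seg <- trace$samples[idx]
  imin <- which.min(seg)
  tibble(amplitude = abs(min(seg, 0)),
         peak_time_s = (idx[imin] - 1) / trace$sample_rate)
}

#' Onset latency at a fractional rise
#'
#' Latency from the light flash to the time the averaged trace first
#' reaches `rise_fraction` of its (signed) peak, with linear interpolation
#' between samples. The canonical setting is the 10% rise point.
#'
#' @inheritParams peak_amplitude
#' @param rise_fraction Fraction of the signed peak that defines onset
#'   (default 0.10).
#' @return Latency in milliseconds.
#' @export
onset_latency <- function(trace, rise_fraction = 0.10, search_window = NULL) {
  stopifnot(inherits(trace, "averaged_trace"))
  if (rise_fraction <= 0 || rise_fraction >= 1) {
    abort("`rise_fraction` must be in (0, 1).")
  }
  search_window <- search_window %||% default_peak_window(trace)
  idx <- window_indices(trace, search_window)
  seg <- trace$samples[idx]
  peak <- min(seg)
  if (peak >= 0) {
    abort("Trace has no inward peak; onset latency is undefined.")
  }
  thr <- rise_fraction * peak          # negative
  below <- which(seg <= thr)
  i <- below[1]
  fs <- trace$sample_rate
  if (i == 1L) {
    t_cross <- (idx[1] - 1) / fs
  } else {
    # linear interpolation between the straddling samples
    y0 <- seg[i - 1L]; y1 <- seg[i]
    frac <- (thr - y0) / (y1 - y0)
    t_cross <- (idx[i - 1L] - 1 + frac) / fs
  }
  (t_cross - trace$stim_time) * 1000
}

#' Percent oEPSC reduction
#'
#' `100 * (1 - peak_drug / peak_baseline)` on condition-averaged traces:
#' 0 for identical responses, 100 for complete block, negative for
#' facilitation.
#'
#' @param baseline,drug `averaged_trace` objects from the same cell.
#' @param search_window Peak search window passed to [peak_amplitude()].
#' @return Percent reduction (scalar).
#' @export
pct_reduction <- function(baseline, drug, search_window = NULL) {
  stopifnot(inherits(baseline, "averaged_trace"),
            inherits(drug, "averaged_trace"))
  if (!isTRUE(all.equal(baseline$stim_time, drug$stim_time))) {
    abort("Baseline and drug traces must share the stimulus time.")
  }
  pb <- peak_amplitude(baseline, search_window)$amplitude
  pd <- peak_amplitude(drug, search_window)$amplitude
  if (pb == 0) abort("Baseline peak is zero; percent reduction undefined.")
  100 * (1 - pd / pb)
}
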
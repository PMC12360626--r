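---
title: "Deconvolving compound oEPSCs: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving compound oEPSCs: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oepsctools)
library(dplyr)
```

## The problem

Optical stimulation of channelrhodopsin-expressing axon terminals evokes,
in a voltage-clamped postsynaptic neuron, a compound inward current: a
short-latency, low-jitter monosynaptic component riding under
longer-latency, higher-jitter polysynaptic events generated by recurrent
excitation in the local circuit. Standard peak-amplitude analysis of the
averaged trace cannot tell these pathways apart, yet presynaptic modulators
(here, the three opioid receptors) can act on either pathway selectively:
kappa-type agonists suppress the direct input — and with it everything the
direct input triggers — while mu- and delta-type agonists preferentially
thin the recurrent component. This package implements the analysis that
makes that dissociation measurable, plus a generative simulator that makes
every stage verifiable against ground truth.

## The deconvolution model

The current evoked by one synaptic event is modelled as a dual-exponential
kernel

$$k(t) = -\frac{A}{\eta}\left(e^{-t/\tau_d} - e^{-t/\tau_r}\right),
\qquad t \ge 0,$$

with rise $\tau_r = 0.5$ ms, decay $\tau_d = 5$ ms, normalised by $\eta$ so
the minimum equals $-A$ (pA). Its peak time
$\tau_r\tau_d/(\tau_d-\tau_r)\,\ln(\tau_d/\tau_r) \approx 1.28$ ms and peak
slope $A(1/\tau_r - 1/\tau_d)/\eta$ have closed forms (`kernel_peak_time()`,
`kernel_peak_slope()`), which the tests use as oracles.

Events are recovered from each sweep, not from the average: the sweep is
low-pass filtered, differentiated (central difference, reported in pA/ms,
numerically identical to nA·s⁻¹), and scanned in a window of −50 to +50 ms
around the flash. An event opens when the derivative crosses below the
threshold (default −50 pA/ms) and closes when it returns above it; its
latency is the time of its most negative derivative sample and its
`max_slope` the magnitude of that sample. We timestamp events at the slope
extremum rather than the threshold crossing because the extremum is the
point tied to synaptic conductance onset rate and is insensitive to the
threshold's exact value; the crossing time shifts with threshold. With the
minimum event separation at its default of 0 ms, any re-crossing opens a
new event; overlapping capture windows are permitted and never merge
events. Two of the detector settings carried in `detection_settings()`
(`time_to_peak`, `peak_measurement_interval`) are template metadata from
the acquisition-software convention: they are logged verbatim for
provenance but have no effect on a pure threshold detector, whose output is
fully determined by threshold, separation, capture and window.

## Filtering and averaged-trace metrics

The low-pass filter is Gaussian with the cutoff interpreted as the −3 dB
point — the common instrumentation meaning — giving
$\sigma_t = \sqrt{\ln 2}/(2\pi f_c)$ (132.5 µs at 1 kHz). The discrete
kernel is truncated at $4\sigma$ and renormalised, so DC gain is exactly 1;
edges are reflected. Filtering and sweep-averaging commute to float
precision; the default order is filter-then-average.

Averaged-trace metrics follow the convention of inward currents being
negative while summaries report magnitudes. Peak amplitude is the most
negative point in a stimulus-to-+50 ms window (the positive half of the
detection window; configurable). Onset latency is the time from flash to
the first crossing of 10% of the signed peak, linearly interpolated between
samples, with ties resolved to the earliest crossing; it is scale-invariant
by construction. For drug and antagonist conditions the first four sweeps
are omitted from the average so the bath has equilibrated; baseline
conditions keep all sweeps. Percent reduction,
$100(1 - \mathrm{peak}_{\mathrm{drug}}/\mathrm{peak}_{\mathrm{base}})$, is
computed per cell and then averaged across cells — never from pooled
traces.

Series-resistance QC enforces the standard whole-cell inclusion rule
(every sweep below 10 MΩ, no more than a 20% rise). The reference for the
relative rise is the first sweep, exposed as a parameter because
acquisition practice varies; missing Rs data yields "not assessable", never
a silent pass.

## The early/late split

In-range event latencies (0–10 ms by default) are binned at 0.5 ms and the
counts fitted with a double Gaussian by least squares
(`minpack.lm::nlsLM`). We fit counts rather than densities because the
histogram is the object of interest and the trough is invariant to
normalisation. Initialisation takes the two highest local maxima of a
3-bin moving average as the component seeds, with σ seeded at the bin
width; ten jittered restarts run from a fixed internal seed and the lowest
SSE wins. Histograms whose smoothed counts lack two local maxima are
rejected explicitly ("no bimodality") rather than fitted badly, and fewer
than 30 in-range events refuses to fit at all. The trough — the argmin of
the fitted curve on $[\mu_1, \mu_2]$, found on a 1 µs grid and refined by
golden-section search — is the classification boundary; latencies below it
are *early*, at or above it *late* (ties go late, a documented convention
that matters only for exact-boundary values). `trough_sensitivity()` refits
at 0.25/0.5/1 ms bins as a standing check that the boundary is not a
binning artefact; the bin width itself is a free parameter because the
underlying histogramming convention of the original workflow is not
determined by the data.

The same machinery serves two splits: the event-level split (derivative
events pooled across cells) and the cell-level split of 10%-rise onset
latencies. They share code because they are the same estimator applied to
different latency sets. Under the default generator the pooled event
trough lands near 4 ms — the analytic minimum of the configured latency
mixture — while `analyze_cohort()`'s default classification boundary of
4.72 ms is the event-level boundary reported for the recorded
claustrocortical dataset this package models; the split is insensitive to
boundary choices between the two modes.

## The generative model

`sim_config()` fixes the study conditions: 20 kHz sampling, 120 ms sweeps
with the flash at 55 ms (leaving the full ±50 ms detection window and a
50 ms baseline window in-sweep), and per sweep:

- a monosynaptic event with release probability 0.9, latency
  $\mathcal N(2.5, 0.4^2)$ ms truncated at 0.5 ms, amplitude
  $\mathcal N(600, 150^2)$ pA truncated at 10% of its mean;
- a polysynaptic count drawn from
  $\mathrm{Poisson}\!\left(\lambda\, s_p\, (A_{\mathrm{mono}}/\bar A)^{c}\right)$
  with base rate $\lambda = 2.1$, coupling $c = 1$, latencies
  $\mathcal N(6.5, 1.5^2)$ ms truncated to follow the sweep's monosynaptic
  event, amplitudes $\mathcal N(150, 60^2)$ pA;
- additive Gaussian noise (5 pA SD; an optional 1/f fraction is available
  and off by default).

Sweeps without a monosynaptic event have no recurrent events — recurrent
excitation requires the direct input to fire. This coupling is the
mechanism behind the kappa signature and the TTX logic, and it makes the
expected ground-truth rate $0.9 + 0.9 \times 2.1 \approx 2.8$
events/episode, the baseline calibration point; the base rate was set to
2.1 (not 2.8/0.9 − 1) precisely so the *coupled* expectation lands at 2.8.
Drug action enters as two scale factors: `mono_scale` multiplies the
release probability (kappa agonists, default preset 0.2, i.e. ~80%
suppression of the direct drive), `poly_scale` multiplies the recurrent
rate (mu 0.45, delta 0.5). `"ttx"` removes all events; `"ttx_4ap"` removes
recurrent events and scales monosynaptic amplitude by 0.3, the partial
direct-pathway recovery seen when terminal depolarisation is restored
pharmacologically. All randomness flows from one seed through a
deterministic per-sweep seed stream, so identical configurations are
bit-identical and individual sweeps are reproducible in isolation.

`preset_cohort()` adds cell-level random effects (log-normal amplitude,
latency jitter) and, for mu/delta cohorts, a late-dominated subpopulation:
half the cells get a direct input too weak to set the 10%-rise onset
(amplitude scaled by the square of a weight drawn in [0.12, 0.3]) and a
correspondingly stronger, later recurrent barrage. This gives the
latency–inhibition regression genuine support across onset latencies, the
way real cohorts include cells dominated by relayed input. Kappa cohorts
are uniformly direct-dominated (weights in [0.85, 1]), so their percent
reduction is latency-independent by construction.

### What the generator does and does not emulate

It reproduces stimulus-locked timing structure, pathway-specific drug
scaling, sweep-to-sweep release stochasticity, recording noise, and the
TTX pharmacology — the features the pipeline's statistics consume. It does
not model conductance-based membrane dynamics, short-term plasticity,
GABAergic currents, electrode artefacts, series-resistance filtering of
fast events, or postsynaptic (e.g. GIRK) effects. Passing tests therefore
demonstrate that the pipeline recovers the statistics of this event-based
model, not that it is robust to every pathology of real recordings; the
compound peak amplitude of the default cell (~500 pA) also sits below
typical recorded means because synchronous polysynaptic summation is
deliberately not tuned up to match it.

## Numerical choices

- Derivatives are central differences with one-sided endpoints. Against a
  discontinuous-onset kernel the discrete slope extremum necessarily sits
  a sample or two after onset and a few percent below the instantaneous
  closed form; the honest reference for testing is the closed-form
  derivative of the *filtered* kernel (erfc-filtered exponential steps),
  which is smooth and matches the detector to a fraction of a sample and
  under 1% in magnitude.
- The 10%-rise crossing interpolates linearly between the straddling
  samples; a true step function therefore reads up to one sample early,
  which is the resolution limit of the definition.
- Histogram bins are left-closed/right-open with a closed final bin, so
  the range's upper limit is counted, and out-of-range latencies are
  dropped with their count recorded.
- Amplitude and latency truncations in the generator use rejection
  sampling with a hard floor after 100 rounds, preventing acausal or
  sign-flipped events without distorting the bulk of the distributions.
- Kruskal–Wallis uses midranks with the standard tie correction; Dunn z
  statistics use the pooled tie-corrected variance and Bonferroni
  adjustment. The implementation is from the rank formulas (the
  transcript-comparison use case needs the pairwise z's), and is checked
  in the tests against both a brute-force rank computation and
  `stats::kruskal.test`.

## Verification sizes and operationalisation

The acceptance checks run at sizes chosen to keep the full suite fast
while leaving comfortable statistical margins: 50 noise-free three-event
sweeps for oracle equivalence (synthesised at 40 kHz so $O(\Delta t^2)$
discretisation does not mask algorithmic error); 1000 pure-noise sweeps at
slope-noise SD of a tenth of threshold (≥99% must be event-free); 100
replicates of 400-event mixtures for trough recovery (≥90% within 0.5 ms
of the analytic mixture minimum, which sits at 4.26 ms for the default
parameters); 20 replicates of 16-cell cohorts per receptor; 1000 null
replicates for rank-test calibration.

Because a per-replicate bound on $r^2$ is meaningless under the null
($r^2 \sim \mathrm{Beta}(\tfrac12, 7)$ at $n = 16$, so values above 0.1
occur in about a third of null replicates), the cohort criteria are
evaluated in aggregate: the kappa cohorts must show median $r^2 < 0.1$ and
both early and late event-rate ratios below 0.5, while mu/delta cohorts
must show a significantly positive latency–reduction slope in at least 75%
of replicates (measured per-replicate power ≈ 0.9), late-rate ratios below
0.9, and early-rate ratios within [0.85, 1.15].

## Limitations

Threshold detection cannot resolve events whose derivative never
re-crosses the threshold between them, so detected events/episode
saturates below the true rate when recurrent events cluster tightly; the
generative ground truth quantifies this gap. Amplitudes of individual
overlapping events are not estimated — that requires template fitting,
which is out of scope. The double-Gaussian split assumes exactly two
latency populations; model selection over component counts is deliberately
not provided. Sweep I/O is plain-text CSV with a key-value sidecar; HDF5
and NWB container support is a declared extension point in
`load_sweeps()`/`save_sweeps()` but not implemented in this build.
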
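Package: oepsctools
Title: Deconvolution and Pharmacological Analysis of Optically Evoked
    Compound EPSCs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing compound optically evoked excitatory
    postsynaptic currents (oEPSCs) recorded in whole-cell voltage clamp.
    Sweeps are low-pass Gaussian filtered, baseline subtracted and
    averaged; each sweep is deconvolved into discrete synaptic events by
    thresholding its first temporal derivative; event and onset latency
    histograms are split into early (monosynaptic) and late
    (polysynaptic) populations via a double-Gaussian fit and its trough;
    and receptor-specific drug effects (percent oEPSC reduction,
    early/late events per episode, event slopes, latency-inhibition
    regression) are quantified per cell. A generative simulator of
    stimulus-locked monosynaptic and recurrent polysynaptic events makes
    every stage testable, and a small module summarises opioid-receptor
    transcript expression over MERFISH-style cell tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
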
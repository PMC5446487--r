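Package: sstosc
Title: Trial-by-Trial Proactive Control in the Stop-Signal Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of proactive control in the stop-signal
    task. Provides a dynamic Bayesian observer that tracks the trial-by-trial
    probability of a stop signal, P(stop), and the Bayesian surprise on stop
    trials; grid-search fitting of the observer to reaction-time sequences;
    a race-model task simulator with a one-up-one-down stop-signal-delay
    staircase; SSRT estimation via a maximum-likelihood inhibition function;
    a single-channel EEG epoch generator with planted oscillatory bursts;
    Morlet wavelet time-frequency decomposition with baseline correction;
    and two-loop brain-behavior statistics (within-subject Spearman z-maps
    by trial permutation, group-level cluster-based permutation tests,
    cluster-power correlations, and condition-mean residualization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
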
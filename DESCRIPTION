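Package: fearext
Title: Simulation and Analysis of Multi-Session Fear-Extinction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-session auditory fear
    conditioning and extinction experiments in rodents. Generates synthetic
    cohorts with planted ground truth (inhomogeneous-Poisson spike trains,
    waveform snippets with inter-session drift, binary immobility traces,
    patch-clamp sweep sets), scores conditioned freezing under the 2-s
    immobility rule, splits animals into successful and poor extinction-recall
    groups by a t-based upper confidence bound, grades single-unit isolation
    (J3, Davies-Bouldin) and cross-session template stability, builds z-scored
    peri-event time histograms in tone-aligned (100-ms bin) and pip-aligned
    (20-ms bin) dialects, classifies fear, extinction and session-selective
    neurons from CS-responsiveness profiles, computes slice-electrophysiology
    metrics (paired-pulse ratio, AMPA/NMDA ratio, miniature-event detection,
    input-output slope, series-resistance QC), and provides the accompanying
    nonparametric statistics battery (exact small-sample Mann-Whitney,
    Kruskal-Wallis, Friedman, Dunn post-hoc with two-stage
    Benjamini-Krieger-Yekutieli FDR, repeated-measures one-way ANOVA with
    Newman-Keuls, two-sample Kolmogorov-Smirnov).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
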
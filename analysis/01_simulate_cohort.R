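#!/usr/bin/env Rscript
# Simulate the basal-amygdala recording cohort: 27 rats, 130 stably recorded
# units with the planted phenotype mix (8 fear, 6 extinction, 21 other
# session-selective responders, 95 unresponsive), pip-aligned CS protocol.
# Writes the raw tables (events, spikes head, freezing, waveform QC) under
# results/cohort/.

suppressPackageStartupMessages(library(fearext))

seed <- 20260929
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(
  n_rats = 27,
  phenotypes = c(fear = 8, extinction = 6, session_selective = 21,
                 non_responsive = 95),
  seed = seed,
  out_dir = out)

message("simulating cohort (this runs the full pipeline once) ...")
bundle <- run_experiment(cfg, verbose = TRUE)

message(sprintf("rats: %d   units simulated: %d   units stable: %d",
                cfg$n_rats, nrow(bundle$unit_qc), sum(bundle$unit_qc$stable)))
message("planted phenotypes:")
print(table(bundle$types$planted))
message(sprintf("tables written under %s/", out))
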
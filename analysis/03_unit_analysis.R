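#!/usr/bin/env Rscript
# Classify the simulated basal-amygdala cohort (run 01 first): per-unit
# CS-responsiveness profiles across recall epochs, fear/extinction typing,
# and the population composition; checks recovery against the planted
# ground truth and runs the within-cell Friedman statistics.

suppressPackageStartupMessages(library(fearext))

res_dir <- "results/cohort"
if (!file.exists(file.path(res_dir, "types.tsv"))) {
  stop("run analysis/01_simulate_cohort.R first")
}
types <- read_tsv(file.path(res_dir, "types.tsv"))
profiles <- read_tsv(file.path(res_dir, "profiles.tsv"))

message("recovered composition (of ", nrow(types), " stable units):")
comp <- cohort_summary(types$label, n_recorded = nrow(types))
print(comp, row.names = FALSE)

agree <- table(planted = types$planted, recovered = types$label)
message("planted vs recovered labels:")
print(agree)
pos <- types$planted %in% c("fear", "extinction")
message(sprintf("fear/extinction recovery: %.1f%%",
                100 * mean(types$label[pos] == types$planted[pos])))

# within-cell response trajectories: Friedman over epochs, blocks = cells
ep_order <- c("Hab", "post-Cond", "post-Ext1", "post-Ext2", "post-Ext3")
for (lab in c("fear", "extinction")) {
  u <- types$unit_id[types$label == lab]
  if (length(u) < 2) next
  sub <- profiles[profiles$unit_id %in% u, ]
  m <- matrix(sub$mean_window_z[order(match(sub$unit_id, u),
                                      match(sub$epoch, ep_order))],
              nrow = length(u), byrow = TRUE, dimnames = list(u, ep_order))
  message(sprintf("%s neurons (n = %d): window z across epochs", lab,
                  length(u)))
  print(round(colMeans(m), 2))
  print(friedman_test(m))
  print(dunn_bky(m, design = "repeated"))
}
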
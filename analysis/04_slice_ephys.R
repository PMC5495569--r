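#!/usr/bin/env Rscript
# Slice-physiology arm: simulate sweep sets per behavioural group with
# planted synaptic parameters, recover every metric (paired-pulse ratio,
# AMPA/NMDA ratio, mIPSC amplitude/frequency, input-output slope), and run
# the across-group Kruskal-Wallis + Dunn battery.  Planted input-output
# slopes follow the reported group means; the other planted values encode
# the qualitative group ordering (transient enhancement after single-session
# extinction, return to baseline with further training).

suppressPackageStartupMessages(library(fearext))

seed <- 20260929
out <- "results/slice"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- list(
  #                 ppr   a/n  mini_amp  io_slope
  naive     = list(0.80, 2.0,       30,     5.28),
  post_Cond = list(0.80, 2.0,       24,     8.79),
  post_Ext1 = list(0.55, 3.5,       36,     6.71),
  post_Ext2 = list(0.80, 2.2,       31,     5.63),
  post_Ext3 = list(0.80, 2.1,       30,     4.68))

n_cells <- 8
metrics <- list()
for (g in names(groups)) {
  pars <- groups[[g]]
  for (cell in seq_len(n_cells)) {
    sdat <- simulate_slice_data(
      list(ppr = pars[[1]], ampa_nmda = pars[[2]], mini_amp_pA = pars[[3]],
           mini_amp_sd_pA = 6, io_slope_pA_per_uA = pars[[4]]),
      seed = substream_seed(seed, "slice", g, cell),
      n_sweeps = 10, noise_sd_pA = 2, duration_s = 60)
    rs_ok <- sweep_qc(vapply(sdat$paired_pulse,
                             function(s) s$series_resistance_Mohm, 1))$keep
    mini <- detect_minis(sdat$continuous$t_ms, sdat$continuous$i_pA,
                         threshold_pA = 10)
    metrics[[length(metrics) + 1]] <- data.frame(
      group = g, cell = cell, rs_keep = rs_ok,
      ppr = paired_pulse_ratio(sdat$paired_pulse)$ratio,
      ampa_nmda = ampa_nmda_ratio(sdat$neg70, sdat$pos50)$ratio,
      mipsc_amp_pA = mini$mean_amplitude_pA,
      mipsc_freq_hz = mini$frequency_hz,
      io_slope = io_slope(sdat$io_series)$slope_pA_per_uA)
  }
}
metrics <- do.call(rbind, metrics)
metrics <- metrics[metrics$rs_keep, ]
write_tsv(metrics, file.path(out, "metrics.tsv"))

message("group means:")
print(aggregate(cbind(ppr, ampa_nmda, mipsc_amp_pA, io_slope) ~ group,
                metrics, function(v) round(mean(v), 2)), row.names = FALSE)

for (m in c("ppr", "ampa_nmda", "io_slope")) {
  g <- split(metrics[[m]], metrics$group)
  message(sprintf("--- %s ---", m))
  print(kruskal_wallis(g))
  print(dunn_bky(g, design = "independent"))
}

# cumulative mIPSC amplitude distributions: KS against the naive group
naive_sd <- simulate_slice_data(list(mini_amp_pA = 30, mini_amp_sd_pA = 6),
                                seed = substream_seed(seed, "ks", "naive"),
                                duration_s = 60, noise_sd_pA = 2)
ext1_sd <- simulate_slice_data(list(mini_amp_pA = 36, mini_amp_sd_pA = 6),
                               seed = substream_seed(seed, "ks", "ext1"),
                               duration_s = 60, noise_sd_pA = 2)
amp_naive <- detect_minis(naive_sd$continuous$t_ms, naive_sd$continuous$i_pA,
                          10)$amplitudes_pA
amp_ext1 <- detect_minis(ext1_sd$continuous$t_ms, ext1_sd$continuous$i_pA,
                         10)$amplitudes_pA
message("mIPSC amplitude distribution, post-Ext1 vs naive:")
print(ks_two_sample(amp_ext1, amp_naive))
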
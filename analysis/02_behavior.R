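#!/usr/bin/env Rscript
# Score conditioned freezing for a 19-rat cohort (14 with a successful-
# extinction trajectory, 5 with a poor one), then split rats at the upper
# 99% confidence bound of post-Ext1 freezing.  Writes freezing and group
# tables under results/behavior/.

suppressPackageStartupMessages(library(fearext))

seed <- 20260929
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plan <- make_session_plan("recording")
profiles <- c(rep("successful", 14), rep("poor", 5))

movement <- do.call(rbind, lapply(seq_along(profiles), function(i) {
  rid <- sprintf("rat%02d", i)
  simulate_freezing(default_rat_params(rid, profiles[i]), plan,
                    substream_seed(seed, "behav", rid))
}))
freezing <- score_freezing_table(movement, plan)
write_tsv(freezing, file.path(out, "freezing.tsv"))

session_means <- aggregate(freezing_pct ~ session, freezing, mean)
session_means <- session_means[match(plan$sessions$label,
                                     session_means$session), ]
message("mean scored freezing per session (%):")
print(session_means, row.names = FALSE)

post_ext1 <- post_ext1_freezing(freezing, plan)
groups <- assign_recall_groups(post_ext1)
write_tsv(groups, file.path(out, "groups.tsv"))
message(sprintf("post-Ext1 threshold (upper 99%% CI bound): %.1f%%",
                groups$threshold_pct[1]))
message(sprintf("successful recall: %d rats   poor recall: %d rats",
                sum(groups$group == "successful"),
                sum(groups$group == "poor")))

# freezing decreases across extinction: Friedman over rats x epochs
ep <- recall_epochs(plan)
recall_mat <- sapply(seq_len(nrow(ep)), function(i) {
  sel <- freezing$session == ep$session[i] &
    freezing$cs_index >= ep$cs_from[i] & freezing$cs_index <= ep$cs_to[i]
  tapply(freezing$freezing_pct[sel], freezing$rat_id[sel], mean)
})
colnames(recall_mat) <- ep$epoch
fr <- friedman_test(recall_mat)
message("freezing across recall epochs: ")
print(fr)
print(dunn_bky(recall_mat, design = "repeated"))
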
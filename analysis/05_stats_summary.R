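#!/usr/bin/env Rscript
# Worked examples of the statistics battery on its documented fixtures plus
# a repeated-measures ANOVA with Newman-Keuls on a simulated population
# z-matrix shaped like the successful-recall group (56 cells x 5 epochs,
# transient elevation at post-Ext1).

suppressPackageStartupMessages(library(fearext))

seed <- 20260929

message("Mann-Whitney, disjoint samples {1,2,3} vs {4,5,6}:")
print(mann_whitney_u(1:3, 4:6))
message("Kruskal-Wallis on {1,2},{3,4},{5,6}:")
print(kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6))))
message("Friedman on three concordantly ordered blocks:")
print(friedman_test(rbind(c(1, 2, 3), c(2, 3, 9), c(0, 5, 6))))
message("Upper 99% confidence bound of {0, 0, 100}:")
print(upper_conf_bound(c(0, 0, 100)))

# 56 cells x 5 recall epochs with a transient post-Ext1 elevation
set.seed(substream_seed(seed, "anova-demo"))
epochs <- c("Hab", "post-Cond", "post-Ext1", "post-Ext2", "post-Ext3")
effect <- c(0, 0, 0.5, 0, 0)
m <- matrix(rnorm(56 * 5), 56, 5, dimnames = list(NULL, epochs)) +
  matrix(rep(effect, each = 56), 56)
res <- rm_anova1(m)
message(sprintf("RM one-way ANOVA, 56 cells x 5 epochs: F(%d,%d) = %.3f, p = %.4f",
                res$df[1], res$df[2], res$statistic$F, res$p_value))
nk <- newman_keuls(res$means, res$ms_error, res$df[2], n = 56)
message("Newman-Keuls pairs involving post-Ext1:")
print(nk[grepl("post-Ext1", nk$pair), ], row.names = FALSE)
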
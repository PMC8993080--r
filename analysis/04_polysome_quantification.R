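#!/usr/bin/env Rscript
# Polysome-profile quantification: percentage of ribosomes in polysomes
# from a UV trace, and spike-in normalized 13-fraction mRNA distributions
# with cumulative curves and the area-above-curve association score,
# compared across the 4 conditions with 4 replicates each.

library(ribokinetics)

dir.create("results/polysome", recursive = TRUE, showWarnings = FALSE)

## UV trace: polysome share of total ribosomes ------------------------------
uv <- simulate_uv_trace(monosome_area = 30, polysome_area = 70,
                        baseline = 0.3, noise_sd = 0.01, seed = 4L)
write_uv_trace(uv, "results/polysome/uv_trace.tsv",
               "results/polysome/uv_regions.yaml")
pct <- polysome_percentage(uv$trace, uv$regions, baseline = 0.3)
cat(sprintf("UV trace: %.1f%% of ribosomes in polysomes (target 70%%)\n", pct))

## fraction distributions: an mRNA shifting out of polysomes in WT ----------
# per-condition target distributions emulate a transcript that loses heavy
# polysomes upon treatment in WT but not in KO
targets <- list(
  WT_control = c(1, 1, 2, 3, 4, 6, 8, 10, 12, 13, 14, 14, 12),
  WT_NCS     = c(4, 6, 9, 12, 14, 13, 11, 9, 8, 6, 4, 2, 2),
  KO_control = c(1, 1, 2, 3, 4, 6, 8, 10, 12, 13, 14, 14, 12),
  KO_NCS     = c(1, 2, 2, 3, 5, 6, 8, 10, 12, 13, 14, 13, 11)
)
scores <- do.call(rbind, lapply(names(targets), function(cond) {
  do.call(rbind, lapply(1:4, function(rep) {
    ct <- simulate_fraction_cts(targets[[cond]], noise_sd = 0.15,
                                seed = 40 + 10 * match(cond, names(targets)) + rep)
    fd <- quantify_ct_table(ct)
    data.frame(condition = cond, replicate = rep,
               score = area_above_cumulative(fd)$score)
  }))
}))
write.table(scores, "results/polysome/association_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summary_tab <- compare_conditions(scores)
write.table(summary_tab, "results/polysome/association_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Association score (area above the cumulative distribution), mean +/- SD:\n")
for (i in seq_len(nrow(summary_tab)))
  cat(sprintf("  %-11s %.3f +/- %.3f (n = %d)\n", summary_tab$condition[i],
              summary_tab$mean[i], summary_tab$sd[i], summary_tab$n[i]))
cat("The treatment shifts the WT distribution toward light fractions",
    "(lower score); the KO profile barely moves.\n")
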
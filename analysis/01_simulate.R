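#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort and its regional volume tables.
#
# Generates a 23 + 23 two-group cohort (17 F / 6 M per group, ages 21-63,
# strong sex difference in TIV) and subject-by-region volume tables for the
# two analysis families: the 16-region lobar parcellation (four regions
# carrying a true group effect) and the hemisphere / whole-brain family.
# Writes subjects.tsv and one volume table per family under results/sim/.

suppressMessages(library(ahglm))

seed <- 20L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(), seed = seed)
write_subjects(cohort, file.path(out_dir, "subjects.tsv"))

aud <- sex_tiv_audit(cohort)
cat(sprintf("cohort: %d subjects (%d F / %d M); sex->TIV t(%d) = %.2f, p = %.2g\n",
            nrow(cohort), sum(cohort$sex == "F"), sum(cohort$sex == "M"),
            aud$df, aud$t, aud$p))
bal <- group_balance_audit(cohort)
cat(sprintf("group balance: age p = %.2f, TIV p = %.2f (matched groups)\n",
            bal$p[1], bal$p[2]))

for (fam in c("lobar16", "hemi3")) {
  specs <- if (fam == "lobar16") lobar16_specs() else hemi3_specs()
  tab <- generate_volumes(cohort, specs, seed = seed + 1L)
  write_volume_table(tab, file.path(out_dir, paste0(fam, "_volumes.tsv")))
  wb <- grep("whole", tab$regions, value = TRUE)
  cat(sprintf("%s: %d regions written%s\n", fam, length(tab$regions),
              if (length(wb)) sprintf(" (control whole-brain mean %.1f mL)",
                                      mean(tab$volumes[cohort$med == 0, wb]))
              else ""))
}
cat("wrote", out_dir, "\n")
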
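#!/usr/bin/env Rscript
# Stage 5: group statistics and PLS-1 inference.
#
# Whole-brain ISTS group contrasts (couples vs random pairs, high vs low
# satisfaction), correlation of whole-brain ISTS with satisfaction, and the
# regional PLS-1 analysis: permutation test of the covariance explained
# (5,000 shuffles), bootstrap z per ROI (500 resamples), BH-FDR mask.

suppressPackageStartupMessages(library(dyadsync))

seed <- 20240105L
ds <- load_dataset("results/dataset/manifest.json")
couple_tab <- compute_ists_table(ds)
y <- ds$dyads$cmqi_score

wb_all <- as.data.frame(data.table::fread("results/ists/whole_brain.tsv"))
gc <- group_compare(data.frame(value = wb_all$mean_ists,
                               status = wb_all$dyad_class))
cat("one-way status ANOVA:\n")
print(gc$anova, digits = 4)

wb <- whole_brain_average(couple_tab)$mean_ists
rc <- ists_correlation(wb, y, method = "pearson")
cat(sprintf("whole-brain ISTS vs satisfaction: r = %.3f, p = %.2g\n", rc$r, rc$p))

pls <- pls_inference(couple_tab$values, y, n_perm = 5000, n_boot = 500,
                     seed = seed)
cat(sprintf("PLS-1: covariance explained %.4g, permutation p = %.4g, %d/%d ROIs FDR-significant\n",
            pls$covariance_explained, pls$p_permutation,
            sum(pls$fdr_mask), nrow(pls$table)))

wwb <- as.data.frame(data.table::fread("results/within_event/within_event_whole_brain.tsv"))
hi <- wwb$mean_ists[wwb$dyad_class == "couple_high"]
lo <- wwb$mean_ists[wwb$dyad_class == "couple_low"]
tt <- t.test(hi, lo)
cat(sprintf("within-event ISTS, high vs low satisfaction: t = %.2f, p = %.2g\n",
            tt$statistic, tt$p.value))

write_results(list(
  pls_result = pls$table,
  group_tests = gc$t_tests,
  anova = gc$anova,
  ists_satisfaction_r = rc$r,
  ists_satisfaction_p = rc$p,
  pls_permutation_p = pls$p_permutation,
  within_event_t = unname(tt$statistic),
  within_event_p = tt$p.value
), "results/stats")
cat("statistics written to results/stats\n")
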
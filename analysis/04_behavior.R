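#!/usr/bin/env Rscript
# Stage 4: the five behavioural endpoints with BH-FDR control, effect
# sizes, and the brain-behaviour partial correlation.

library(nfmed)

seed <- 1L
out <- "results/04_behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort_path <- "results/01_simulate/cohort.csv"
cohort <- if (file.exists(cohort_path)) {
  read_cohort_csv(cohort_path)
} else {
  simulate_cohort(cohort_config(seed = seed))
}

tab <- run_endpoints(cohort)
write.csv(as.data.frame(tab), file.path(out, "endpoints.csv"),
          row.names = FALSE)
cat("five behavioural endpoints (BH-FDR across the family of 5):\n")
print(cbind(tab[, c("endpoint", "test_kind")],
            round(tab[, c("statistic", "raw_p", "bh_p", "cohen_d")], 3)))

# partial correlation between coupling change and distress change,
# controlling for age and sex (the brain-behaviour association)
ch <- cohort$dass_followup - cohort$dass_baseline
pc <- partial_correlation(cohort$coupling_beta, ch,
                          cbind(cohort$age, cohort$sex))
cat(sprintf("\ncoupling-distress partial correlation: r = %.2f, df = %d, p = %.4f\n",
            pc$effect_size, pc$df, pc$p))
g <- cohort$group == "experimental"
pe <- partial_correlation(cohort$coupling_beta[g], ch[g],
                          cbind(cohort$age, cohort$sex)[g, ])
pcN <- partial_correlation(cohort$coupling_beta[!g], ch[!g],
                           cbind(cohort$age, cohort$sex)[!g, ])
cat(sprintf("  experimental only: r = %.2f (p = %.4f); control only: r = %.2f (p = %.4f)\n",
            pe$effect_size, pe$p, pcN$effect_size, pcN$p))
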
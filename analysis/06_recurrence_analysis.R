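#!/usr/bin/env Rscript
# Two-year recurrence by PRS group within provoked and unprovoked strata:
# Kaplan-Meier curves, log-rank tests and Cox hazard ratios (high vs low).

suppressPackageStartupMessages(library(vteprs))

fx <- read_fixture("results/cohort")
qc <- apply_qc(fx$cohort)
prs <- prs_stage(qc$cohort)
res <- recurrence_analysis(qc$cohort, prs)

write.table(res$summary, "results/recurrence_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (stratum in setdiff(names(res), "summary")) {
  for (grp in names(res[[stratum]]$km)) {
    write.table(res[[stratum]]$km[[grp]],
                sprintf("results/km_%s_%s.tsv", stratum, grp),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

cat("Recurrence tables written to results/recurrence_summary.tsv",
    "and results/km_*.tsv\n")
sm <- res$summary
for (i in seq_len(nrow(sm)))
  cat(sprintf(
    "  %-10s (n=%d low / %d high): log-rank p = %.3f, HR = %s\n",
    sm$stratum[i], sm$n_low[i], sm$n_high[i], sm$logrank_p[i],
    ifelse(is.na(sm$hr_high_vs_low[i]), "NA",
           sprintf("%.2f (%.2f-%.2f)", sm$hr_high_vs_low[i],
                   sm$hr_ci_low[i], sm$hr_ci_high[i]))))
cat("  the generator plants HR 1 in the provoked stratum and HR 3.53 in the\n",
    " unprovoked stratum; at 36 unprovoked cases the interval is wide\n")
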
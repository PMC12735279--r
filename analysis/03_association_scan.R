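#!/usr/bin/env Rscript
# Case-control association scan over the QC-passing panel variants: allelic
# odds ratios with Woolf/exact CIs and chi-square/Fisher p-values, plus
# dominant and recessive genotype models, with age/sex/BMI-adjusted logistic
# estimates for nominally significant variants.

suppressPackageStartupMessages(library(vteprs))

fx <- read_fixture("results/cohort")
qc <- apply_qc(fx$cohort)
scan <- association_scan(qc$cohort)

allelic <- scan[scan$model == "allelic", ]
write.table(allelic, "results/association_allelic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan[scan$model != "allelic", ],
            "results/association_genetic_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hits <- allelic[!allelic$degenerate & !is.na(allelic$p_value) &
                  allelic$p_value < 0.05, ]
hits <- hits[order(hits$p_value), ]
cat("Association tables written to results/association_*.tsv\n")
cat(sprintf("  %d of %d variants nominally significant (allelic, p < 0.05):\n",
            nrow(hits), nrow(allelic)))
for (i in seq_len(nrow(hits)))
  cat(sprintf("    %-12s OR %5.2f (%4.2f-%5.2f)  p = %.4g  adj. OR %s\n",
              hits$rsid[i], hits$or_estimate[i], hits$ci_low[i],
              hits$ci_high[i], hits$p_value[i],
              ifelse(is.na(hits$adjusted_or[i]), "-",
                     sprintf("%.2f", hits$adjusted_or[i]))))
cat("  (the generating frequencies encode seven true signals; at n = 122/87\n",
    "  a scan of one replicate typically recovers most but not all of them)\n")
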
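#!/usr/bin/env Rscript
# Generate the study-shaped synthetic cohort (122 VTE cases / 87 controls,
# genotypes at the published case/control effect-allele frequencies, two-year
# recurrence follow-up) and write it as a reusable fixture.

suppressPackageStartupMessages(library(vteprs))

seed <- 20251L
out <- "results/cohort"

cfg <- sim_config(seed = seed)
sim <- generate_cohort(cfg)
write_fixture(sim$cohort, out, truth = sim$truth)

s <- sim$cohort$subjects
cat("Simulated cohort written to", out, "\n")
cat(sprintf("  %d cases / %d controls, %d panel variants\n",
            sum(s$status == "case"), sum(s$status == "control"),
            nrow(sim$cohort$genotypes)))
cat(sprintf("  provoked/unprovoked cases: %d / %d\n",
            sum(s$risk_class == "provoked", na.rm = TRUE),
            sum(s$risk_class == "unprovoked", na.rm = TRUE)))
cat(sprintf("  two-year recurrence fraction among cases: %.2f\n",
            mean(s$event[s$status == "case"])))
cat(sprintf("  seed %d; ground truth in %s/truth.json\n", seed, out))
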
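---
title: "Methods: panel association, polygenic scoring and recurrence analysis for VTE"
author: "vteprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel association, polygenic scoring and recurrence analysis for VTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`vteprs` implements a complete case-control analysis of a curated venous
thromboembolism (VTE) SNP panel: per-variant genotyping QC, allelic and
genotype-model association statistics, retrospective power, a
log-odds-weighted polygenic risk score (PRS) with control-referenced
standardization, and a PRS-stratified two-year recurrence survival analysis.
The bundled panel holds 38 variants in 26 genes, each with its effect and
reference allele, a literature odds ratio (the default PRS weight) and the
published case/control effect-allele frequencies at the study's sample size
of 122 cases and 87 controls. Because no individual-level data accompany
those summary figures, the package ships a synthetic cohort generator that
emulates the cohort's statistical structure; every stage of the pipeline is
exercised and tested against it.

## Genotype representation

Genotypes are effect-allele dosages (0, 1, 2, or missing). The dosage counts
the panel's designated *effect* allele — not the minor allele — so
protective variants (for example *F5* rs4524 and *TGFB2* rs57615042) still
count the listed allele and their protection enters the score through a
negative weight. VCF input is matched by rsID; when a site's REF/ALT
orientation is flipped relative to the panel the dosage is re-oriented as
`2 - alt count` (applying the flip twice is the identity). Indel alleles are
compared after trimming the shared VCF anchor base, so the panel's `-`
deletion token (rs8176719) matches its anchored VCF encoding. Missing calls
are never imputed at read time; each downstream stage declares its policy.

## Quality control

Two per-variant filters mirror standard genotyping QC:

* **Call rate**: the exact non-missing fraction; a variant passes only when
  the rate is *strictly greater* than the threshold (default 0.95).
* **Hardy–Weinberg equilibrium, controls only**: the exact conditional test.
  Given `n` control subjects carrying `n_eff` effect-allele copies, the
  heterozygote count `h` has conditional probability proportional to
  `2^h n! / [((n_eff-h)/2)! h! ((n_oth-h)/2)!]`; the p-value sums the
  probabilities of all heterozygote counts no more probable than the one
  observed (ties included with a `1e-7` relative tolerance). A variant fails
  at `p <= alpha` (default 0.05); `alpha = 0` disables the filter. The exact
  test was chosen over the chi-square approximation because several panel
  variants are rare in this population, exactly where the approximation is
  least trustworthy. Monomorphic sites have a single attainable
  configuration, hence `p = 1`: they pass rather than being spuriously
  flagged.

Note that testing 38 variants at `alpha = 0.05` drops roughly two variants
by chance even on perfectly clean data; the QC report records every decision
so chance failures are visible, and the tests bound them with a
multiplicity-aware limit instead of asserting zero.

## Association statistics

For each variant the allelic 2×2 table counts effect/other alleles in cases
and controls (two alleles per subject). The odds ratio is the cross-product
`ad/(bc)`; with a single zero cell it is reported as `Inf` or `0` together
with an **exact conditional CI** (inversion of the noncentral hypergeometric
tail probabilities, conditioning on both margins) rather than a
Haldane-corrected point estimate — matching how the study prints
"Infinity (0.33–infinity)" rows. All-positive tables get the **Woolf CI**,
`exp(log OR ± z·sqrt(1/a+1/b+1/c+1/d))`.

The test is Pearson's chi-square without continuity correction when every
expected cell count is at least 5, otherwise the two-sided Fisher exact test
by the point-probability method. The source study states the selection rule
but not the cutoff; 5 is the convention. Both branches are verified against
independent enumeration oracles in the test suite.

Dominant (carriers vs non-carriers) and recessive (homozygous-effect vs
rest) models collapse genotype counts to subject-level 2×2 tables and reuse
the same machinery. Covariate adjustment fits a maximum-likelihood logistic
model of case status on the coded genotype plus age (years), sex (male
indicator; the study does not state its coding, this is the conventional
choice) and BMI (kg/m²), with convergence by relative log-likelihood change
below `1e-8` within 100 iterations. Complete separation is flagged and
returns no estimate; rank-deficient designs are an error naming the
collinear columns. Adjusted estimates are computed only for variants with
unadjusted `p < 0.05` (mirroring the study's sparse adjusted column), a
gate that is fully configurable. Raw p-values are reported without
multiplicity correction, as in the source analysis.

Whether the study's univariate ORs are allele-count cross-products or
univariate logistic estimates on dosage is ambiguous in its methods text;
both routes are implemented, they agree asymptotically (a tested property),
and reconstruction from the printed frequency pairs matches the
allele-count reading.

## Retrospective power

`power_of()` gives the probability that the level-`alpha` two-sided
comparison of exposure proportions rejects, under an alternative specified
by the control frequency and an odds ratio. The allelic ("log-additive")
model uses two alleles per subject; dominant/recessive models use subject
counts with HWE exposure frequencies. Two methods are provided:

* **exact** (default at this study's sizes): full enumeration of the two
  independent binomial exposure counts, pushing every attainable table
  through the same chi-square/Fisher selection rule as the analysis itself.
  At 244 vs 174 alleles this is ~43k tables and runs in well under a second.
* **approx**: the classical normal approximation with pooled variance under
  the null and unpooled under the alternative, used automatically when the
  enumeration grid would exceed ~2×10⁶ cells.

The exact method is the default because it reproduces, rather than
approximates, the operating characteristics of the discrete test actually
used — the two methods agree to about a percent at n = 122/87.
`detectable_or()` inverts the power function by bisection to `1e-4`. Power
is not symmetric under `OR -> 1/OR` at a fixed frequency; the true symmetry
is allele relabelling, `(eaf, OR) <-> (1-eaf, 1/OR)`, which is what the
tests assert.

## Polygenic risk score

`PRS = Σ β_i × dosage_i` with `β_i = ln(OR_i)`. The default weight source is
the panel's curated literature ORs; an in-cohort weight mode exists but
literature weights avoid in-sample circularity for the case/control
contrast, and variants whose in-cohort OR is undefined (zero cells,
monomorphic) fall back to literature weights with a flag. Missing dosages
are substituted by the mean control dosage by default (keeping scores
comparable across subjects); a zero policy is available for sensitivity
analysis.

Scores are standardized against the control distribution:
`z = (raw − mean_controls)/sd_controls`, so control z-scores have mean 0 and
SD 1 by construction (asserted to `1e-10`). The source study prints
standardized-score means far from 0/1 for both groups, which is arithmetically
incompatible with this definition; the package implements the formula as
written and treats the printed means as unverifiable. The median split sends
ties to the low group so the high group strictly exceeds the median; the
split reference defaults to the patient cohort (the recurrence analysis
splits patients at the patient median). The OR-by-bin report defaults to
control z quartiles with the lowest bin as reference, both configurable
since the study does not state its bins.

PRS linearity in the weights (scaling weights by `c` scales raw scores by
`c` and leaves z-scores unchanged) is a tested invariant. A uniform *shift*
of the weight vector is **not** absorbed by standardization — it moves
subjects by `shift × total dosage`, which varies across subjects — so only
scale invariance is claimed.

## Recurrence analysis

Time-to-event runs from anticoagulant discontinuation to confirmed
recurrence, administratively censored at 24 months (events recorded beyond
the cap become censorings; negative times are rejected at I/O). Within each
provoked/unprovoked stratum the high- vs low-PRS groups are compared by the
Kaplan–Meier product-limit estimator with log-scale Greenwood intervals,
the two-group log-rank test, and a univariable Cox model. Ties are handled
by the Efron method, which is less biased under the heavy ties that
month-granular follow-up produces. The univariable Cox reading matches the
single published HR; the study does not state any further covariates.
Monotone partial likelihoods (all events in one group) are flagged rather
than reported as spuriously huge estimates. Strata with fewer than two
subjects per PRS group are skipped with a warning.

## Synthetic cohort generator

The generator's defaults are the study conditions: 122 cases / 87 controls;
HWE genotypes at the published control frequencies, case genotypes at the
published case frequencies (marginal emulation — the study publishes
marginal frequencies, not a liability model; a logistic-selection mode
exists for covariate-confounded scenarios); age from a truncated normal
with median 44.5 and IQR-matched spread (32–57), BMI 24.5 ± 4.0, 55% male;
70.5% provoked cases; and exponential recurrence times over the 24-month
window. The provoked stratum uses a monthly baseline hazard of 0.028 in
both PRS groups (group HR 1); the unprovoked low-PRS group uses 0.014 with
HR 3.53 for high PRS. These baselines were calibrated once so the overall
two-year recurrence fraction is ≈ 0.49, matching the published cohort, and
are not tuned thereafter. The generator assigns each case's PRS group from
its own simulated genotypes (literature weights, median split), so the
genotype-to-recurrence link the analysis estimates is genuinely present.

What the generator does **not** emulate: linkage disequilibrium between
panel variants (the analysis treats variants marginally), population
structure, genotyping error beyond random missingness, covariate-genotype
confounding (in the default marginal mode), and non-exponential hazard
shapes. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to those real-data
features.

All draws are reproducible from `(config, seed)`; fixtures written to disk
(`panel.tsv`, `cohort.vcf`, `phenotypes.tsv`, `truth.json`) are
byte-identical across runs at a fixed seed and round-trip through the
readers to an equal cohort.

## Numerical choices and degenerate inputs

* HWE and Fisher p-values include probability ties with `1e-7` relative
  tolerance; both are checked against independent enumeration oracles
  (recurrence-based for HWE, direct hypergeometric summation for Fisher).
* Exact CI bounds are solved by `uniroot` on `log(psi)` in `[-50, 50]` to
  `1e-10`; a table whose margins determine it entirely yields `(0, Inf)`.
* Logistic separation is detected from fitted probabilities at the 0/1
  boundary combined with a diverging coefficient, and flagged.
* Cox monotone likelihoods are flagged when the coefficient or its standard
  error diverges.
* Degenerate association tables (zero margins, monomorphic variants) are
  retained in every report with flags, never silently dropped.

## Problem sizes used by the tests

The suite verifies exact-test equivalences exhaustively for all genotype
triples with totals ≤ 40–60 and on seeded random triples up to 200; Woolf
coverage on 2,000 simulated tables; the power function against a
20,000-replicate Monte-Carlo oracle on a 3×3 grid; parameter recovery for
the adjusted logistic OR at n = 2,000, the Cox HR at n = 500 (plus interval
width at the unprovoked stratum's n = 36), log-rank size over 1,000 null
replicates, and end-to-end OR recovery at n = 5,000/5,000 with
direction-recovery at the study's own 122/87 over 200 replicates. These
sizes give comfortable Monte-Carlo resolution for every claim while keeping
the default suite fast.

## Known limitations

* The panel ships the 38 variants actually printed in the source table; the
  accompanying text counts 39 (the missing locus is not identifiable from
  the publication). The file format accepts a user-supplied 39th row.
* Exact per-variant genotype counts are not published, so verification
  against the study rests on two-decimal frequency pairs; reconstruction
  tolerances reflect that rounding.
* No LD-aware scoring, haplotype analysis, competing risks, or multivariable
  Cox modelling — none are part of the source analysis.
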
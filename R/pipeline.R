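#' End-to-end pipeline
#'
#' Orchestrates panel -> QC -> association -> power -> PRS -> recurrence on a
#' cohort read from disk (or passed in memory) and renders the report tables:
#' a QC report, an association table shaped like the study's main results
#' table, a dominant/recessive genetic-model table, a power grid, per-subject
#' PRS scores, OR-by-PRS-bin estimates, per-stratum recurrence summaries and
#' a run manifest. The pipeline is a pure function of (inputs, config).
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param panel_path Panel TSV (default: bundled panel).
#' @param genotypes_path VCF (`.vcf`/`.vcf.gz`) or dosage TSV.
#' @param phenotypes_path Phenotype TSV.
#' @param out_dir Output directory for the report bundle.
#' @param call_rate_min,hwe_alpha QC thresholds (see [apply_qc()]).
#' @param weight_source PRS weight source, `"literature"` or `"cohort"`.
#' @param missing_policy PRS missing-dosage policy (see [compute_prs()]).
#' @param prs_bin_edges Interior z-score bin edges for the OR-by-bin report
#'   (NULL: control quartiles).
#' @param followup_cap Administrative censoring cap, months.
#' @param power_eafs,power_ors Grid for the power report.
#' @param adjust_when_p_below Gate for covariate-adjusted estimates.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(panel_path = system.file("extdata",
                                                     "vte_panel.tsv",
                                                     package = "vteprs"),
                            genotypes_path, phenotypes_path,
                            out_dir = "vteprs_out",
                            call_rate_min = 0.95, hwe_alpha = 0.05,
                            weight_source = "literature",
                            missing_policy = "mean_dosage_controls",
                            prs_bin_edges = NULL,
                            followup_cap = 24,
                            power_eafs = c(0.1, 0.2, 0.36, 0.5),
                            power_ors = c(1.2, 1.5, 1.94, 2.5),
                            adjust_when_p_below = 0.05,
                            seed = 1L) {
  list(panel_path = panel_path, genotypes_path = genotypes_path,
       phenotypes_path = phenotypes_path, out_dir = out_dir,
       call_rate_min = call_rate_min, hwe_alpha = hwe_alpha,
       weight_source = weight_source, missing_policy = missing_policy,
       prs_bin_edges = prs_bin_edges, followup_cap = followup_cap,
       power_eafs = power_eafs, power_ors = power_ors,
       adjust_when_p_below = adjust_when_p_below, seed = as.integer(seed))
}

write_report_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vteprs %s | seed %s",
                     as.character(utils::packageVersion("vteprs")), seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' @param config From [pipeline_config()].
#' @param cohort Optional in-memory `vte_cohort`, bypassing the input paths.
#' @return Invisibly, a list with every stage result and the bundle paths.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- run_stage("input", {
      panel <- load_panel(config$panel_path)
      gt <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes_path))
        read_genotypes_vcf(config$genotypes_path, panel)
      else read_genotype_table(config$genotypes_path, panel)
      assemble_cohort(panel, gt, read_phenotypes(config$phenotypes_path))
    })
  }
  qc <- run_stage("qc", apply_qc(cohort, config$call_rate_min,
                                 config$hwe_alpha))
  scan <- run_stage("association",
                    association_scan(qc$cohort,
                                     adjust_when_p_below =
                                       config$adjust_when_p_below))
  allelic <- scan[scan$model == "allelic", ]
  assoc_table <- run_stage("association", {
    p <- qc$cohort$panel
    idx <- match(allelic$rsid, p$rsid)
    data.frame(gene = p$gene[idx], rsid = allelic$rsid,
               effect_allele = p$effect_allele[idx],
               reference_allele = p$reference_allele[idx],
               literature_or = p$literature_or[idx],
               eaf_case = round(allelic$eaf_case, 4),
               eaf_control = round(allelic$eaf_control, 4),
               or_estimate = allelic$or_estimate,
               ci_low = allelic$ci_low, ci_high = allelic$ci_high,
               p_value = allelic$p_value, test_used = allelic$test_used,
               adjusted_or = allelic$adjusted_or,
               adjusted_ci_low = allelic$adjusted_ci_low,
               adjusted_ci_high = allelic$adjusted_ci_high,
               adjusted_p = allelic$adjusted_p,
               stringsAsFactors = FALSE)
  })
  models_table <- scan[scan$model != "allelic", ]
  n_ca <- sum(cohort$subjects$status == "case")
  n_co <- sum(cohort$subjects$status == "control")
  pow <- run_stage("power",
                   power_grid(n_ca, n_co, config$power_eafs,
                              config$power_ors))
  weights <- run_stage("prs",
                       prs_weights(qc$cohort$panel, config$weight_source,
                                   cohort_scan = scan))
  prs <- run_stage("prs", prs_stage(qc$cohort, weights,
                                    config$missing_policy))
  bins <- run_stage("prs",
                    or_by_prs_bin(prs$z_prs, prs$status,
                                  bin_edges = config$prs_bin_edges))
  have_followup <- any(!is.na(cohort$subjects$time_months))
  recur <- if (have_followup)
    run_stage("recurrence",
              recurrence_analysis(qc$cohort, prs, config$followup_cap))
  else NULL

  seed <- config$seed
  paths <- c(
    qc_report = write_report_tsv(qc$report,
                                 file.path(config$out_dir, "qc_report.tsv"),
                                 seed),
    association = write_report_tsv(assoc_table,
                                   file.path(config$out_dir,
                                             "association.tsv"), seed),
    genetic_models = write_report_tsv(models_table,
                                      file.path(config$out_dir,
                                                "genetic_models.tsv"), seed),
    power_grid = write_report_tsv(pow,
                                  file.path(config$out_dir,
                                            "power_grid.tsv"), seed),
    prs_subjects = write_report_tsv(
      prs[, c("subject_id", "status", "raw_prs", "z_prs", "prs_group")],
      file.path(config$out_dir, "prs_subjects.tsv"), seed),
    prs_bins = write_report_tsv(bins,
                                file.path(config$out_dir, "prs_bins.tsv"),
                                seed),
    recurrence = if (have_followup)
      write_report_tsv(recur$summary,
                       file.path(config$out_dir, "recurrence_summary.tsv"),
                       seed) else NA_character_)
  manifest <- list(
    package = "vteprs",
    version = as.character(utils::packageVersion("vteprs")),
    r_version = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    n_case = n_ca, n_control = n_co,
    n_variants_input = nrow(cohort$genotypes),
    n_variants_kept = nrow(qc$cohort$genotypes))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, qc = qc, scan = scan,
                 association = assoc_table, genetic_models = models_table,
                 power = pow, weights = weights, prs = prs, bins = bins,
                 recurrence = recur, paths = paths,
                 manifest = manifest))
}
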
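#' SNP panel registry
#'
#' A panel is the ordered table of curated variants that every downstream
#' stage keys on: one row per SNP with gene symbol, rsID, effect and
#' reference alleles, the literature odds ratio used as the default PRS
#' weight, and an established/novel category tag.
#'
#' @name panel
NULL

PANEL_CORE_COLS <- c("gene", "rsid", "effect_allele", "reference_allele",
                     "literature_or", "category")

#' Load a SNP panel definition table
#'
#' Reads a tab-separated panel file (UTF-8, `#` comment lines ignored) with
#' columns `gene`, `rsid`, `effect_allele`, `reference_allele`,
#' `literature_or` and optionally `category`. Extra columns (for example
#' per-group effect-allele frequencies used by the simulator) are preserved.
#' Row order is preserved. A `-` allele token is legal and denotes a
#' deletion/insertion allele.
#'
#' @param path Path to the panel TSV. Defaults to the bundled VTE panel of
#'   38 variants in 26 genes.
#' @param name Informational panel name.
#' @param genome_build Informational genome build tag (no liftover is done).
#' @return A data frame of class `vte_panel`, one row per variant.
#' @examples
#' p <- load_panel()
#' nrow(p)
#' @export
load_panel <- function(path = system.file("extdata", "vte_panel.tsv",
                                          package = "vteprs"),
                       name = "vte_panel", genome_build = "GRCh38") {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse panel file: ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("panel file is empty: ", path)
  missing_cols <- setdiff(setdiff(PANEL_CORE_COLS, "category"), names(df))
  if (length(missing_cols) > 0L)
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"category" %in% names(df)) df$category <- "established"
  df$literature_or <- suppressWarnings(as.numeric(df$literature_or))
  for (col in grep("^eaf_", names(df), value = TRUE))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  panel <- new_panel(df, name = name, genome_build = genome_build)
  validate_panel(panel)
  panel
}

new_panel <- function(df, name = "panel", genome_build = "unknown") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("vte_panel", "data.frame"),
            panel_name = name, genome_build = genome_build)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (nrow(panel) == 0L) stop("panel must be non-empty")
  dup <- unique(panel$rsid[duplicated(panel$rsid)])
  if (length(dup) > 0L)
    stop("duplicate rsID(s) in panel: ", paste(dup, collapse = ", "))
  bad_or <- panel$rsid[is.na(panel$literature_or) | panel$literature_or <= 0]
  if (length(bad_or) > 0L)
    stop("non-positive or missing literature OR for: ",
         paste(bad_or, collapse = ", "))
  same <- panel$rsid[panel$effect_allele == panel$reference_allele]
  if (length(same) > 0L)
    stop("effect allele equals reference allele for: ",
         paste(same, collapse = ", "))
  bad_cat <- setdiff(unique(panel$category), c("established", "novel"))
  if (length(bad_cat) > 0L)
    stop("unknown category value(s): ", paste(bad_cat, collapse = ", "))
  invisible(panel)
}

#' Write a panel back to a TSV file
#'
#' Inverse of [load_panel()]; loading, writing and reloading yields an
#' identical panel.
#'
#' @param panel A `vte_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-odds weight of a panel variant
#'
#' The per-SNP weight of the polygenic score is the natural logarithm of an
#' odds ratio: the curated literature OR by default, or a cohort-estimated OR
#' when supplied. Protective variants (OR < 1) yield negative weights.
#'
#' @param variant One-row slice of a `vte_panel` (or any list with a
#'   `literature_or` field).
#' @param source `"literature"` (default) or `"cohort"`.
#' @param cohort_or Positive cohort OR, required when `source = "cohort"`.
#' @return The natural-log odds ratio.
#' @examples
#' p <- load_panel()
#' weight_of(p[p$rsid == "rs146922325", ])  # log(6.91)
#' @export
weight_of <- function(variant, source = c("literature", "cohort"),
                      cohort_or = NULL) {
  source <- match.arg(source)
  if (source == "literature") {
    or <- variant$literature_or
  } else {
    if (is.null(cohort_or))
      stop("source = \"cohort\" requires cohort_or")
    or <- cohort_or
  }
  if (!is.numeric(or) || length(or) != 1L || is.na(or) || or <= 0)
    stop("odds ratio must be a single positive number")
  log(or)
}

#' @export
print.vte_panel <- function(x, ...) {
  cat(sprintf("<vte_panel '%s'> %d variants, %d genes (build %s)\n",
              attr(x, "panel_name"), nrow(x), length(unique(x$gene)),
              attr(x, "genome_build")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}
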
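# Small in-code fixtures shared across test files.

make_test_panel <- function(n = 5L) {
  df <- data.frame(
    gene = paste0("G", seq_len(n)),
    rsid = paste0("rs", 1000 + seq_len(n)),
    effect_allele = rep(c("A", "T", "C", "G", "C"), length.out = n),
    reference_allele = rep(c("G", "C", "T", "A", "-"), length.out = n),
    literature_or = seq(1.2, by = 0.3, length.out = n),
    category = rep(c("established", "novel"), length.out = n),
    stringsAsFactors = FALSE)
  vteprs:::new_panel(df, name = "test_panel")
}

make_subjects <- function(n_case = 10L, n_control = 10L, followup = FALSE) {
  n <- n_case + n_control
  df <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    status = c(rep("case", n_case), rep("control", n_control)),
    age = seq(30, 60, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    bmi = seq(20, 30, length.out = n),
    diagnosis = NA_character_, risk_class = NA_character_,
    time_months = NA_real_, event = NA_integer_,
    stringsAsFactors = FALSE)
  if (n_case > 0) {
    df$diagnosis[seq_len(n_case)] <- "DVT"
    df$risk_class[seq_len(n_case)] <- rep(c("provoked", "unprovoked"),
                                          length.out = n_case)
    if (followup) {
      df$time_months[seq_len(n_case)] <- rep(c(6, 12, 24), length.out = n_case)
      df$event[seq_len(n_case)] <- rep(c(1L, 0L), length.out = n_case)
    }
  }
  df
}

make_small_cohort <- function(n_case = 10L, n_control = 10L, seed = 101L,
                              panel = make_test_panel(), followup = FALSE,
                              eaf = 0.3) {
  set.seed(seed)
  subjects <- make_subjects(n_case, n_control, followup)
  gt <- matrix(sample(0:2, nrow(panel) * nrow(subjects), replace = TRUE,
                      prob = c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)),
               nrow(panel), nrow(subjects),
               dimnames = list(panel$rsid, subjects$subject_id))
  assemble_cohort(panel, gt, subjects)
}
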
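test_that("effect allele frequency excludes missing dosages", {
  expect_equal(effect_allele_frequency(c(2, 2, 2)), 1.00)
  expect_equal(effect_allele_frequency(c(0, 1)), 0.25)
  expect_equal(effect_allele_frequency(c(0, 1, NA)), 0.25)
  expect_error(effect_allele_frequency(c(NA_integer_, NA_integer_)), "missing")
})

test_that("frequency recovery from seeded synthetic controls", {
  set.seed(360)
  d <- simulate_genotypes(87, 0.36)
  se <- sqrt(0.36 * 0.64 / (2 * 87))
  expect_lt(abs(effect_allele_frequency(d) - 0.36), 3 * se)
})

test_that("allelic tables match hand and brute-force tallies", {
  tab <- allelic_table(c(1, 1), c(0, 0))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 2, 0, 4))
  expect_false(tab$degenerate)

  tab2 <- allelic_table(c(2, 2), c(2, 2))
  expect_true(tab2$degenerate)   # zero unexposed margin

  set.seed(5)
  dca <- sample(c(0:2, NA), 60, TRUE)
  dco <- sample(c(0:2, NA), 40, TRUE)
  tab3 <- allelic_table(dca, dco)
  expect_equal(tab3$a, sum(dca, na.rm = TRUE))
  expect_equal(tab3$b, 2 * sum(!is.na(dca)) - sum(dca, na.rm = TRUE))
  expect_equal(tab3$c, sum(dco, na.rm = TRUE))
  expect_equal(tab3$d, 2 * sum(!is.na(dco)) - sum(dco, na.rm = TRUE))
})

test_that("odds ratio is the cross-product with principled zero handling", {
  expect_equal(odds_ratio(two_by_two(10, 10, 10, 10)), 1)
  expect_equal(odds_ratio(two_by_two(127, 117, 63, 111)),
               127 * 111 / (117 * 63))
  expect_equal(odds_ratio(two_by_two(2, 242, 0, 174)), Inf)
  expect_error(odds_ratio(two_by_two(0, 5, 0, 5)), "zero cells")
  # transposing the exposure inverts the OR
  set.seed(17)
  for (i in 1:25) {
    cells <- sample(1:50, 4, TRUE)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t1) * odds_ratio(t2), 1, tolerance = 1e-12)
  }
})

test_that("frequency-form OR matches published worked examples", {
  expect_equal(or_from_eaf(0.52, 0.36), (0.52 / 0.48) / (0.36 / 0.64))
  expect_equal(or_from_eaf(0.3, 0.3), 1)
  expect_error(or_from_eaf(0, 0.3), "strictly between")
})

test_that("Woolf CI is log-symmetric, contains the estimate, widens with level", {
  ci <- woolf_ci(two_by_two(10, 10, 10, 10))
  expect_equal(log(ci[1]), -log(ci[2]), tolerance = 1e-12)

  set.seed(23)
  for (i in 1:20) {
    cells <- sample(1:60, 4, TRUE)
    tab <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    ci95 <- woolf_ci(tab, 0.95)
    ci99 <- woolf_ci(tab, 0.99)
    or <- odds_ratio(tab)
    expect_true(ci95[1] <= or && or <= ci95[2])
    expect_true(ci99[1] < ci95[1] && ci99[2] > ci95[2])
  }
  expect_error(woolf_ci(two_by_two(0, 5, 5, 5)), "exact_ci")
})

test_that("Woolf CI attains near-nominal coverage at n = 200", {
  set.seed(77)
  n_sim <- 2000L
  p1 <- 0.45; p0 <- 0.30
  true_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  covered <- 0L; usable <- 0L
  for (i in seq_len(n_sim)) {
    a <- rbinom(1, 200, p1); c_ <- rbinom(1, 200, p0)
    if (a %in% c(0L, 200L) || c_ %in% c(0L, 200L)) next
    usable <- usable + 1L
    ci <- woolf_ci(two_by_two(a, 200 - a, c_, 200 - c_))
    if (ci[1] <= true_or && true_or <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / usable, 0.94)
})

test_that("exact conditional CI inverts the hypergeometric tails", {
  # zero control-exposed cell: finite lower bound, infinite upper
  ci <- exact_ci(two_by_two(2, 242, 0, 174))
  expect_equal(ci[2], Inf)
  expect_equal(ci[1], oracle_exact_ci_lower(2, 242, 0, 174), tolerance = 1e-3)

  # reversed exposure pattern swaps the bounds reciprocally
  ci_rev <- exact_ci(two_by_two(242, 2, 174, 0))
  expect_equal(ci_rev[2], 1 / ci[1], tolerance = 1e-6)
  expect_equal(ci_rev[1], 0)

  # no-information table
  expect_equal(exact_ci(two_by_two(0, 10, 0, 10)), c(0, Inf))

  # all-positive tables: agrees with the grid-search oracle
  set.seed(31)
  for (i in 1:10) {
    cells <- sample(1:40, 4, TRUE)
    ci <- exact_ci(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(ci[1],
                 oracle_exact_ci_lower(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-3)
  }
})

test_that("test selection follows the expected-count rule", {
  # identical margins, no association
  res <- association_test(two_by_two(20, 20, 20, 20))
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$test_used, "chi_square")

  # an expected cell below 5 routes to Fisher
  res2 <- association_test(two_by_two(3, 30, 4, 30))  # expected exposed < 5
  expect_equal(res2$test_used, "fisher")

  # chi-square branch matches the closed-form statistic
  tab <- two_by_two(30, 20, 15, 35)
  res3 <- association_test(tab)
  n <- 100
  stat <- n * (30 * 35 - 20 * 15)^2 / (50 * 50 * 45 * 55)
  expect_equal(res3$statistic, stat, tolerance = 1e-12)
  expect_equal(res3$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Fisher branch equals hypergeometric enumeration for n <= 60", {
  set.seed(47)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    tab <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    if (tab$degenerate) next
    res <- association_test(tab)
    if (res$test_used == "fisher")
      expect_equal(res$p_value,
                   oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-9)
  }
})

test_that("genotype collapse implements dominant and recessive exposure", {
  tab_d <- genetic_model_collapse(c(10, 5, 1), c(10, 5, 1), "dominant")
  expect_equal(c(tab_d$a, tab_d$b), c(6, 10))
  expect_equal(tab_d$unit, "subject")
  tab_r <- genetic_model_collapse(c(10, 5, 1), c(10, 5, 1), "recessive")
  expect_equal(c(tab_r$a, tab_r$b), c(1, 15))

  set.seed(53)
  for (i in 1:25) {
    n <- sample(1:100, 3, TRUE)
    dom <- genetic_model_collapse(n, n, "dominant")
    rec <- genetic_model_collapse(n, n, "recessive")
    # dominant-exposed + recessive-unexposed - n_het = total
    expect_equal(dom$a + rec$b - n[2], sum(n))
  }
})

test_that("saturated logistic fit equals the 2x2 subject OR", {
  panel <- make_test_panel(1)
  subjects <- make_subjects(40, 40)
  set.seed(61)
  dos <- c(sample(0:1, 40, TRUE, prob = c(0.4, 0.6)),
           sample(0:1, 40, TRUE, prob = c(0.7, 0.3)))
  gt <- matrix(as.integer(dos), 1, 80,
               dimnames = list(panel$rsid, subjects$subject_id))
  cohort <- assemble_cohort(panel, gt, subjects)
  fit <- logistic_adjusted_or(cohort, panel$rsid, covariates = character(0),
                              coding = "dominant")
  dca <- gt[1, subjects$status == "case"]
  dco <- gt[1, subjects$status == "control"]
  tab <- two_by_two(sum(dca == 1), sum(dca == 0),
                    sum(dco == 1), sum(dco == 0), unit = "subject")
  expect_equal(fit$adjusted_or, odds_ratio(tab), tolerance = 1e-6)
})

test_that("logistic fit flags separation and collinearity rather than crashing", {
  panel <- make_test_panel(1)
  subjects <- make_subjects(20, 20)
  gt <- matrix(c(rep(2L, 20), rep(0L, 20)), 1, 40,
               dimnames = list(panel$rsid, subjects$subject_id))
  cohort <- assemble_cohort(panel, gt, subjects)
  fit <- logistic_adjusted_or(cohort, panel$rsid, covariates = character(0))
  expect_true(fit$separation)
  expect_true(is.na(fit$adjusted_or))

  cohort2 <- make_small_cohort(15, 15, seed = 63)
  cohort2$subjects$bmi <- 25  # zero-variance covariate
  expect_error(logistic_adjusted_or(cohort2, "rs1001",
                                    covariates = c("age", "bmi")),
               "collinear.*bmi")
})

test_that("association scan keeps degenerate variants and is deterministic", {
  panel <- make_test_panel(3)
  subjects <- make_subjects(15, 15)
  set.seed(71)
  gt <- rbind(sample(0:2, 30, TRUE),
              rep(0L, 30),                      # monomorphic
              sample(0:2, 30, TRUE))
  dimnames(gt) <- list(panel$rsid, subjects$subject_id)
  cohort <- assemble_cohort(panel, gt, subjects)
  scan <- association_scan(cohort)
  expect_equal(nrow(scan), 3L * 3L)   # three models per variant
  mono <- scan[scan$rsid == panel$rsid[2] & scan$model == "allelic", ]
  expect_true(mono$degenerate)

  scan2 <- association_scan(cohort)
  expect_identical(scan, scan2)

  single <- assemble_cohort(vteprs:::new_panel(panel[1, ]),
                            gt[1, , drop = FALSE], subjects)
  expect_equal(nrow(association_scan(single, models = "allelic")), 1L)
})

test_that("additive logistic estimate approaches the allelic OR without covariates", {
  sim <- generate_cohort(sim_config(n_case = 1000, n_control = 1000,
                                    seed = 83))
  fit <- logistic_adjusted_or(sim$cohort, "rs2066865",
                              covariates = character(0), coding = "additive")
  dca <- sim$cohort$genotypes["rs2066865", vteprs:::case_ids(sim$cohort)]
  dco <- sim$cohort$genotypes["rs2066865", vteprs:::control_ids(sim$cohort)]
  allelic_or <- odds_ratio(allelic_table(dca, dco))
  expect_equal(log(fit$adjusted_or), log(allelic_or), tolerance = 0.08)
})
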
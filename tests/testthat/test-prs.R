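test_that("raw PRS is the weighted dosage sum", {
  panel <- make_test_panel(2)
  gt <- matrix(c(0L, 0L, 2L, 1L), 2, 2,
               dimnames = list(panel$rsid, c("s1", "s2")))
  w <- data.frame(rsid = panel$rsid, beta = c(log(2), log(0.5)))
  res <- compute_prs(gt, w, missing_policy = "zero")
  expect_equal(res$raw_prs[1], 0)
  expect_equal(res$raw_prs[2], 2 * log(2) - log(2))  # = log 2

  # brute-force oracle on a 20 x 50 random problem
  set.seed(19)
  panel20 <- make_test_panel(20)
  gt20 <- matrix(sample(0:2, 1000, TRUE), 20, 50,
                 dimnames = list(panel20$rsid, sprintf("u%02d", 1:50)))
  w20 <- data.frame(rsid = panel20$rsid, beta = rnorm(20))
  res20 <- compute_prs(gt20, w20, missing_policy = "zero")
  beta_map <- setNames(as.list(w20$beta), w20$rsid)
  expect_equal(res20$raw_prs, oracle_prs(gt20, beta_map), tolerance = 1e-12)

  expect_error(compute_prs(gt, w[1, , drop = FALSE], missing_policy = "zero"),
               panel$rsid[2])
})

test_that("missing-dosage policies are applied and counted", {
  panel <- make_test_panel(1)
  gt <- matrix(c(NA_integer_, 1L, 2L, 1L), 1, 4,
               dimnames = list(panel$rsid, c("c1", "c2", "c3", "s4")))
  w <- data.frame(rsid = panel$rsid, beta = 1)
  zero <- compute_prs(gt, w, missing_policy = "zero")
  expect_equal(zero$raw_prs[1], 0)
  expect_equal(zero$n_missing, c(1L, 0L, 0L, 0L))
  # mean control dosage of c2, c3 (controls supplied explicitly) is 1.5
  mean_sub <- compute_prs(gt, w, missing_policy = "mean_dosage_controls",
                          control_ids = c("c2", "c3"))
  expect_equal(mean_sub$raw_prs[1], 1.5)
  expect_error(compute_prs(gt, w, missing_policy = "mean_dosage_controls"),
               "control_ids")
})

test_that("standardization is an exact control-referenced z-score", {
  raw <- data.frame(subject_id = c("a", "b", "c", "x"),
                    raw_prs = c(1, 2, 3, 3))
  std <- standardize_prs(raw, control_ids = c("a", "b", "c"))
  expect_equal(std$z_prs[std$subject_id == "x"], 1)  # sample SD of 1,2,3 is 1
  expect_equal(std$z_prs[std$subject_id == "b"], 0)
  ctrl_z <- std$z_prs[std$subject_id %in% c("a", "b", "c")]
  expect_equal(mean(ctrl_z), 0, tolerance = 1e-10)
  expect_equal(sd(ctrl_z), 1, tolerance = 1e-10)
  expect_error(standardize_prs(data.frame(subject_id = c("a", "b"),
                                          raw_prs = c(2, 2)),
                               control_ids = c("a", "b")), "zero")
})

test_that("PRS is linear in the weights and z is scale-invariant", {
  set.seed(29)
  panel <- make_test_panel(10)
  gt <- matrix(sample(0:2, 300, TRUE), 10, 30,
               dimnames = list(panel$rsid, sprintf("p%02d", 1:30)))
  w <- data.frame(rsid = panel$rsid, beta = rnorm(10))
  ctrl <- sprintf("p%02d", 1:15)
  r1 <- compute_prs(gt, w, missing_policy = "zero")
  w2 <- transform(w, beta = 3 * beta)
  r2 <- compute_prs(gt, w2, missing_policy = "zero")
  expect_equal(r2$raw_prs, 3 * r1$raw_prs, tolerance = 1e-12)
  z1 <- standardize_prs(r1, ctrl)
  z2 <- standardize_prs(r2, ctrl)
  expect_equal(z1$z_prs, z2$z_prs, tolerance = 1e-10)
})

test_that("median split sends ties to the low group", {
  expect_equal(median_split(c(-1, 0, 1)), c("low", "low", "high"))
  expect_warning(labels <- median_split(rep(2, 5)), "degenerate")
  expect_true(all(labels == "low"))
  set.seed(37)
  z <- rnorm(101)  # odd n, no ties: high group excludes the median point
  sp <- median_split(z)
  expect_equal(abs(sum(sp == "low") - sum(sp == "high")), 1L)
})

test_that("OR by PRS bin contrasts against the reference bin", {
  z <- c(rep(-1, 40), rep(1, 40))
  status <- rep(c("case", "control"), 40)   # equal case fraction per bin
  res <- or_by_prs_bin(z, status, bin_edges = 0)
  expect_equal(nrow(res), 2L)
  expect_equal(res$or_estimate[2], 1)
  # a bin spanning every value offers no contrast
  expect_error(or_by_prs_bin(z, status, bin_edges = 10), "no contrast")
  expect_error(or_by_prs_bin(z, status, bin_edges = numeric(0)), "bin edge")

  # logistic risk increasing in z gives non-decreasing bin ORs (fixed seed)
  set.seed(43)
  n <- 4000
  zz <- rnorm(n)
  st <- ifelse(runif(n) < plogis(-0.5 + 0.9 * zz), "case", "control")
  res2 <- or_by_prs_bin(zz, st)
  ors <- res2$or_estimate
  expect_true(all(diff(ors) > 0))
})

test_that("OR per SD recovers the generating logistic coefficient", {
  set.seed(47)
  n <- 5000
  z <- rnorm(n)
  beta_true <- log(1.6)
  status <- rbinom(n, 1, plogis(-0.3 + beta_true * z))
  fit <- glm(status ~ z, family = binomial())
  se <- sqrt(vcov(fit)["z", "z"])
  expect_lt(abs(coef(fit)[["z"]] - beta_true), 4 * se)
})

test_that("prs_stage ties the stages together on a cohort", {
  cohort <- make_small_cohort(30, 30, seed = 53)
  prs <- prs_stage(cohort)
  expect_equal(nrow(prs), 60L)
  ctrl_z <- prs$z_prs[prs$status == "control"]
  expect_equal(mean(ctrl_z), 0, tolerance = 1e-10)
  expect_equal(sd(ctrl_z), 1, tolerance = 1e-10)
  expect_setequal(unique(prs$prs_group), c("low", "high"))
  # cohort-weight mode falls back to literature weights on degenerate ORs
  scan <- association_scan(cohort, models = "allelic")
  w <- prs_weights(cohort$panel, source = "cohort", cohort_scan = scan)
  expect_true(all(is.finite(w$beta)))
})
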
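test_that("call rate is the exact non-missing fraction", {
  m <- matrix(0L, 2, 20, dimnames = list(c("rs1", "rs2"), NULL))
  m[2, 1] <- NA
  cr <- call_rate(m)
  expect_equal(unname(cr), c(1.00, 0.95))

  set.seed(3)
  big <- matrix(sample(c(0:2, NA), 500, TRUE, prob = c(.3, .3, .3, .1)),
                10, 50)
  rownames(big) <- paste0("v", 1:10)
  brute <- apply(big, 1, function(r) sum(!is.na(r)) / length(r))
  expect_equal(unname(call_rate(big)), unname(brute))
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25))
  expect_equal(hwe_exact_test(50, 0, 50), oracle_hwe(50, 0, 50))
  # extreme-tail case is the sum of the most improbable configurations
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 0))
})

test_that("HWE exact test equals the recurrence oracle across genotype triples", {
  # exhaustive sweep over every triple with small totals
  for (n in c(1:10, 20, 35)) {
    for (n00 in 0:n) for (n01 in 0:(n - n00)) {
      n02 <- n - n00 - n01
      expect_equal(hwe_exact_test(n00, n01, n02),
                   oracle_hwe(n00, n01, n02), tolerance = 1e-10)
    }
  }
  # seeded random triples at larger totals
  set.seed(99)
  for (i in 1:200) {
    n <- sample(40:200, 1)
    split <- sort(sample(0:n, 2))
    tri <- c(split[1], split[2] - split[1], n - split[2])
    expect_equal(hwe_exact_test(tri[1], tri[2], tri[3]),
                 oracle_hwe(tri[1], tri[2], tri[3]), tolerance = 1e-10)
  }
})

test_that("HWE exact p-values are uniform-conservative under HWE", {
  set.seed(1234)
  n_sites <- 1500L
  p <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    eaf <- runif(1, 0.05, 0.95)
    d <- simulate_genotypes(87, eaf)
    p[i] <- hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  rate <- mean(p <= 0.05)
  # exact conditional test is conservative: type-I error at or below nominal
  # (allow 2 binomial SEs above for sampling noise)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sites))
})

test_that("replicate concordance counts agreeing non-missing cells", {
  m <- matrix(rep(1L, 20), 4, 5, dimnames = list(paste0("r", 1:4), paste0("s", 1:5)))
  expect_equal(replicate_concordance(m, m), 1)
  m2 <- m; m2[1, 1] <- 2L
  expect_equal(replicate_concordance(m, m2), 0.95)

  set.seed(8)
  a <- matrix(sample(0:2, 200, TRUE), 10, 20,
              dimnames = list(paste0("r", 1:10), paste0("s", 1:20)))
  b <- a
  k <- 13L
  flip <- sample(length(a), k)
  b[flip] <- (a[flip] + 1L) %% 3L
  expect_equal(replicate_concordance(a, b), (200 - k) / 200)
  expect_error(replicate_concordance(a, b[, 1:10]), "share")
})

test_that("apply_qc drops low-call-rate variants and respects thresholds", {
  cohort <- make_small_cohort(30, 30, seed = 21)
  # clean HWE cohort with no missingness: call-rate filter drops nothing
  res <- apply_qc(cohort)
  expect_true(all(res$report$call_rate == 1))
  expect_false(any(res$report$flag_low_call_rate))

  # 10% missing calls on one variant -> dropped under the default threshold
  cohort$genotypes[1, 1:6] <- NA   # 6/60 missing -> call rate 0.90
  res <- apply_qc(cohort)
  expect_true(res$report$flag_low_call_rate[1])
  expect_false(rownames(cohort$genotypes)[1] %in%
                 rownames(res$cohort$genotypes))

  # exactly at the threshold fails the strict > rule
  cohort2 <- make_small_cohort(30, 30, seed = 22)
  cohort2$genotypes[2, 1:3] <- NA  # call rate exactly 0.95
  res2 <- apply_qc(cohort2)
  expect_true(res2$report$flag_low_call_rate[2])

  # hwe_alpha = 0 disables the HWE filter
  bad_hwe <- make_small_cohort(5, 60, seed = 23)
  ctrl <- bad_hwe$subjects$subject_id[bad_hwe$subjects$status == "control"]
  # no heterozygotes at p ~ 0.5: gross HWE violation
  bad_hwe$genotypes[3, ctrl] <- rep(c(0L, 2L), length.out = 60)
  res3 <- apply_qc(bad_hwe, hwe_alpha = 0.05)
  expect_true(res3$report$flag_hwe_fail[3])
  res4 <- apply_qc(bad_hwe, hwe_alpha = 0)
  expect_false(any(res4$report$flag_hwe_fail))
})

test_that("QC under the generator's HWE guarantee keeps essentially all variants", {
  sim <- generate_cohort(sim_config(seed = 31))
  res <- apply_qc(sim$cohort)
  expect_false(any(res$report$flag_low_call_rate))
  # 38 variants tested at alpha = 0.05: allow the multiplicity-expected
  # handful of chance HWE failures, no more
  expect_lte(sum(res$report$flag_hwe_fail), qbinom(0.999, 38, 0.05))
})

test_that("apply_qc is order-independent across variants", {
  cohort <- make_small_cohort(20, 20, seed = 41)
  cohort$genotypes[2, 1:5] <- NA
  res <- apply_qc(cohort)
  perm <- rev(seq_len(nrow(cohort$genotypes)))
  cohort_p <- cohort
  cohort_p$genotypes <- cohort$genotypes[perm, ]
  cohort_p$panel <- vteprs:::new_panel(cohort$panel[perm, ])
  res_p <- apply_qc(cohort_p)
  expect_setequal(rownames(res$cohort$genotypes),
                  rownames(res_p$cohort$genotypes))
})
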
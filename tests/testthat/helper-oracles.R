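# Independent oracles used to check the package's statistics. Each is
# implemented by a different route than the package code.

# HWE exact p-value by the heterozygote-count recurrence (the package uses a
# closed-form log-gamma expression instead)
oracle_hwe <- function(n_hom_ref, n_het, n_hom_eff) {
  n_eff <- 2L * n_hom_eff + n_het
  n_oth <- 2L * n_hom_ref + n_het
  hmax <- min(n_eff, n_oth)
  hs <- seq.int(hmax %% 2L, hmax, by = 2L)
  probs <- numeric(length(hs))
  probs[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    a <- (n_eff - h) / 2   # hom-effect count at h
    b <- (n_oth - h) / 2
    probs[k] <- probs[k - 1] * 4 * a * b / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided Fisher p by explicit enumeration over the support of cell a
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(c1, r1)
  lw <- lchoose(r1, support) + lchoose(r2, c1 - support)
  w <- exp(lw - max(lw))
  probs <- w / sum(w)
  obs <- probs[match(a, support)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# product-limit estimator by direct risk-set recount
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}

# two-group log-rank chi-square by direct O/E/V accumulation
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & g == 1L)
    n2 <- sum(time >= t & g == 2L)
    nt <- n1 + n2
    dt <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / nt
    if (nt > 1)
      V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  (O1 - E1)^2 / V
}

# exact conditional CI bound by coarse-to-fine grid search on log(psi)
oracle_exact_ci_lower <- function(a, b, c, d, level = 0.95) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(c1, r1)
  upper_tail <- function(lp) {
    lw <- lchoose(r1, support) + lchoose(r2, c1 - support) + support * lp
    w <- exp(lw - max(lw))
    sum(w[support >= a]) / sum(w)
  }
  target <- (1 - level) / 2
  grid <- seq(-40, 40, length.out = 20001)
  vals <- vapply(grid, upper_tail, numeric(1))
  i <- which(vals >= target)[1]   # upper tail increases with psi
  # linear interpolation between bracketing grid points
  x0 <- grid[i - 1]; x1 <- grid[i]
  y0 <- vals[i - 1]; y1 <- vals[i]
  exp(x0 + (target - y0) * (x1 - x0) / (y1 - y0))
}

# brute-force weighted dosage sum
oracle_prs <- function(genotypes, beta_by_rsid) {
  out <- numeric(ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    s <- 0
    for (i in seq_len(nrow(genotypes))) {
      d <- genotypes[i, j]
      if (!is.na(d)) s <- s + beta_by_rsid[[rownames(genotypes)[i]]] * d
    }
    out[j] <- s
  }
  out
}
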
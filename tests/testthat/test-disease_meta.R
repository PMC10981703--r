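test_that("multiplicative replacement fills zeros and preserves the unit sum", {
  out <- multiplicative_replacement(c(0.5, 0.5, 0), delta = 0.001)
  expect_equal(out, c(0.4995, 0.4995, 0.001), tolerance = 1e-12)

  x <- c(0.2, 0.3, 0.5)
  expect_identical(multiplicative_replacement(x), x)

  set.seed(3)
  for (i in 1:10) {
    x <- rgamma(8, 0.3)
    x[sample(8, 3)] <- 0
    x <- x / sum(x)
    out <- multiplicative_replacement(x)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_true(all(out > 0))
  }
  expect_error(multiplicative_replacement(c(0.5, 0.5, 0, 0, 0), delta = 0.4),
               "delta")
})

test_that("clr transform matches hand evaluation and sums to zero", {
  out <- clr_transform(c(0.5, 0.25, 0.25))
  lx <- log(c(0.5, 0.25, 0.25))
  expect_equal(out, lx - mean(lx), tolerance = 1e-15)
  expect_equal(round(out, 4), c(0.4621, -0.2310, -0.2310))

  expect_equal(clr_transform(rep(0.25, 4)), rep(0, 4))
  set.seed(8)
  for (i in 1:10) {
    x <- rgamma(6, 1)
    x <- x / sum(x)
    expect_equal(sum(clr_transform(x)), 0, tolerance = 1e-12)
  }
  expect_error(clr_transform(c(0.5, 0.5, 0)), "positive")
})

test_that("clr of a matrix is scale invariant and matches the per-row path", {
  set.seed(13)
  mat <- matrix(rlnorm(60), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("sp", 1:6)))
  mat[sample(60, 12)] <- 0
  mat[, 1] <- pmax(mat[, 1], 0.01)  # keep rows nonzero
  clr1 <- stentmb:::clr_matrix(mat)
  expect_equal(stentmb:::clr_matrix(mat * 7.3), clr1, tolerance = 1e-12)

  frac <- mat / rowSums(mat)
  delta <- min(frac[frac > 0]) / 2
  manual <- t(apply(frac, 1, function(x)
    clr_transform(multiplicative_replacement(x, delta))))
  dimnames(manual) <- dimnames(mat)
  expect_equal(clr1, manual, tolerance = 1e-12)
})

test_that("adjusted linear model matches a brute-force normal-equations solve", {
  set.seed(21)
  n <- 20
  cov <- data.frame(age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5),
                    bmi = rnorm(n, 25, 3), depth = round(rlnorm(n, 16, 0.4)))
  status <- rep(c(1, 0), each = n / 2)
  y <- 0.3 * status + 0.02 * cov$age + rnorm(n)
  fit <- fit_adjusted_model(y, status, cov)
  X <- cbind(1, status, cov$age, cov$sex, cov$bmi, log10(cov$depth))
  oracle <- ols_oracle(X, y)
  expect_equal(fit$beta_disease, oracle$beta[2], tolerance = 1e-10)
  expect_equal(fit$se_beta, oracle$se[2], tolerance = 1e-10)
  expect_equal(fit$df, n - 6)

  # exact fit when noise is zero
  y0 <- 0.8 * status
  fit0 <- fit_adjusted_model(y0, status, cov)
  expect_equal(fit0$beta_disease, 0.8, tolerance = 1e-10)

  # collinear design is refused with the column named
  cov_bad <- cov
  cov_bad$bmi <- 2 * cov_bad$age
  expect_error(fit_adjusted_model(y, status, cov_bad), "collinear")
})

test_that("t-to-SMD conversion matches the stated formulas", {
  out <- smd_from_t(2, df = 94, n_case = 50, n_control = 50)
  expect_equal(out$d, 2 * 100 / (50 * sqrt(94)), tolerance = 1e-12)
  expect_equal(out$var_d, 100 / 2500 + out$d^2 / 200, tolerance = 1e-12)

  out0 <- smd_from_t(0, df = 40, n_case = 30, n_control = 12)
  expect_equal(out0$d, 0)
  expect_equal(out0$var_d, 1 / 30 + 1 / 12, tolerance = 1e-12)

  d1 <- smd_from_t(1, 50, 20, 25)$d
  expect_equal(smd_from_t(3, 50, 20, 25)$d, 3 * d1, tolerance = 1e-12)
  expect_error(smd_from_t(1, 50, 0, 25), "positive")
})

test_that("DerSimonian-Laird pooling matches hand values, the oracle and metafor", {
  fit <- dl_random_effects(c(0.2, 0.6), c(0.04, 0.04))
  expect_equal(fit$Q, 2.0, tolerance = 1e-12)
  expect_equal(fit$tau2, 0.04, tolerance = 1e-12)
  expect_equal(fit$pooled_d, 0.4, tolerance = 1e-12)
  expect_equal(fit$se, 0.2, tolerance = 1e-12)

  # degenerate: all effects equal
  fit_eq <- dl_random_effects(rep(0.5, 4), rep(0.02, 4))
  expect_equal(fit_eq$pooled_d, 0.5)
  expect_equal(fit_eq$Q, 0)
  expect_equal(fit_eq$tau2, 0)

  # k = 1 passthrough
  f1 <- dl_random_effects(0.3, 0.01)
  expect_true(f1$singleton)
  expect_equal(f1$pooled_d, 0.3)
  expect_equal(f1$se, 0.1)

  set.seed(17)
  for (k in 2:5) {
    d <- rnorm(k, 0.3, 0.3)
    v <- runif(k, 0.01, 0.1)
    fit <- dl_random_effects(d, v)
    oracle <- dl_oracle(d, v)
    expect_equal(fit$pooled_d, oracle$pooled_d, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
    expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-10)
    mf <- metafor::rma(yi = d, vi = v, method = "DL")
    expect_equal(fit$pooled_d, as.numeric(mf$beta), tolerance = 1e-10)
    expect_equal(fit$tau2, mf$tau2, tolerance = 1e-10)
    # ordering invariance
    perm <- sample(k)
    expect_equal(dl_random_effects(d[perm], v[perm])$pooled_d, fit$pooled_d,
                 tolerance = 1e-12)
  }
})

test_that("DL reduces to fixed-effect pooling when tau2 is zero", {
  d <- c(0.30, 0.31, 0.29)
  v <- c(0.05, 0.04, 0.06)
  fit <- dl_random_effects(d, v)
  expect_equal(fit$tau2, 0)
  w <- 1 / v
  expect_equal(fit$pooled_d, sum(w * d) / sum(w), tolerance = 1e-12)
  expect_equal(fit$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("two-level synthesis pools diseases then an overall score", {
  effects <- data.frame(
    species_id = "sp1",
    dataset_id = paste0("ds", 1:16),
    disease_id = rep(paste0("D", 1:12), c(2, 2, 2, 2, rep(1, 8))),
    d = 0.5, var_d = 0.04
  )
  res <- two_level_synthesis(effects)
  overall <- res[res$scope == "overall", ]
  expect_equal(nrow(res), 13)      # 12 per-disease rows + overall
  expect_equal(overall$k, 12L)     # four meta-analyses + eight coefficients
  expect_equal(overall$pooled_d, 0.5, tolerance = 1e-12)
  expect_equal(res$k[res$scope == "D1"], 2L)

  # a species missing from one disease reduces k
  effects2 <- effects[effects$disease_id != "D5", ]
  res2 <- two_level_synthesis(effects2)
  expect_equal(res2$k[res2$scope == "overall"], 11L)
})

test_that("BH adjustment and association gates behave as stated", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(2)
  p <- runif(30)
  expect_true(all(bh_fdr(p) >= p))

  res <- data.frame(species_id = c("a", "b", "c"), scope = "overall",
                    pooled_d = c(0.35, 0.15, 0.50), se = 0.1,
                    ci_lo = 0, ci_hi = 0, Q = 0, tau2 = 0, k = 3L,
                    p = c(0.001, 0.001, 0.9))
  out <- call_associations(res)
  # q = 0.0015 & d = 0.35 -> associated; small effect or high q -> not
  expect_true(out$associated[1])
  expect_false(out$associated[2])
  expect_false(out$associated[3])

  # boundary strictness: q or |d| exactly at the threshold is not associated
  res2 <- res
  res2$p <- c(0.2, 0.2, 0.2)
  res2$q_manual <- bh_fdr(res2$p)
  res2$pooled_d <- c(0.2, 0.21, 0.3)
  out2 <- call_associations(res2)
  expect_false(out2$associated[1])  # |d| exactly 0.2
  expect_false(out2$associated[3])  # q exactly 0.2
})

test_that("negative controls: no planted effect means centered estimates", {
  panel <- gen_case_control_panel(
    panel_spec(diseases = small_panel_layout(40), n_species = 30, seed = 5))
  fit <- meta_disease_association(panel)
  overall <- fit$results[fit$results$scope == "overall", ]
  expect_lt(abs(mean(overall$pooled_d)), 0.05)
  expect_equal(nrow(overall), 30)
})
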
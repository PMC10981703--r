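test_that("alpha diversity matches closed forms", {
  mat <- make_matrix(0, 3, 4)
  mat[1, ] <- 25                     # uniform over 4 species
  mat[2, 1] <- 100                   # single species
  mat[3, 1:3] <- c(50, 25, 25)
  pt <- make_profile(mat)
  div <- alpha_diversity(pt)
  expect_equal(div$richness, c(4L, 1L, 3L))
  expect_equal(div$shannon[1], log(4), tolerance = 1e-10)
  expect_equal(div$simpson[1], 0.75, tolerance = 1e-10)
  expect_equal(div$shannon[2], 0)
  expect_equal(div$simpson[2], 0)
  expect_equal(div$shannon[3],
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-10)

  mat0 <- make_matrix(0, 2, 4)
  mat0[1, 1] <- 100
  expect_warning(div0 <- alpha_diversity(make_profile(mat0)), "all-zero")
  expect_equal(div0$richness[2], 0L)
  expect_equal(div0$shannon[2], 0)
})

test_that("Shannon is maximal at uniform composition for fixed richness", {
  set.seed(11)
  for (s in c(3, 8, 20)) {
    mat <- make_matrix(0, 6, s)
    mat[1, ] <- 100 / s
    for (i in 2:6) {
      w <- rgamma(s, 0.4)
      mat[i, ] <- 100 * w / sum(w)
    }
    div <- alpha_diversity(make_profile(mat))
    expect_true(all(div$shannon[1] >= div$shannon[-1]))
    expect_true(all(div$simpson >= 0 & div$simpson <= 1 - 1 / s + 1e-12))
  }
})

test_that("arcsine square-root transform has the stated closed forms", {
  expect_equal(arcsin_sqrt_transform(0), 0)
  expect_equal(arcsin_sqrt_transform(1), pi / 2)
  expect_equal(arcsin_sqrt_transform(0.25), pi / 6, tolerance = 1e-12)
  expect_equal(arcsin_sqrt_transform(25, percent = TRUE), pi / 6,
               tolerance = 1e-12)
  expect_error(arcsin_sqrt_transform(1.2), "above 1")
})

test_that("Bray-Curtis matches the formula and stays in [0, 1]", {
  m <- rbind(a = c(0.7, 0.3), b = c(0.3, 0.7))
  colnames(m) <- c("x", "y")
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.4, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))

  m2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  colnames(m2) <- c("x", "y")
  d2 <- bray_curtis(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)

  m3 <- rbind(a = c(1, 2), b = c(0, 0), c = c(0, 0))
  colnames(m3) <- c("x", "y")
  expect_warning(d3 <- bray_curtis(m3), "all-zero")
  expect_equal(d3["b", "c"], 0)

  set.seed(2)
  m4 <- matrix(runif(40), 8, 5,
               dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  d4 <- bray_curtis(m4)
  expect_true(all(d4 >= 0 & d4 <= 1))
  expect_equal(d4, t(d4))
})

test_that("Bray-Curtis shrinks as one sample moves proportionally toward the other", {
  x <- c(5, 1, 0, 2)
  y <- c(1, 3, 4, 0)
  steps <- seq(0, 1, by = 0.25)
  dists <- vapply(steps, function(a) {
    m <- rbind(p = x + a * (y - x), q = y)
    colnames(m) <- paste0("f", 1:4)
    bray_curtis(m)["p", "q"]
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
  expect_equal(dists[length(dists)], 0)
})

test_that("PCoA reconstructs Euclidean configurations and handles degeneracy", {
  # collinear points: first axis recovers the line up to sign
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  fit <- suppressWarnings(pcoa_ordination(d, k = 2))
  ax1 <- fit$coordinates[, 1]
  expect_equal(abs(diff(ax1)), c(1, 1), tolerance = 1e-8,
               ignore_attr = TRUE)

  # equidistant triple: two equal positive eigenvalues
  d2 <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(d2) <- 0
  eig <- pcoa_ordination(d2, k = 2)$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_true(eig[2] > 0)

  # Euclidean-embeddable distances are reproduced exactly
  set.seed(9)
  pts <- matrix(rnorm(30), 10, 3)
  rownames(pts) <- paste0("s", 1:10)
  d3 <- as.matrix(dist(pts))
  fit3 <- suppressWarnings(pcoa_ordination(d3, k = 9))
  expect_equal(as.matrix(dist(fit3$coordinates)), d3, tolerance = 1e-8)

  expect_warning(z <- pcoa_ordination(matrix(0, 1, 1), k = 2), "zero-dimensional")
  expect_equal(ncol(z$coordinates), 0)
})

test_that("PERMANOVA separates planted clusters and rejects bad groupings", {
  m <- rbind(matrix(rep(c(1, 0, 0, 0), each = 10), 10),
             matrix(rep(c(0, 0, 0, 1), each = 10), 10))
  rownames(m) <- paste0("x", 1:20)
  colnames(m) <- paste0("f", 1:4)
  d <- bray_curtis(m)
  fit <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 199, seed = 1)
  expect_equal(fit$p, 1 / 200)

  expect_error(permanova(d, c("a", rep("b", 19)), n_perm = 99, seed = 1),
               "size 1")
  expect_error(permanova(d, rep("a", 20), n_perm = 99, seed = 1),
               "at least two groups")

  # constant zero distances: F = 0, p = 1
  dz <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  expect_warning(fz <- permanova(dz, rep(c("a", "b"), 3), n_perm = 99, seed = 1),
                 "constant")
  expect_equal(fz$pseudo_F, 0)
  expect_equal(fz$p, 1)
})

test_that("PERMANOVA pseudo-F agrees with vegan and ignores sample order", {
  set.seed(4)
  m <- matrix(runif(80), 16, 5,
              dimnames = list(paste0("s", 1:16), paste0("f", 1:5)))
  g <- rep(c("a", "b"), each = 8)
  d <- bray_curtis(m)
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 2)
  expect_equal(fit$pseudo_F, ad$F[1], tolerance = 1e-10)

  perm <- sample(16)
  fit2 <- permanova(d[perm, perm], g[perm], n_perm = 99, seed = 1)
  expect_equal(fit2$pseudo_F, fit$pseudo_F, tolerance = 1e-12)
})

test_that("Mann-Whitney matches exact enumeration and its U identity", {
  fit <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(fit$U, 0)
  expect_equal(fit$p_two_sided, 0.1, tolerance = 1e-12)

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)

  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(7)
    b <- rnorm(9)
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 7 * 9)
  }
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Spearman correlation matches hand ranks", {
  expect_equal(spearman_cor(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_cor(1:5, rev(1:5))$rho, -1)
  fit <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(fit$rho, 0.8, tolerance = 1e-12)
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("prevalence, dominance and the 83.0% worked example", {
  # one species present in 39 of 47 samples
  mat <- make_matrix(0, 47, 3)
  mat[, 1] <- 5
  mat[1:39, 2] <- 50
  mat[, 3] <- 1
  rec <- prevalence_and_dominance(make_profile(mat))
  expect_equal(rec$prevalence[2], 39 / 47)
  expect_equal(round(100 * rec$prevalence[2], 1), 83.0)
  expect_equal(rec$prevalence[1], 1)

  # absent species: prevalence 0, never dominant
  mat2 <- make_matrix(0, 4, 3)
  mat2[, 1] <- c(50, 30, 20, 10)
  mat2[, 2] <- c(30, 50, 60, 70)
  rec2 <- prevalence_and_dominance(make_profile(mat2))
  expect_equal(rec2$prevalence[3], 0)
  expect_equal(rec2$n_dominant[3], 0L)
  expect_equal(sum(rec2$n_dominant), 4L)

  # (A:50, B:30, C:20) -> dominant A; ties broken lexicographically
  mat3 <- make_matrix(0, 2, 3)
  mat3[1, ] <- c(50, 30, 20)
  mat3[2, ] <- c(40, 40, 20)
  expect_message(rec3 <- prevalence_and_dominance(make_profile(mat3)), "tie")
  expect_equal(rec3$n_dominant, c(2L, 0L, 0L))
})

test_that("oral membership is strict at 50% reference prevalence", {
  mat <- make_matrix(10, 4, 3)
  rec <- prevalence_and_dominance(make_profile(mat))
  ref <- data.frame(sgb_id = c("t__SGB001", "t__SGB002"),
                    oral = c(0.60, 0.50))
  out <- classify_body_site(rec, ref)
  expect_true(out$oral_member[1])
  expect_false(out$oral_member[2])
  expect_true(is.na(out$oral_member[3]))
})

test_that("trait fractions reproduce the prevalent-species arithmetic", {
  mat <- make_matrix(100 / 36, 4, 36)
  rec <- prevalence_and_dominance(make_profile(mat))
  expect_true(all(rec$prevalent))
  tt <- data.frame(sgb_id = rec$sgb_id,
                   facultative_anaerobe = rep(c(1, 0), c(18, 18)),
                   gram_positive = rep(c(1, 0), c(21, 15)),
                   ferments_glucose = rep(c(1, 0), c(30, 6)),
                   all_missing = NA)
  expect_warning(fr <- trait_fraction(rec, tt), "all_missing")
  expect_equal(fr$fraction[fr$trait == "facultative_anaerobe"], 0.5)
  expect_equal(round(100 * fr$fraction[fr$trait == "gram_positive"], 1), 58.3)
  expect_equal(round(100 * fr$fraction[fr$trait == "ferments_glucose"], 1), 83.3)
  expect_false("all_missing" %in% fr$trait)
})
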
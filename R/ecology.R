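#' Per-sample alpha diversity
#'
#' Computes SGB richness, Shannon entropy (natural log) and the Gini-Simpson
#' index for every sample. An SGB counts as detected when its abundance is
#' strictly greater than `cfg$detection_threshold`; detected abundances are
#' renormalized to proportions before the entropy calculations (Shannon and
#' Simpson are delegated to \pkg{vegan}). An all-zero sample gets richness 0
#' and, with a warning, Shannon and Simpson reported as 0.
#'
#' @param t A [profile_table()] or a nonnegative sample-by-SGB matrix.
#' @param cfg An [analysis_config()] (detection threshold).
#' @return `data.frame` with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(t, cfg = analysis_config()) {
  mat <- if (inherits(t, "profile_table")) t$abundances else t
  stop_unless(is.matrix(mat) && all(mat >= 0), "abundances must be nonnegative")
  detected <- mat > cfg$detection_threshold
  richness <- rowSums(detected)
  masked <- mat * detected
  shannon <- as.numeric(vegan::diversity(masked, index = "shannon"))
  simpson <- as.numeric(vegan::diversity(masked, index = "simpson"))
  empty <- richness == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero sample(s); Shannon/Simpson reported as 0",
            call. = FALSE)
    shannon[empty] <- 0
    simpson[empty] <- 0
  }
  data.frame(sample_id = rownames(mat), richness = as.integer(richness),
             shannon = shannon, simpson = simpson, stringsAsFactors = FALSE)
}

#' Arcsine square-root transform
#'
#' The variance-stabilizing transform applied to fractional relative
#' abundances before Bray-Curtis distances are computed: `asin(sqrt(p))`,
#' mapping `[0,1]` to `[0, pi/2]`.
#'
#' @param p Numeric vector/matrix of fractional abundances in `[0,1]`, or in
#'   percent when `percent = TRUE` (divided by 100 first).
#' @param percent Set `TRUE` when `p` is on the 0-100 scale.
#' @return Transformed values, same shape as `p`.
#' @export
arcsin_sqrt_transform <- function(p, percent = FALSE) {
  if (percent) p <- p / 100
  stop_unless(all(p >= 0), "abundances must be nonnegative")
  if (any(p > 1 + 1e-12)) {
    stop("abundance above 1 after normalization; pass percent = TRUE for 0-100 input",
         call. = FALSE)
  }
  asin(sqrt(pmin(p, 1)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities `sum|x_i - y_i| / sum(x_i + y_i)`
#' between sample rows, computed with [vegan::vegdist()]. Pairs of all-zero
#' samples have an undefined dissimilarity and are reported as 0 with a
#' warning.
#'
#' @param x Nonnegative sample-by-feature matrix (typically arcsine-sqrt
#'   transformed fractional abundances) or a [profile_table()].
#' @return Symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0,1]`, sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  mat <- if (inherits(x, "profile_table")) x$abundances else x
  stop_unless(is.matrix(mat) && all(mat >= 0), "input must be a nonnegative matrix")
  # vegdist warns about all-zero rows; we handle that case explicitly below
  d <- as.matrix(suppressWarnings(vegan::vegdist(mat, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero sample pair(s); Bray-Curtis reported as 0", call. = FALSE)
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Ordination of a distance matrix by eigendecomposition of the double-centred
#' `-d^2/2` matrix ([stats::cmdscale()]). Negative eigenvalues (from
#' non-Euclidean dissimilarities) are clipped from the explained-variance
#' denominator and reported. If fewer than `k` positive axes exist, the
#' available axes are returned with a warning.
#'
#' @param d Symmetric distance matrix or `dist`.
#' @param k Number of coordinate axes requested (default 2).
#' @return List with `coordinates` (samples x axes), `eigenvalues`,
#'   `explained` (fraction of positive-eigenvalue variance per returned axis)
#'   and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 2) {
    warning("fewer than two samples; returning zero-dimensional ordination",
            call. = FALSE)
    return(list(coordinates = matrix(numeric(0), nrow = n, ncol = 0),
                eigenvalues = numeric(0), explained = numeric(0),
                negative_eigenvalues = numeric(0)))
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-10]
  coords <- fit$points
  avail <- min(ncol(coords), length(pos))
  if (avail < k) {
    warning("only ", avail, " positive axis/axes available (requested ", k, ")",
            call. = FALSE)
  }
  coords <- coords[, seq_len(avail), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       explained = pos[seq_len(avail)] / sum(pos),
       negative_eigenvalues = eig[eig < -1e-10])
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix. The pseudo-F statistic is
#' computed from squared-distance sums:
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value is the permutation estimate `(1 + #{F* >= F}) / (1 + n_perm)`
#' over random relabelings, which can never be exactly zero.
#'
#' @param d Symmetric distance matrix (or `dist`) over samples.
#' @param groups Group labels, one per sample; at least two groups with at
#'   least two samples each.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permanova` with `pseudo_F`, `p`, `n_perm`,
#'   `groups` (table of group sizes) and the partitioned sums of squares.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1L) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  groups <- as.factor(groups)
  stop_unless(length(groups) == n, "one group label per sample required")
  sizes <- table(groups)
  stop_unless(length(sizes) >= 2, "need at least two groups")
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "),
         call. = FALSE)
  }
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  a <- length(sizes)
  ss_within <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  pseudo_f <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  if (ss_total < 1e-14) {
    warning("constant (zero) distances; F = 0, p = 1", call. = FALSE)
    return(structure(list(pseudo_F = 0, p = 1, n_perm = n_perm, groups = sizes,
                          ss_total = ss_total, ss_within = ss_total),
                     class = "permanova"))
  }
  ssw_obs <- ss_within(groups)
  f_obs <- ((ss_total - ssw_obs) / (a - 1)) / (ssw_obs / (n - a))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (pseudo_f(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs,
                 p = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, groups = sizes,
                 ss_total = ss_total, ss_within = ssw_obs,
                 ss_between = ss_total - ssw_obs),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p, x$n_perm))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]. The p-value is exact
#' (full enumeration) when `n_a * n_b <= 400` and there are no ties, otherwise
#' it uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @return List with `U` (the U statistic of `a`) and `p_two_sided`.
#' @export
mann_whitney <- function(a, b) {
  stop_unless(length(a) > 0 && length(b) > 0, "both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  fit <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                            correct = TRUE)
  list(U = unname(fit$statistic), p_two_sided = fit$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed values; the p-value uses the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. A constant vector has no defined rank correlation and is an error.
#'
#' @param x,y Numeric vectors of equal length at least 3.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  stop_unless(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}
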
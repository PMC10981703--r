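#' Covariate-adjusted linear model for one species
#'
#' Ordinary least squares of a CLR-transformed abundance on disease status
#' adjusted for sex, age, BMI and sequencing depth (depth entered as
#' log10(reads)). The disease coefficient is the adjusted group difference on
#' the CLR scale; its t statistic is later converted to a standardized mean
#' difference.
#'
#' @param y Numeric response (CLR abundance per sample).
#' @param status 0/1 (control/case) or a factor with levels control, case.
#' @param covariates `data.frame` with columns `age`, `sex`, `bmi`, `depth`
#'   (raw read counts; log10 is taken internally).
#' @return List with `beta_disease`, `se_beta`, `t_stat`, `df`
#'   (`n - 6`: intercept + status + 4 covariates).
#' @export
fit_adjusted_model <- function(y, status, covariates) {
  status <- as_status(status)
  stop_unless(all(c("age", "sex", "bmi", "depth") %in% names(covariates)),
              "covariates must contain age, sex, bmi, depth")
  stop_unless(!anyNA(covariates[c("age", "sex", "bmi", "depth")]),
              "covariates must be complete")
  X <- cbind(intercept = 1, status = status,
             age = covariates$age, sex = as.numeric(covariates$sex),
             bmi = covariates$bmi, log10_depth = log10(covariates$depth))
  fit <- ols_multi(X, matrix(y, ncol = 1))
  list(beta_disease = unname(fit$beta[2, 1]), se_beta = unname(fit$se_status[1]),
       t_stat = unname(fit$t_status[1]), df = fit$df)
}

as_status <- function(status) {
  if (is.factor(status) || is.character(status)) {
    status <- as.character(status)
    stop_unless(all(status %in% c("case", "control")),
                "status labels must be 'case'/'control'")
    as.numeric(status == "case")
  } else {
    stop_unless(all(status %in% c(0, 1)), "numeric status must be 0/1")
    as.numeric(status)
  }
}

# Multi-response OLS: one design matrix X (n x p), response matrix Y (n x m).
# Returns the full coefficient matrix plus the status-row (column 2 of X)
# standard errors and t statistics, vectorized over species.
ols_multi <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X)
  stop_unless(n > p, "need more samples than model parameters")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se_status <- sqrt(sigma2 * xtx_inv[2, 2])
  list(beta = beta, se_status = se_status,
       t_status = beta[2, ] / se_status, df = df)
}

#' Standardized mean difference from a model t statistic
#'
#' Converts the disease-term t statistic of a covariate-adjusted linear model
#' into a standardized mean difference and its sampling variance:
#' `d = t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))`,
#' `var_d = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))`.
#' Vectorized over its arguments.
#'
#' @param t_stat t statistic of the disease coefficient.
#' @param df Residual degrees of freedom.
#' @param n_case,n_control Group sizes (both positive).
#' @return List with `d` and `var_d`.
#' @export
smd_from_t <- function(t_stat, df, n_case, n_control) {
  stop_unless(all(n_case > 0) && all(n_control > 0), "group sizes must be positive")
  stop_unless(all(df > 0), "df must be positive")
  n <- n_case + n_control
  d <- t_stat * n / (sqrt(n_case * n_control) * sqrt(df))
  var_d <- n / (n_case * n_control) + d^2 / (2 * n)
  list(d = d, var_d = var_d)
}

#' Per-dataset effect estimates for every species
#'
#' For one case-control dataset: closes the abundance matrix to compositions,
#' imputes zeros multiplicatively, CLR-transforms, fits the covariate-adjusted
#' linear model to every species at once (shared design matrix, multi-response
#' least squares) and converts each disease t statistic to a standardized mean
#' difference.
#'
#' @param dataset A list with `dataset_id`, `disease_id`, `abundances`
#'   (sample x species matrix), `status`, `covariates` (see
#'   [fit_adjusted_model()]).
#' @param delta Zero-replacement value; default half the smallest nonzero
#'   fraction in the dataset.
#' @return `data.frame` with one row per species: `species_id`, `dataset_id`,
#'   `disease_id`, `d`, `var_d`, `n_case`, `n_control`, `t_stat`, `df`.
#' @export
dataset_effects <- function(dataset, delta = NULL) {
  status <- as_status(dataset$status)
  n_case <- sum(status == 1)
  n_control <- sum(status == 0)
  stop_unless(n_case >= 10 && n_control >= 10,
              "each dataset needs at least 10 cases and 10 controls")
  clr <- clr_matrix(dataset$abundances, delta = delta)
  cov <- dataset$covariates
  X <- cbind(intercept = 1, status = status,
             age = cov$age, sex = as.numeric(cov$sex),
             bmi = cov$bmi, log10_depth = log10(cov$depth))
  fit <- ols_multi(X, clr)
  smd <- smd_from_t(fit$t_status, fit$df, n_case, n_control)
  data.frame(species_id = colnames(dataset$abundances),
             dataset_id = dataset$dataset_id,
             disease_id = dataset$disease_id,
             d = as.numeric(smd$d), var_d = as.numeric(smd$var_d),
             n_case = n_case, n_control = n_control,
             t_stat = as.numeric(fit$t_status), df = fit$df,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools effect estimates allowing between-study heterogeneity. With
#' fixed-effect weights `w_i = 1/v_i` and the fixed-effect mean `d_FE`:
#' `Q = sum w_i (d_i - d_FE)^2`;
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`;
#' random-effect weights `w*_i = 1/(v_i + tau2)` give the pooled estimate,
#' `se = 1/sqrt(sum w*)`, and a two-sided normal p-value. A single input
#' (`k = 1`) is passed through with its own variance and flagged.
#'
#' @param d Effect estimates.
#' @param v Sampling variances (all positive).
#' @return List with `pooled_d`, `se`, `ci95` (length-2), `Q`, `tau2`, `k`,
#'   `p`, `singleton`.
#' @export
dl_random_effects <- function(d, v) {
  k <- length(d)
  stop_unless(k >= 1 && length(v) == k, "d and v must be nonempty, equal length")
  stop_unless(all(v > 0), "variances must be positive")
  if (k == 1) {
    se <- sqrt(v)
    return(list(pooled_d = d, se = se, ci95 = d + c(-1, 1) * 1.959963984540054 * se,
                Q = 0, tau2 = 0, k = 1L,
                p = 2 * stats::pnorm(-abs(d / se)), singleton = TRUE))
  }
  w <- 1 / v
  d_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - d_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  w_star <- 1 / (v + tau2)
  pooled <- sum(w_star * d) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  list(pooled_d = pooled, se = se,
       ci95 = pooled + c(-1, 1) * 1.959963984540054 * se,
       Q = Q, tau2 = tau2, k = as.integer(k),
       p = 2 * stats::pnorm(-abs(pooled / se)), singleton = FALSE)
}

#' Two-level synthesis of per-dataset effects
#'
#' Implements the study's hierarchical pooling: diseases represented by
#' multiple datasets are first pooled with [dl_random_effects()]; diseases
#' with a single dataset contribute their single effect estimate directly.
#' The per-disease summaries (each with variance `se^2`) are then combined in
#' a second random-effects meta-analysis into one overall score per species.
#' Species absent from a disease panel simply reduce `k` for that species.
#'
#' @param effects `data.frame` as returned by [dataset_effects()] (rows from
#'   all datasets bound together).
#' @return `data.frame` with one row per species per scope: `species_id`,
#'   `scope` (a disease id or `"overall"`), `pooled_d`, `se`, `ci_lo`,
#'   `ci_hi`, `Q`, `tau2`, `k`, `p`.
#' @export
two_level_synthesis <- function(effects) {
  need <- c("species_id", "disease_id", "d", "var_d")
  stop_unless(all(need %in% names(effects)),
              "effects must have species_id, disease_id, d, var_d")
  species <- unique(effects$species_id)
  diseases_all <- unique(effects$disease_id)
  n_max <- length(species) * (length(diseases_all) + 1L)
  acc <- list(species_id = character(n_max), scope = character(n_max),
              pooled_d = numeric(n_max), se = numeric(n_max),
              ci_lo = numeric(n_max), ci_hi = numeric(n_max),
              Q = numeric(n_max), tau2 = numeric(n_max),
              k = integer(n_max), p = numeric(n_max))
  i <- 0L
  put <- function(sp, scope, pool) {
    i <<- i + 1L
    acc$species_id[i] <<- sp; acc$scope[i] <<- scope
    acc$pooled_d[i] <<- pool$pooled_d; acc$se[i] <<- pool$se
    acc$ci_lo[i] <<- pool$ci95[1]; acc$ci_hi[i] <<- pool$ci95[2]
    acc$Q[i] <<- pool$Q; acc$tau2[i] <<- pool$tau2
    acc$k[i] <<- pool$k; acc$p[i] <<- pool$p
  }
  sp_idx <- split(seq_len(nrow(effects)), effects$species_id)
  for (sp in species) {
    eff_sp <- effects[sp_idx[[sp]], , drop = FALSE]
    dis_idx <- split(seq_len(nrow(eff_sp)), eff_sp$disease_id)
    dd <- numeric(length(dis_idx))
    vv <- numeric(length(dis_idx))
    j <- 0L
    for (dis in names(dis_idx)) {
      rows_d <- dis_idx[[dis]]
      pool <- dl_random_effects(eff_sp$d[rows_d], eff_sp$var_d[rows_d])
      j <- j + 1L
      dd[j] <- pool$pooled_d
      vv[j] <- pool$se^2
      put(sp, dis, pool)
    }
    put(sp, "overall", dl_random_effects(dd, vv))
  }
  acc <- lapply(acc, function(v) v[seq_len(i)])
  do.call(data.frame, c(acc, list(stringsAsFactors = FALSE)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, via
#' [stats::p.adjust()]. The family is whatever vector is passed in one call —
#' here all species-by-scope tests of a run.
#'
#' @param p Vector of p-values in `[0,1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stop_unless(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call disease associations
#'
#' Adds BH q-values over all rows (one family per run) and flags a result as
#' associated when `q` is strictly below `cfg$fdr_threshold` and the absolute
#' pooled standardized mean difference is strictly above
#' `cfg$effect_threshold`. The sign of `pooled_d` carries the direction.
#'
#' @param results Output of [two_level_synthesis()].
#' @param cfg An [analysis_config()].
#' @return `results` with added columns `q` and `associated`.
#' @export
call_associations <- function(results, cfg = analysis_config()) {
  results$q <- bh_fdr(results$p)
  results$associated <- results$q < cfg$fdr_threshold &
    abs(results$pooled_d) > cfg$effect_threshold
  results
}

#' Disease-association meta-analysis of a case-control panel
#'
#' The full association procedure: per-dataset covariate-adjusted effects on
#' CLR abundances ([dataset_effects()]), two-level random-effects pooling
#' ([two_level_synthesis()]) and FDR-gated association calls
#' ([call_associations()]).
#'
#' @param panel A `case_control_panel` (see [gen_case_control_panel()]) or a
#'   plain list of dataset lists.
#' @param cfg An [analysis_config()].
#' @param delta Zero-replacement value forwarded to [dataset_effects()].
#' @return Object of class `meta_assoc`: list with `effects` (per dataset x
#'   species), `results` (per species x scope with `q` and `associated`) and
#'   `cfg`.
#' @export
meta_disease_association <- function(panel, cfg = analysis_config(), delta = NULL) {
  datasets <- if (inherits(panel, "case_control_panel")) panel$datasets else panel
  stop_unless(length(datasets) >= 1, "panel must contain at least one dataset")
  effects <- do.call(rbind, lapply(datasets, dataset_effects, delta = delta))
  results <- call_associations(two_level_synthesis(effects), cfg)
  structure(list(effects = effects, results = results, cfg = cfg),
            class = "meta_assoc")
}

#' @export
print.meta_assoc <- function(x, ...) {
  overall <- x$results[x$results$scope == "overall", , drop = FALSE]
  cat(sprintf("meta_assoc: %d species, %d datasets, %d disease scopes\n",
              length(unique(x$results$species_id)),
              length(unique(x$effects$dataset_id)),
              length(unique(x$results$scope)) - 1L))
  cat(sprintf("  associated overall (q < %.2g, |d| > %.2g): %d species\n",
              x$cfg$fdr_threshold, x$cfg$effect_threshold,
              sum(overall$associated)))
  invisible(x)
}

#' @export
summary.meta_assoc <- function(object, ...) {
  overall <- object$results[object$results$scope == "overall", , drop = FALSE]
  overall <- overall[order(overall$q, -abs(overall$pooled_d)), , drop = FALSE]
  structure(list(overall = overall,
                 n_associated = sum(overall$associated),
                 cfg = object$cfg),
            class = "summary.meta_assoc")
}

#' @export
print.summary.meta_assoc <- function(x, ...) {
  cat("Overall disease-association scores (best first):\n")
  print(utils::head(x$overall, 10), row.names = FALSE)
  cat(sprintf("%d species associated at q < %.2g and |d| > %.2g\n",
              x$n_associated, x$cfg$fdr_threshold, x$cfg$effect_threshold))
  invisible(x)
}
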
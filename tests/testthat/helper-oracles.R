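# Independent oracles and small fixture builders used across the suite.

# Step-by-step DerSimonian-Laird pooling, written directly from the moment
# formulas, independent of the package implementation.
dl_oracle <- function(d, v) {
  k <- length(d)
  w <- 1 / v
  d_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - d_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  list(pooled_d = sum(ws * d) / sum(ws), se = sqrt(1 / sum(ws)),
       Q = Q, tau2 = tau2)
}

# Normal-equations least squares, solved by brute force.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = as.numeric(beta), se = unname(sqrt(sigma2 * diag(xtx_inv))))
}

# Minimal profile table: abundance matrix with generated metadata.
make_profile <- function(mat, reads = NULL, material = NULL, procedure = NULL,
                         patency = NULL) {
  n <- nrow(mat)
  metadata <- data.frame(
    sample_id = rownames(mat),
    patient_id = paste0("P", seq_len(n)),
    material = material %||% rep(c("metallic", "plastic"), length.out = n),
    procedure = procedure %||% rep(c("endoscopy", "surgery"), length.out = n),
    patency_days = patency %||% rep(70L, n),
    microbial_reads = reads %||% rep(5e6, n),
    age = rep(65L, n),
    sex = rep(c("female", "male"), length.out = n),
    stringsAsFactors = FALSE
  )
  profile_table(mat, metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small named abundance matrix with uniform row sums of 100.
make_matrix <- function(values, n_samples, n_sgbs) {
  matrix(values, nrow = n_samples, ncol = n_sgbs,
         dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                         sprintf("t__SGB%03d", seq_len(n_sgbs))))
}

# A 12-disease panel layout (4 diseases x 2 datasets + 8 x 1) at a chosen
# per-dataset size; the layout the two-level synthesis expects.
small_panel_layout <- function(n_case, n_control = n_case) {
  data.frame(disease_id = paste0("D", 1:12),
             n_datasets = c(2L, 2L, 2L, 2L, rep(1L, 8)),
             n_case = n_case, n_control = n_control,
             stringsAsFactors = FALSE)
}
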
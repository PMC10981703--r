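#' Multiplicative zero replacement
#'
#' Replaces zeros in a composition with a small positive value `delta` and
#' shrinks the nonzero parts multiplicatively so the result still sums to 1:
#' zeros become `delta`, nonzeros are scaled by `1 - delta * n_zero`. A
#' zero-free composition is returned unchanged.
#'
#' @param x Nonnegative composition summing to 1 (tolerance 1e-9).
#' @param delta Replacement value; must satisfy `delta * n_zero < 1`. Default
#'   `NULL` means half the smallest nonzero component of `x`.
#' @return Zero-free composition summing to 1.
#' @export
multiplicative_replacement <- function(x, delta = NULL) {
  stop_unless(all(x >= 0), "composition must be nonnegative")
  stop_unless(abs(sum(x) - 1) <= 1e-9, "composition must sum to 1")
  zero <- x == 0
  if (!any(zero)) return(x)
  if (is.null(delta)) delta <- min(x[!zero]) / 2
  stop_unless(delta > 0, "delta must be positive")
  if (delta * sum(zero) >= 1) {
    stop("delta too large: delta * number_of_zeros must be below 1", call. = FALSE)
  }
  out <- x * (1 - delta * sum(zero))
  out[zero] <- delta
  out
}

#' Centered log-ratio transform
#'
#' `clr_i = log(x_i) - mean(log(x))`. Maps a strictly positive composition to
#' an unconstrained real vector summing to zero. Zeros must be imputed first
#' (see [multiplicative_replacement()]).
#'
#' @param x Strictly positive composition (sums to 1 up to tolerance).
#' @return Real vector of the same length, summing to 0.
#' @export
clr_transform <- function(x) {
  if (any(x <= 0)) {
    stop("clr requires strictly positive components; impute zeros first",
         call. = FALSE)
  }
  lx <- log(x)
  lx - mean(lx)
}

# Row-wise closure + multiplicative replacement + clr for a sample x species
# abundance matrix (any nonnegative scale). delta defaults to half the minimum
# nonzero *fraction* observed anywhere in the matrix, shared across samples so
# the imputation is comparable between cases and controls.
clr_matrix <- function(mat, delta = NULL) {
  rs <- rowSums(mat)
  stop_unless(all(rs > 0), "each sample must have positive total abundance")
  frac <- mat / rs
  n_zero <- rowSums(frac == 0)
  if (is.null(delta)) delta <- min(frac[frac > 0]) / 2
  if (any(delta * n_zero >= 1)) {
    stop("delta too large: delta * number_of_zeros must be below 1", call. = FALSE)
  }
  out <- frac * (1 - delta * n_zero)  # row-wise shrink (recycles down columns)
  out[frac == 0] <- delta
  lx <- log(out)
  lx - rowMeans(lx)
}
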
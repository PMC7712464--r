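#' Covariance builders for the simulation designs
#'
#' `factor_covariance()` is the AR-type factor covariance with entries
#' `rho_f^|i-j|`. `model1_error_covariance()` inverts a block-diagonal
#' precision matrix of 2x2 blocks `[[1, 0.8], [0.8, 1]]` — a sparse
#' conditional-dependence structure in which variables are correlated only
#' within pairs. `model2_error_covariance()` is the non-sparse
#' equicorrelated matrix with unit diagonal and all off-diagonals 0.5,
#' whose eigenvalues are `0.5` (multiplicity `p - 1`) and `0.5 + 0.5 p`.
#' All three are symmetric positive definite by construction.
#'
#' @param K Number of factors.
#' @param rho_f AR parameter, `|rho_f| < 1` (default 0.6).
#' @param p Number of variables (`p >= 2`).
#' @return A covariance matrix.
#' @export
factor_covariance <- function(K, rho_f = 0.6) {
  if (!is.finite(rho_f) || abs(rho_f) >= 1) {
    stop("|rho_f| must be strictly below 1")
  }
  rho_f^abs(outer(seq_len(K), seq_len(K), "-"))
}

#' @rdname factor_covariance
#' @export
model1_error_covariance <- function(p) {
  if (p < 2) stop("p must be at least 2")
  prec <- diag(p)
  for (b in seq_len(p %/% 2)) {
    i <- 2L * b - 1L
    prec[i, i + 1L] <- 0.8
    prec[i + 1L, i] <- 0.8
  }
  # odd p: the unpaired last coordinate keeps unit precision, uncoupled
  sigma <- solve(prec)
  (sigma + t(sigma)) / 2
}

#' @rdname factor_covariance
#' @export
model2_error_covariance <- function(p) {
  if (p < 2) stop("p must be at least 2")
  matrix(0.5, p, p) + diag(0.5, p)
}

#' Simulate a factor panel with known loadings
#'
#' Draws a panel from `y_t = B f_t + u_t`: loading rows i.i.d. `N(0, I_K)`
#' (unless a fixed `B` is supplied), factors i.i.d. `N(0, cov_f)` with
#' `cov_f[i,j] = rho_f^|i-j|`, and errors i.i.d. `N(0, Sigma_u)` with
#' `Sigma_u` from the sparse-precision design (`model = 1`) or the
#' equicorrelated design (`model = 2`). The factor and error streams are
#' generated from independent sub-seeds of `seed`, so the draw is
#' reproducible component-wise and factors are independent of errors by
#' construction.
#'
#' @param n_time Sample size `T`.
#' @param p Number of variables.
#' @param K Number of factors (default 3).
#' @param model Error-covariance design, 1 (sparse precision) or 2
#'   (equicorrelated).
#' @param rho_f Factor AR parameter (default 0.6).
#' @param B Optional fixed `p x K` loading matrix; `NULL` draws one.
#' @param seed Optional integer master seed.
#' @param error_chol,factor_chol Optional pre-computed upper-triangular
#'   Cholesky factors of `Sigma_u` and `cov_f`, to amortize the
#'   factorization across many replications; validated against `p`/`K`.
#' @return A list with `panel` (a [factor_panel]), `B` (the true loadings)
#'   and the design parameters.
#' @examples
#' sim <- simulate_panel(n_time = 100, p = 6, model = 2, seed = 42)
#' fit <- fit_loadings(sim$panel)
#' max(abs(fit$B_hat - sim$B))
#' @export
simulate_panel <- function(n_time, p, K = 3, model = 1, rho_f = 0.6,
                           B = NULL, seed = NULL,
                           error_chol = NULL, factor_chol = NULL) {
  if (n_time <= K) stop("n_time must exceed the number of factors K")
  if (p < 2) stop("p must be at least 2")
  if (!model %in% c(1, 2)) stop("model must be 1 or 2")
  if (is.null(factor_chol)) {
    factor_chol <- chol(factor_covariance(K, rho_f))
  }
  if (is.null(error_chol)) {
    sigma_u <- switch(as.character(model),
                      "1" = model1_error_covariance(p),
                      "2" = model2_error_covariance(p))
    error_chol <- chol(sigma_u)
  }
  stopifnot(ncol(factor_chol) == K, ncol(error_chol) == p)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    list(derive_seed(seed, 11), derive_seed(seed, 23), derive_seed(seed, 37))
  if (is.null(B)) {
    B <- with_seed_if(seeds[[1]], matrix(rnorm(p * K), p, K))
  } else {
    B <- as.matrix(B)
    stopifnot(nrow(B) == p, ncol(B) == K)
  }
  Fm <- with_seed_if(seeds[[2]],
                     matrix(rnorm(n_time * K), n_time, K)) %*% factor_chol
  U <- with_seed_if(seeds[[3]],
                    matrix(rnorm(n_time * p), n_time, p)) %*% error_chol
  Y <- Fm %*% t(B) + U
  list(panel = factor_panel(Y, Fm), B = B,
       n_time = n_time, p = p, K = K, model = model, rho_f = rho_f,
       seed = seed)
}

#' Null-value tables for the simulation alternatives
#'
#' `power_curve_nulls()` offsets every tested null by `-c/40` from the true
#' loadings (so the truth sits `c/40` above the null, the power-curve
#' design with `c = 0.8 * ell`). `shifted_nulls()` offsets the first `s0`
#' nulls by `shift` and leaves the rest at the truth — the sparse-signal
#' multiple-testing design (shift 0.5 under the sparse-precision errors,
#' 0.35 under equicorrelated errors).
#'
#' @param B True loading matrix.
#' @param k Factor (column) index being tested.
#' @param c Power-curve offset parameter; the per-entry offset is `c / 40`.
#' @param s0 Number of shifted (truly violated) nulls.
#' @param shift Offset added to the first `s0` null values.
#' @return Numeric vector of null values, one per variable.
#' @export
power_curve_nulls <- function(B, k, c) {
  B <- as.matrix(B)
  k <- check_k(k, ncol(B))
  B[, k] - c / 40
}

#' @rdname power_curve_nulls
#' @export
shifted_nulls <- function(B, k, s0, shift) {
  B <- as.matrix(B)
  k <- check_k(k, ncol(B))
  p <- nrow(B)
  if (s0 < 0 || s0 > p) stop("s0 must lie in 0..p")
  null <- B[, k]
  if (s0 > 0) null[seq_len(s0)] <- null[seq_len(s0)] + shift
  null
}
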
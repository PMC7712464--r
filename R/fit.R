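#' Estimate factor loadings by ordinary least squares
#'
#' Fits `y_t = B f_t + u_t` column by column: `B_hat = Y'F (F'F)^{-1}`.
#' Alongside the loading estimates it returns every plug-in quantity the
#' simultaneous tests need: the residual matrix, the residual covariance
#' `Sigma_u_hat = U'U / T` (divisor `T`, no degrees-of-freedom correction),
#' and the inverse factor second moment `Omega_f_hat = (F'F/T)^{-1}`.
#'
#' @param panel A [factor_panel].
#' @param rcond_tol Reciprocal-condition-number threshold for `F'F`; below
#'   it the factors are declared rank-deficient and the fit fails loudly
#'   rather than silently regularizing. Default `1e-12`.
#' @return An object of class `loading_fit` with elements `B_hat` (p x K),
#'   `U_hat` (T x p residuals), `Sigma_u_hat` (p x p), `Omega_f_hat`
#'   (K x K), and the panel dimensions.
#' @examples
#' sim <- simulate_panel(n_time = 100, p = 8, model = 1, seed = 7)
#' fit <- fit_loadings(sim$panel)
#' tidy(fit)
#' @export
fit_loadings <- function(panel, rcond_tol = 1e-12) {
  stopifnot(inherits(panel, "factor_panel"))
  Fm <- panel$F
  Y <- panel$Y
  FtF <- crossprod(Fm)
  rc <- rcond(FtF)
  if (!is.finite(rc) || rc < rcond_tol) {
    stop("rank-deficient factors: F'F is singular or near-singular ",
         "(reciprocal condition number ", format(rc), ")")
  }
  n_time <- panel$n_time
  coef_kp <- solve(FtF, crossprod(Fm, Y))      # K x p
  B_hat <- t(coef_kp)                          # p x K
  U_hat <- Y - Fm %*% coef_kp
  Sigma_u_hat <- crossprod(U_hat) / n_time
  Omega_f_hat <- solve(FtF / n_time)
  Omega_f_hat <- (Omega_f_hat + t(Omega_f_hat)) / 2
  dimnames(B_hat) <- list(colnames(Y), colnames(Fm))
  structure(
    list(B_hat = B_hat, U_hat = U_hat, F = Fm,
         Sigma_u_hat = Sigma_u_hat, Omega_f_hat = Omega_f_hat,
         n_time = n_time, p = panel$p, K = panel$K,
         variables = colnames(Y), factors = colnames(Fm)),
    class = "loading_fit"
  )
}

#' @export
print.loading_fit <- function(x, ...) {
  cat("<loading_fit> OLS loadings:", x$p, "variables x", x$K,
      "factors, T =", x$n_time, "\n")
  invisible(x)
}

#' @describeIn fit_loadings One row per loading-matrix entry, with the
#'   estimate and its plug-in standard error `sqrt(omega_hat_ii / T)`.
#' @param x A `loading_fit`.
#' @param ... Unused.
#' @export
tidy.loading_fit <- function(x, ...) {
  omega_kk <- diag(x$Omega_f_hat)
  se <- sqrt(outer(diag(x$Sigma_u_hat), omega_kk) / x$n_time)
  tibble::tibble(
    variable = rep(x$variables, times = x$K),
    factor = rep(x$factors, each = x$p),
    estimate = as.vector(x$B_hat),
    std_error = as.vector(se)
  )
}

#' @describeIn fit_loadings One-row summary of the fit.
#' @export
glance.loading_fit <- function(x, ...) {
  tibble::tibble(
    n_time = x$n_time, p = x$p, K = x$K,
    mean_resid_var = mean(diag(x$Sigma_u_hat))
  )
}

# Per-variable plug-in variances omega_hat_ii = Omega_f_hat[k,k] * sigma_hat_ii
# for a single factor k.
omega_ii <- function(fit, k) {
  fit$Omega_f_hat[k, k] * diag(fit$Sigma_u_hat)
}
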
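#' Max-type deviation statistic for one factor's loadings
#'
#' For the simultaneous null `b_ik = b_null_i` over `i` in `G`, computes the
#' per-entry scaled deviations `sqrt(T) |b_hat_ik - b_null_i|` (divided by
#' `sqrt(omega_hat_ii)` with `omega_hat_ii = Omega_f_hat[k,k] sigma_hat_ii`
#' when studentized) and their maximum, the observed test statistic.
#'
#' @param fit A [loading_fit].
#' @param k Factor index (column of the loading matrix) being tested.
#' @param null Null values, either a scalar recycled over `G` or one value
#'   per tested entry. Default 0.
#' @param G Integer vector of variable indices under test; `NULL` means all
#'   `1..p`.
#' @param studentize Divide each deviation by its estimated standard
#'   deviation so the maximum is scale-free. Default `TRUE`.
#' @return A list with `per_entry` (named vector of scaled deviations),
#'   `statistic` (their maximum) and `which_max` (index in `G` attaining it;
#'   first index wins on ties).
#' @export
loading_statistic <- function(fit, k, null = 0, G = NULL, studentize = TRUE) {
  stopifnot(inherits(fit, "loading_fit"))
  G <- check_G(G, fit$p)
  k <- check_k(k, fit$K)
  null <- recycle_null(null, length(G))
  dev <- sqrt(fit$n_time) * abs(fit$B_hat[G, k] - null)
  if (studentize) {
    w <- omega_ii(fit, k)[G]
    if (any(w <= 0)) stop("degenerate variance: omega_hat_ii <= 0")
    dev <- dev / sqrt(w)
  }
  names(dev) <- fit$variables[G]
  list(per_entry = dev,
       statistic = max(dev),
       which_max = G[which.max(dev)])
}

#' Multiplier-bootstrap draws of the max statistic
#'
#' Draws `n_boot` replicates of the bootstrap statistic: per replicate, a
#' vector of i.i.d. standard-normal multipliers `e_1..e_T` (shared across
#' variables) perturbs the residual scores, giving
#' `max_i s_i T^{-1/2} |sum_t u_hat_it e_t|` with scale `s_i =
#' sqrt(Omega_f_hat[k,k])` (non-studentized) or `sigma_hat_ii^{-1/2}`
#' (studentized). Conditional on the data the pre-max scores have covariance
#' `Omega_f_hat[k,k] sigma_hat_ij`, the same covariance the estimation-error
#' expansion of the loadings has, which is what licenses the bootstrap
#' critical value.
#'
#' @inheritParams loading_statistic
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Optional integer seed for the multiplier stream; the ambient
#'   RNG state is restored afterwards.
#' @return Numeric vector of `n_boot` nonnegative draws.
#' @export
multiplier_draws <- function(fit, k, G = NULL, n_boot = 500,
                             studentize = TRUE, seed = NULL) {
  bank <- multiplier_score_bank(fit, k, G, n_boot, studentize, seed,
                                absolute = TRUE)
  col_max(bank)
}

# Raw signed bootstrap scores T^{-1/2} (U'[G,] E), one row per tested entry,
# one column per replicate.  All single-factor bootstrap quantities derive
# from this bank so the test, the step-down procedure and the simulation
# drivers share one code path.
raw_score_bank <- function(U_G, n_boot, seed = NULL) {
  n_time <- nrow(U_G)
  E <- with_seed_if(seed, matrix(rnorm(n_time * n_boot), n_time, n_boot))
  crossprod(U_G, E) / sqrt(n_time)
}

multiplier_score_bank <- function(fit, k, G = NULL, n_boot = 500,
                                  studentize = TRUE, seed = NULL,
                                  absolute = TRUE) {
  stopifnot(inherits(fit, "loading_fit"))
  G <- check_G(G, fit$p)
  k <- check_k(k, fit$K)
  if (n_boot < 1) stop("n_boot must be at least 1")
  raw <- raw_score_bank(fit$U_hat[, G, drop = FALSE], n_boot, seed)
  if (absolute) raw <- abs(raw)
  if (studentize) {
    s_ii <- diag(fit$Sigma_u_hat)[G]
    if (any(s_ii <= 0)) stop("degenerate variance: sigma_hat_ii <= 0")
    raw / sqrt(s_ii)
  } else {
    raw * sqrt(fit$Omega_f_hat[k, k])
  }
}

#' Bootstrap critical value
#'
#' Empirical conditional `(1-alpha)`-quantile of the bootstrap draws under
#' the inf convention: the `ceiling((1-alpha) * B)`-th smallest of `B`
#' draws. With all draws equal, any level returns that common value; as
#' `alpha` approaches 1 the minimum draw is returned.
#'
#' @param draws Numeric vector of bootstrap statistics.
#' @param alpha Significance level in (0, 1).
#' @return The critical value.
#' @export
bootstrap_critical_value <- function(draws, alpha) {
  if (length(draws) == 0) stop("empty bootstrap draw vector")
  check_alpha(alpha)
  idx <- min(max(ceiling((1 - alpha) * length(draws)), 1L), length(draws))
  sort(draws)[idx]
}

#' Simultaneous bootstrap test for one factor's loadings
#'
#' Tests `H0: b_ik = b_null_i for all i in G` against the two-sided
#' alternative with the max-type statistic and a multiplier-bootstrap
#' critical value. Rejects when the observed maximum exceeds the
#' conditional `(1-alpha)`-quantile of the bootstrap maxima. No sparsity is
#' assumed on either the loadings or the error covariance, and `|G|` may be
#' of the same order as `p`.
#'
#' @param panel A [factor_panel] (or a pre-computed [loading_fit] via
#'   `fit`).
#' @inheritParams loading_statistic
#' @inheritParams multiplier_draws
#' @param alpha Significance level (default 0.05).
#' @param fit Optionally a [loading_fit] to reuse; otherwise the panel is
#'   fitted internally.
#' @return A `loading_test` object; see [tidy.loading_test()] and
#'   [glance.loading_test()].
#' @examples
#' sim <- simulate_panel(n_time = 200, p = 20, model = 1, seed = 3)
#' tst <- test_loadings(sim$panel, k = 1, null = sim$B[, 1],
#'                      n_boot = 200, seed = 11)
#' glance(tst)
#' @export
test_loadings <- function(panel, k, null = 0, G = NULL, alpha = 0.05,
                          studentize = TRUE, n_boot = 500, seed = NULL,
                          fit = NULL) {
  if (is.null(fit)) fit <- fit_loadings(panel)
  check_alpha(alpha)
  obs <- loading_statistic(fit, k, null, G, studentize)
  draws <- multiplier_draws(fit, k, G, n_boot, studentize, seed)
  cv <- bootstrap_critical_value(draws, alpha)
  G <- check_G(G, fit$p)
  new_loading_test(
    mode = "single_factor",
    statistic = obs$statistic, critical_value = cv,
    reject = obs$statistic > cv,
    draws = draws, alpha = alpha, studentize = studentize,
    per_entry = tibble::tibble(
      variable = fit$variables[G],
      factor = fit$factors[k],
      deviation = unname(obs$per_entry)
    ),
    which_max = obs$which_max, n_time = fit$n_time
  )
}

new_loading_test <- function(...) {
  structure(list(...), class = "loading_test")
}

#' @export
print.loading_test <- function(x, ...) {
  cat("<loading_test> ", x$mode,
      if (isTRUE(x$studentize)) " (studentized)" else " (non-studentized)",
      "\n  statistic = ", format(x$statistic, digits = 4),
      ", bootstrap critical value (alpha = ", x$alpha, ") = ",
      format(x$critical_value, digits = 4),
      "\n  decision: ", if (x$reject) "REJECT" else "do not reject",
      " the simultaneous null\n", sep = "")
  invisible(x)
}

#' Tidiers for loading tests
#'
#' `tidy()` returns one row per tested entry with its scaled (and possibly
#' studentized) absolute deviation; `glance()` returns the one-row decision
#' summary.
#'
#' @param x A `loading_test`.
#' @param ... Unused.
#' @export
tidy.loading_test <- function(x, ...) {
  x$per_entry
}

#' @rdname tidy.loading_test
#' @export
glance.loading_test <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    statistic = x$statistic,
    critical_value = x$critical_value,
    alpha = x$alpha,
    studentized = isTRUE(x$studentize),
    n_boot = length(x$draws),
    reject = x$reject
  )
}

#' Long-run covariance entry for a pair of loading coordinates
#'
#' The plug-in asymptotic covariance between the estimation errors of
#' `b_hat[i, k]` and `b_hat[j, l]`:
#' `(Omega_f_hat v_k)' (T^{-1} sum_t u_hat_it u_hat_jt f_t f_t') (Omega_f_hat v_l)`.
#' Used to studentize the multi-factor test.
#'
#' @param fit A [loading_fit].
#' @param i,j Variable indices.
#' @param k,l Factor indices.
#' @return A scalar; symmetric under swapping `(i,k)` and `(j,l)`.
#' @export
omega_star <- function(fit, i, k, j = i, l = k) {
  stopifnot(inherits(fit, "loading_fit"))
  g <- fit$F %*% fit$Omega_f_hat
  mean(fit$U_hat[, i] * fit$U_hat[, j] * g[, k] * g[, l])
}

#' Simultaneous bootstrap test across several factors
#'
#' Tests `H0: b_ik = b_null_(i,k) for all (i,k) in G*`, where `G*` is a set
#' of (variable, factor) pairs, with the studentized max statistic
#' `max sqrt(T) |b_hat_ik - b_null| / sqrt(omega_star_(i,k),(i,k))` and a
#' multiplier bootstrap on the per-pair influence scores
#' `u_hat_it f_t' Omega_f_hat v_k` with multipliers shared across pairs
#' within a replicate.
#'
#' @inheritParams test_loadings
#' @param pairs Two-column matrix or data frame of (variable index, factor
#'   index) pairs; columns named `i`/`k` or positional.
#' @param null Null values, scalar or one per pair (in the row order of
#'   `pairs`).
#' @export
test_loadings_multi <- function(panel, pairs, null = 0, alpha = 0.05,
                                n_boot = 500, seed = NULL, fit = NULL) {
  if (is.null(fit)) fit <- fit_loadings(panel)
  check_alpha(alpha)
  pairs <- check_pairs(pairs, fit$p, fit$K)
  null <- recycle_null(null, nrow(pairs))
  if (n_boot < 1) stop("n_boot must be at least 1")
  g <- fit$F %*% fit$Omega_f_hat
  # per-pair influence scores xi_t = u_hat_it * g_tk, one column per pair
  Xi <- fit$U_hat[, pairs$i, drop = FALSE] * g[, pairs$k, drop = FALSE]
  w_star <- colMeans(Xi^2)
  if (any(w_star <= 0)) stop("degenerate variance: omega_star <= 0")
  dev <- sqrt(fit$n_time) *
    abs(fit$B_hat[cbind(pairs$i, pairs$k)] - null) / sqrt(w_star)
  bank <- abs(raw_score_bank(Xi, n_boot, seed)) / sqrt(w_star)
  draws <- col_max(bank)
  cv <- bootstrap_critical_value(draws, alpha)
  stat <- max(dev)
  new_loading_test(
    mode = "multi_factor",
    statistic = stat, critical_value = cv, reject = stat > cv,
    draws = draws, alpha = alpha, studentize = TRUE,
    per_entry = tibble::tibble(
      variable = fit$variables[pairs$i],
      factor = fit$factors[pairs$k],
      deviation = unname(dev),
      omega_star = unname(w_star)
    ),
    which_max = which.max(dev), n_time = fit$n_time
  )
}

#' Extreme-value benchmark test
#'
#' The studentized squared maximum, centered by `2 log m - log log m` with
#' `m = |G|`, converges (as `m` grows) to the Gumbel-type law for maxima of
#' squared standard normals, `exp(-pi^{-1/2} exp(-x/2))`; the test rejects
#' when the centered statistic exceeds the analytic quantile
#' `q_alpha = -2 log(-sqrt(pi) log(1 - alpha))` (about 4.7957 at
#' `alpha = 0.05`).
#' It needs no resampling but relies on a diverging number of tested
#' entries and weak cross-sectional dependence, so it can be badly
#' calibrated at small `m` or under strong equicorrelation.
#'
#' @inheritParams loading_statistic
#' @param alpha Significance level.
#' @return A list with `statistic`, `critical_value` and `reject`.
#' @export
extreme_value_test <- function(fit, k, null = 0, alpha = 0.05, G = NULL) {
  stopifnot(inherits(fit, "loading_fit"))
  check_alpha(alpha)
  G <- check_G(G, fit$p)
  m <- length(G)
  if (m < 3) stop("extreme-value test needs at least 3 tested entries")
  dev <- loading_statistic(fit, k, null, G, studentize = TRUE)$per_entry
  stat <- max(dev^2) - 2 * log(m) + log(log(m))
  cv <- extreme_value_quantile(alpha)
  list(statistic = stat, critical_value = cv, reject = stat > cv)
}

#' @rdname extreme_value_test
#' @export
extreme_value_quantile <- function(alpha) {
  check_alpha(alpha)
  -2 * log(-sqrt(pi) * log(1 - alpha))
}

#' Marginal two-sided p-values from the studentized statistics
#'
#' `p_i = 2 (1 - Phi(t_i))` with `t_i` the studentized absolute deviation
#' for entry `i`; the inputs to the Holm and Benjamini-Hochberg
#' comparators.
#'
#' @inheritParams loading_statistic
#' @return Numeric vector of p-values in `[0, 1]`, named by variable.
#' @export
marginal_p_values <- function(fit, k, null = 0, G = NULL) {
  t_i <- loading_statistic(fit, k, null, G, studentize = TRUE)$per_entry
  2 * pnorm(-abs(t_i))
}

# ---- argument checks ----

check_G <- function(G, p) {
  if (is.null(G)) return(seq_len(p))
  G <- as.integer(G)
  if (length(G) == 0) stop("index set G must be nonempty")
  if (anyNA(G) || any(G < 1L) || any(G > p)) {
    stop("index set G out of range 1..", p)
  }
  G
}

check_k <- function(k, K) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1L || k > K) {
    stop("factor index k must be a single integer in 1..", K)
  }
  k
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 ||
      !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1")
  }
  invisible(alpha)
}

recycle_null <- function(null, n) {
  if (length(null) == 1) rep(as.numeric(null), n)
  else if (length(null) == n) as.numeric(null)
  else stop("null values must be a scalar or have one value per tested entry")
}

check_pairs <- function(pairs, p, K) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2 || nrow(pairs) == 0) {
    stop("pairs must be a nonempty two-column (variable, factor) table")
  }
  names(pairs)[1:2] <- c("i", "k")
  pairs$i <- as.integer(pairs$i)
  pairs$k <- as.integer(pairs$k)
  if (anyNA(pairs$i) || anyNA(pairs$k) ||
      any(pairs$i < 1L | pairs$i > p) || any(pairs$k < 1L | pairs$k > K)) {
    stop("pair indices out of range: variables 1..", p, ", factors 1..", K)
  }
  pairs[, c("i", "k")]
}
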
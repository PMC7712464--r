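#' Monte-Carlo experiment drivers
#'
#' `run_size_experiment()` estimates empirical rejection rates of the
#' simultaneous tests under the null (true null values, `G = 1..p`);
#' `run_power_curve()` traces rejection rates along alternatives in which
#' every null is offset by `c/40` from the truth; and
#' `run_multiple_testing_experiment()` evaluates FWER/FDR and average power
#' of the step-down and p-value-based procedures under sparse violations.
#' All three return one tidy long-format tibble with columns
#' `(experiment, model, method, n_time, p, s0, c, metric, value, mc_se,
#' reps)`; unused design columns are `NA`.
#'
#' Replication `r` of a cell `(model, n_time, p)` always derives its
#' sub-seed from `(seed, model, n_time, p, r)` alone — not from the
#' experiment type or the method — so the power curve at `c = 0`
#' reproduces the size cell bit for bit, and all methods within a
#' replication share one simulated panel and one bank of bootstrap
#' multipliers.
#'
#' @param models Error designs to run (subset of `c(1, 2)`).
#' @param n_time Sample size `T`.
#' @param p_values Panel dimensions to run.
#' @param methods For size/power: subset of `c("NST", "ST", "EX")`
#'   (non-studentized / studentized bootstrap max test, extreme-value
#'   benchmark). For multiple testing: subset of `c("NST-FWER", "ST-FWER",
#'   "BH-FWER", "BH-FDR")` (step-down with non-studentized / studentized
#'   bootstrap critical values, Bonferroni-Holm, Benjamini-Hochberg).
#' @param reps Monte-Carlo replications per cell (default 500).
#' @param n_boot Bootstrap draws per replication (default 500).
#' @param alpha Nominal level (default 0.05).
#' @param K,k Number of factors and tested factor column.
#' @param rho_f Factor AR parameter.
#' @param seed Master seed; every random stream in the experiment derives
#'   from it deterministically.
#' @return A tidy tibble, one row per (cell, method, metric).
#' @examples
#' run_size_experiment(models = 1, p_values = 10, n_time = 100,
#'                     reps = 5, n_boot = 50, seed = 1)
#' @export
run_size_experiment <- function(models = c(1, 2), n_time = 400,
                                p_values = c(50, 100, 200, 400, 600),
                                methods = c("NST", "ST", "EX"),
                                reps = 500, n_boot = 500, alpha = 0.05,
                                K = 3, k = 1, rho_f = 0.6, seed = 1) {
  run_power_curve(models = models, n_time = n_time, p_values = p_values,
                  c_values = 0, methods = methods, reps = reps,
                  n_boot = n_boot, alpha = alpha, K = K, k = k,
                  rho_f = rho_f, seed = seed, .experiment = "size",
                  .metric = "size")
}

#' @rdname run_size_experiment
#' @param c_values Power-curve offsets `c` (per-entry shift `c/40`);
#'   the canonical grid is `0.8 * ell` for `ell = 0..10`, optionally with
#'   negative mirror values.
#' @export
run_power_curve <- function(models = 1, n_time = 400,
                            p_values = c(10, 200, 600),
                            c_values = 0.8 * (0:10),
                            methods = c("NST", "ST", "EX"),
                            reps = 500, n_boot = 500, alpha = 0.05,
                            K = 3, k = 1, rho_f = 0.6, seed = 1,
                            .experiment = "power_curve",
                            .metric = "power") {
  stopifnot(reps >= 1, all(methods %in% c("NST", "ST", "EX")))
  factor_chol <- chol(factor_covariance(K, rho_f))
  out <- list()
  for (model in models) {
    for (p in p_values) {
      error_chol <- chol(switch(as.character(model),
                                "1" = model1_error_covariance(p),
                                "2" = model2_error_covariance(p)))
      cell_seed <- derive_seed(seed, model, n_time, p)
      # reject[(method, c), rep]
      rej <- array(0, dim = c(length(methods), length(c_values), reps))
      for (r in seq_len(reps)) {
        rej[, , r] <- single_factor_rep(
          model, n_time, p, K, k, derive_seed(cell_seed, r),
          n_boot, alpha, c_values, methods, error_chol, factor_chol)
      }
      rate <- apply(rej, c(1, 2), mean)
      out[[length(out) + 1L]] <- tibble::tibble(
        experiment = .experiment,
        model = model,
        method = rep(methods, times = length(c_values)),
        n_time = n_time, p = p, s0 = NA_real_,
        c = rep(c_values, each = length(methods)),
        metric = .metric,
        value = as.vector(rate),
        mc_se = sqrt(as.vector(rate) * (1 - as.vector(rate)) / reps),
        reps = reps
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (identical(.experiment, "size")) res$c <- NULL
  res
}

# One replication of the single-factor size/power design: simulate, fit,
# draw one multiplier bank, and evaluate every requested method at every
# offset c. Returns a (method x c) 0/1 rejection matrix.
single_factor_rep <- function(model, n_time, p, K, k, rep_seed, n_boot,
                              alpha, c_values, methods, error_chol,
                              factor_chol) {
  sim <- simulate_panel(n_time, p, K = K, model = model, seed = rep_seed,
                        error_chol = error_chol, factor_chol = factor_chol)
  fit <- fit_loadings(sim$panel)
  delta <- fit$B_hat[, k] - sim$B[, k]
  w <- omega_ii(fit, k)
  need_boot <- any(methods %in% c("NST", "ST"))
  if (need_boot) {
    absraw <- abs(raw_score_bank(fit$U_hat, n_boot,
                                 derive_seed(rep_seed, 97)))
    cv_nst <- if ("NST" %in% methods)
      bootstrap_critical_value(
        col_max(absraw) * sqrt(fit$Omega_f_hat[k, k]), alpha)
    cv_st <- if ("ST" %in% methods)
      bootstrap_critical_value(
        col_max(absraw / sqrt(diag(fit$Sigma_u_hat))), alpha)
  }
  q_ex <- extreme_value_quantile(alpha)
  rej <- matrix(0, length(methods), length(c_values))
  for (j in seq_along(c_values)) {
    # null = truth - c/40, so b_hat - null = delta + c/40
    dev <- delta + c_values[j] / 40
    for (m in seq_along(methods)) {
      rej[m, j] <- switch(
        methods[m],
        NST = as.numeric(sqrt(n_time) * max(abs(dev)) > cv_nst),
        ST = as.numeric(sqrt(n_time) * max(abs(dev) / sqrt(w)) > cv_st),
        EX = as.numeric(
          max(n_time * dev^2 / w) - 2 * log(p) + log(log(p)) > q_ex)
      )
    }
  }
  rej
}

#' @rdname run_size_experiment
#' @param s0_values Numbers of truly violated nulls to run.
#' @param shift Offset of the violated nulls from the truth; `NULL` uses
#'   the design defaults (0.5 under model 1, 0.35 under model 2).
#' @export
run_multiple_testing_experiment <- function(
    models = c(1, 2), n_time = 400, p_values = c(50, 200, 500, 600),
    s0_values = c(3, 15),
    methods = c("NST-FWER", "ST-FWER", "BH-FWER", "BH-FDR"),
    shift = NULL, reps = 500, n_boot = 500, alpha = 0.05,
    K = 3, k = 1, rho_f = 0.6, seed = 1) {
  all_methods <- c("NST-FWER", "ST-FWER", "BH-FWER", "BH-FDR")
  stopifnot(reps >= 1, all(methods %in% all_methods))
  factor_chol <- chol(factor_covariance(K, rho_f))
  out <- list()
  for (model in models) {
    model_shift <- if (is.null(shift)) c(0.5, 0.35)[model] else shift
    for (p in p_values) {
      error_chol <- chol(switch(as.character(model),
                                "1" = model1_error_covariance(p),
                                "2" = model2_error_covariance(p)))
      cell_seed <- derive_seed(seed, model, n_time, p)
      for (s0 in s0_values) {
        if (s0 > p) stop("s0 exceeds p")
        acc <- vector("list", reps)
        for (r in seq_len(reps)) {
          acc[[r]] <- multiple_testing_rep(
            model, n_time, p, K, k, derive_seed(cell_seed, r),
            n_boot, alpha, s0, model_shift, methods,
            error_chol, factor_chol)
        }
        percell <- dplyr::bind_rows(acc)
        summ <- dplyr::summarise(
          dplyr::group_by(percell, .data$method, .data$metric),
          mc_se = stats::sd(.data$value) / sqrt(sum(!is.na(.data$value))),
          value = mean(.data$value),
          .groups = "drop")
        out[[length(out) + 1L]] <- tibble::tibble(
          experiment = "multiple_testing",
          model = model, method = summ$method,
          n_time = n_time, p = p, s0 = s0, c = NA_real_,
          metric = summ$metric, value = summ$value, mc_se = summ$mc_se,
          reps = reps
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# One replication of the sparse-violation multiple-testing design: all four
# procedures run on the same panel, bootstrap bank and studentized
# p-values. FWER-controlling methods report the FWER indicator and power;
# BH-FDR reports the false-discovery proportion and power.
multiple_testing_rep <- function(model, n_time, p, K, k, rep_seed, n_boot,
                                 alpha, s0, shift, methods,
                                 error_chol, factor_chol) {
  sim <- simulate_panel(n_time, p, K = K, model = model, seed = rep_seed,
                        error_chol = error_chol, factor_chol = factor_chol)
  fit <- fit_loadings(sim$panel)
  null <- shifted_nulls(sim$B, k, s0, shift)
  nonnull <- seq_len(s0)
  w <- omega_ii(fit, k)
  t_raw <- sqrt(n_time) * abs(fit$B_hat[, k] - null)
  t_st <- t_raw / sqrt(w)
  boot_seed <- derive_seed(rep_seed, 97)
  absraw <- if (any(methods %in% c("NST-FWER", "ST-FWER")))
    abs(raw_score_bank(fit$U_hat, n_boot, boot_seed))
  pvals <- 2 * pnorm(-t_st)
  rows <- list()
  for (m in methods) {
    rejected <- switch(
      m,
      "NST-FWER" = stepdown_from_bank(
        t_raw, absraw * sqrt(fit$Omega_f_hat[k, k]), alpha)$rejected,
      "ST-FWER" = stepdown_from_bank(
        t_st, absraw / sqrt(diag(fit$Sigma_u_hat)), alpha)$rejected,
      "BH-FWER" = holm_rejected(pvals, alpha),
      "BH-FDR" = bh_rejected(pvals, alpha)
    )
    met <- fwer_fdr_metrics(rejected, nonnull, p)
    rows[[m]] <- tibble::tibble(
      method = m,
      metric = c(if (identical(m, "BH-FDR")) "fdr" else "fwer", "power"),
      value = c(if (identical(m, "BH-FDR")) met$fdp else met$fwer,
                met$power)
    )
  }
  dplyr::bind_rows(rows)
}

#' Sparsity screen for the smallest estimated loadings
#'
#' Standardizes the panel (factors to mean 0 / unit sd, responses
#' centered), fits the loadings, selects per requested factor the
#' `floor(beta_percent% * p)` entries with the smallest `|b_hat_ik|`, and
#' runs the simultaneous multi-factor bootstrap test of `b_ik = 0` on the
#' selected pairs. Accepting supports treating those loadings as sparse.
#'
#' @param panel A [factor_panel].
#' @param factors Integer vector of factor columns to screen.
#' @param beta_percent Percentage (0, 100] of smallest loadings per factor.
#' @param alpha Level of the simultaneous test.
#' @param n_boot Bootstrap draws.
#' @param seed Optional seed for the multiplier stream.
#' @param standardize Apply [standardize_panel()] first (default `TRUE`).
#' @return A list with the selected `pairs` (tibble), the `loading_test`
#'   object, and the `reject` decision.
#' @export
sparsity_screen <- function(panel, factors, beta_percent, alpha = 0.05,
                            n_boot = 500, seed = NULL, standardize = TRUE) {
  stopifnot(inherits(panel, "factor_panel"))
  if (beta_percent <= 0 || beta_percent > 100) {
    stop("beta_percent must be in (0, 100]")
  }
  if (standardize) panel <- standardize_panel(panel)
  fit <- fit_loadings(panel)
  n_sel <- floor(beta_percent / 100 * fit$p)
  if (n_sel < 1) stop("empty selection: beta_percent too small for p = ",
                      fit$p)
  pairs <- purrr::map_dfr(factors, function(kk) {
    kk <- check_k(kk, fit$K)
    tibble::tibble(i = order(abs(fit$B_hat[, kk]))[seq_len(n_sel)], k = kk)
  })
  tst <- test_loadings_multi(panel, pairs, null = 0, alpha = alpha,
                             n_boot = n_boot, seed = seed, fit = fit)
  list(pairs = pairs, test = tst, reject = tst$reject,
       beta_percent = beta_percent, factors = factors)
}
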
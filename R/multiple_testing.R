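#' Step-down multiple testing with bootstrap critical values
#'
#' Tests the `p` marginal hypotheses on one loading column (`H0,i: b_ik =
#' b_null_i` two-sided, or `H0,i: b_ik <= b_null_i` one-sided) with strong
#' family-wise error rate control. At each step the critical value is the
#' bootstrap `(1-alpha)`-quantile of the maximum score over the hypotheses
#' still in play; every hypothesis whose statistic exceeds it is rejected,
#' and the procedure repeats on the survivors until a step rejects nothing.
#' Because the max over a subset never exceeds the max over a superset, the
#' critical value can only shrink as hypotheses are removed, which is what
#' buys power over a single-step max test. One bank of `n_boot` multiplier
#' vectors is drawn up front and reused at every step, so that monotonicity
#' holds exactly on the realized draws, not just in expectation.
#'
#' @inheritParams test_loadings
#' @param sided `"two"` (default) tests equalities with absolute statistics
#'   and max-absolute bootstrap quantiles; `"one"` tests `<=` with signed
#'   statistics and signed score maxima.
#' @return A `stepdown_test` object: use [tidy.stepdown_test()] for the
#'   per-hypothesis table and [glance.stepdown_test()] for the summary.
#' @examples
#' sim <- simulate_panel(n_time = 200, p = 20, model = 1, seed = 5)
#' nulls <- shifted_nulls(sim$B, k = 1, s0 = 3, shift = 0.5)
#' sd_res <- stepdown_test(sim$panel, k = 1, null = nulls,
#'                         n_boot = 200, seed = 9)
#' glance(sd_res)
#' @export
stepdown_test <- function(panel, k, null = 0, alpha = 0.05,
                          sided = c("two", "one"), studentize = TRUE,
                          n_boot = 500, seed = NULL, fit = NULL) {
  sided <- match.arg(sided)
  if (is.null(fit)) fit <- fit_loadings(panel)
  check_alpha(alpha)
  k <- check_k(k, fit$K)
  null <- recycle_null(null, fit$p)
  tstat <- stepdown_statistics(fit, k, null, sided, studentize)
  bank <- multiplier_score_bank(fit, k, G = NULL, n_boot = n_boot,
                                studentize = studentize, seed = seed,
                                absolute = identical(sided, "two"))
  res <- stepdown_from_bank(tstat, bank, alpha)
  structure(
    c(res,
      list(alpha = alpha, sided = sided, studentize = studentize,
           variables = fit$variables, factor = fit$factors[k],
           statistic = tstat, n_boot = n_boot)),
    class = "stepdown_test"
  )
}

# Observed per-hypothesis statistics sqrt(T)(b_hat - b_null), studentized
# and/or folded by |.| according to the test's sidedness.
stepdown_statistics <- function(fit, k, null, sided, studentize) {
  t_i <- sqrt(fit$n_time) * (fit$B_hat[, k] - null)
  if (identical(sided, "two")) t_i <- abs(t_i)
  if (studentize) {
    w <- omega_ii(fit, k)
    if (any(w <= 0)) stop("degenerate variance: omega_hat_ii <= 0")
    t_i <- t_i / sqrt(w)
  }
  unname(t_i)
}

# Core step-down iteration on a fixed bank of per-hypothesis bootstrap
# scores (p x n_boot). Shared draws guarantee c_eta <= c_eta' for nested
# active sets.
stepdown_from_bank <- function(tstat, bank, alpha) {
  p <- length(tstat)
  stopifnot(nrow(bank) == p)
  active <- seq_len(p)
  rejected <- integer(0)
  rejected_step <- integer(0)
  crit_path <- numeric(0)
  step <- 0L
  repeat {
    step <- step + 1L
    cv <- bootstrap_critical_value(
      col_max(bank[active, , drop = FALSE]), alpha)
    crit_path[step] <- cv
    new_rej <- active[tstat[active] > cv]
    if (length(new_rej) == 0) break
    rejected <- c(rejected, new_rej)
    rejected_step <- c(rejected_step, rep(step, length(new_rej)))
    active <- setdiff(active, new_rej)
    if (length(active) == 0) break
  }
  list(rejected = rejected, rejected_step = rejected_step,
       n_steps = step, critical_values = crit_path,
       active_final = active)
}

#' @export
print.stepdown_test <- function(x, ...) {
  cat("<stepdown_test> ", length(x$statistic), " hypotheses on factor ",
      x$factor, " (", x$sided, "-sided, ",
      if (x$studentize) "studentized" else "non-studentized", ")\n",
      "  rejected ", length(x$rejected), " in ", x$n_steps,
      " step(s); final critical value ",
      format(x$critical_values[x$n_steps], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidiers for step-down results
#'
#' `tidy()` gives one row per hypothesis with its statistic, whether it was
#' rejected and at which step; `glance()` summarizes the run.
#'
#' @param x A `stepdown_test`.
#' @param ... Unused.
#' @export
tidy.stepdown_test <- function(x, ...) {
  p <- length(x$statistic)
  step_of <- rep(NA_integer_, p)
  step_of[x$rejected] <- x$rejected_step
  tibble::tibble(
    variable = x$variables,
    statistic = x$statistic,
    rejected = seq_len(p) %in% x$rejected,
    step = step_of
  )
}

#' @rdname tidy.stepdown_test
#' @export
glance.stepdown_test <- function(x, ...) {
  tibble::tibble(
    n_hypotheses = length(x$statistic),
    n_rejected = length(x$rejected),
    n_steps = x$n_steps,
    final_critical_value = x$critical_values[x$n_steps],
    alpha = x$alpha, sided = x$sided, studentized = x$studentize
  )
}

#' Holm and Benjamini-Hochberg comparators
#'
#' Classical step-down (Holm, FWER) and step-up (Benjamini-Hochberg, FDR)
#' procedures on marginal p-values, as used to benchmark the bootstrap
#' step-down method. Both delegate to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target level.
#' @return Integer vector of rejected indices (positions in `p_values`).
#' @export
holm_rejected <- function(p_values, alpha) {
  check_p_values(p_values)
  check_alpha(alpha)
  which(p.adjust(p_values, method = "holm") <= alpha)
}

#' @rdname holm_rejected
#' @export
bh_rejected <- function(p_values, alpha) {
  check_p_values(p_values)
  check_alpha(alpha)
  which(p.adjust(p_values, method = "BH") <= alpha)
}

check_p_values <- function(p_values) {
  if (length(p_values) == 0 || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be a nonempty vector in [0, 1]")
  }
  invisible(p_values)
}

#' Error and power metrics for a multiple-testing outcome
#'
#' Given the rejected indices and the set of true non-nulls `S0`, returns
#' the family-wise error indicator (any rejection outside `S0`), the false
#' discovery proportion (false rejections over total rejections, 0 when
#' nothing is rejected), and average power (fraction of `S0` rejected,
#' `NA` when `S0` is empty).
#'
#' @param rejected Integer vector of rejected hypothesis indices.
#' @param nonnull Integer vector `S0` of truly non-null indices.
#' @param n_hyp Total number of hypotheses `|G|`.
#' @return A one-row tibble with columns `fwer`, `fdp`, `power`.
#' @export
fwer_fdr_metrics <- function(rejected, nonnull, n_hyp) {
  rejected <- as.integer(rejected)
  nonnull <- as.integer(nonnull)
  if (any(rejected < 1L | rejected > n_hyp)) stop("rejected index out of range")
  if (any(nonnull < 1L | nonnull > n_hyp)) stop("nonnull index out of range")
  false_rej <- setdiff(rejected, nonnull)
  tibble::tibble(
    fwer = as.numeric(length(false_rej) > 0),
    fdp = if (length(rejected) == 0) 0 else
      length(false_rej) / length(rejected),
    power = if (length(nonnull) == 0) NA_real_ else
      length(intersect(rejected, nonnull)) / length(nonnull)
  )
}
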
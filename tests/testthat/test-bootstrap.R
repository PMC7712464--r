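test_that("max deviation statistic matches hand-computed values", {
  pn <- make_panel()
  fit <- fit_loadings(pn$panel)

  # null equal to the estimate gives a zero statistic
  st <- loading_statistic(fit, k = 1, null = fit$B_hat[, 1],
                          studentize = FALSE)
  expect_equal(st$statistic, 0)

  # singleton G, T = 4, deviation 0.5 -> sqrt(4) * 0.5 = 1
  fit4 <- fit_loadings(make_panel(n_time = 4, p = 2, K = 1)$panel)
  null <- fit4$B_hat[, 1]
  null[1] <- null[1] - 0.5
  st4 <- loading_statistic(fit4, k = 1, null = null[1], G = 1,
                           studentize = FALSE)
  expect_equal(st4$statistic, 1, tolerance = 1e-12)

  # deviations (0.1, -0.3, 0.2) at T = 100 -> 10 * 0.3 = 3
  fit100 <- fit_loadings(make_panel(n_time = 100, p = 3, K = 1)$panel)
  null <- fit100$B_hat[, 1] - c(0.1, -0.3, 0.2)
  st100 <- loading_statistic(fit100, k = 1, null = null, studentize = FALSE)
  expect_equal(st100$statistic, 3, tolerance = 1e-10)
  expect_equal(st100$which_max, 2L)
})

test_that("zero residuals give identically zero bootstrap draws", {
  nl <- make_noiseless()
  fit <- fit_loadings(nl$panel)
  draws <- multiplier_draws(fit, k = 1, n_boot = 50, studentize = FALSE,
                            seed = 1)
  expect_equal(max(abs(draws)), 0, tolerance = 1e-9)
})

test_that("studentized singleton draws are half-normal (distributional oracle)", {
  pn <- make_panel(n_time = 50, p = 3, K = 1)
  fit <- fit_loadings(pn$panel)
  draws <- multiplier_draws(fit, k = 1, G = 2, n_boot = 50000,
                            studentize = TRUE, seed = 4)
  # conditional on the data these are exactly |N(0,1)| since
  # sigma_hat_ii = sum(u_hat^2)/T is the score scale itself
  ks <- suppressWarnings(
    stats::ks.test(draws, function(q) 2 * pnorm(q) - 1))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("bootstrap critical value implements the inf/order-statistic rule", {
  expect_equal(bootstrap_critical_value(rep(3.2, 17), 0.5), 3.2)
  expect_equal(bootstrap_critical_value(1:100, 0.05), 95)
  expect_equal(bootstrap_critical_value(1:100, 0.999), 1)
  expect_equal(bootstrap_critical_value(1:100, 0.001), 100)
  expect_error(bootstrap_critical_value(numeric(0), 0.05), "empty")
  expect_error(bootstrap_critical_value(1:10, 0), "alpha")
  expect_error(bootstrap_critical_value(1:10, 1), "alpha")
})

test_that("test decisions are monotone in alpha on a fixed seed", {
  sim <- simulate_panel(n_time = 200, p = 15, model = 1, seed = 5)
  null <- sim$B[, 1] + 0.1  # mild violation
  res <- lapply(c(0.01, 0.05, 0.10), function(a) {
    test_loadings(sim$panel, k = 1, null = null, alpha = a,
                  n_boot = 300, seed = 77)
  })
  cvs <- sapply(res, function(x) x$critical_value)
  expect_true(all(diff(cvs) <= 0))
  rej <- sapply(res, function(x) x$reject)
  # rejection at a smaller level implies rejection at a larger one
  expect_true(all(rej == cummax(rej)))
})

test_that("a gross violation is always rejected", {
  sim <- simulate_panel(n_time = 200, p = 10, model = 2, seed = 8)
  tst <- test_loadings(sim$panel, k = 1, null = sim$B[, 1] + 10,
                       n_boot = 200, seed = 3)
  expect_true(tst$reject)
  expect_false(
    test_loadings(sim$panel, k = 1, null = sim$B[, 1] +
                    (fit_loadings(sim$panel)$B_hat[, 1] - sim$B[, 1]),
                  n_boot = 200, seed = 3)$reject)
})

test_that("studentized results are scale equivariant", {
  pn <- make_panel(n_time = 50, p = 4, K = 2)
  scl <- c(7, 1, 1, 1)
  Y2 <- sweep(pn$panel$Y, 2, scl, `*`)
  fit1 <- fit_loadings(pn$panel)
  fit2 <- fit_loadings(factor_panel(Y2, pn$panel$F))
  s1 <- loading_statistic(fit1, 1, null = 0, studentize = TRUE)
  s2 <- loading_statistic(fit2, 1, null = 0, studentize = TRUE)
  expect_equal(s1$per_entry, s2$per_entry, tolerance = 1e-10)
  d1 <- multiplier_draws(fit1, 1, n_boot = 100, studentize = TRUE, seed = 6)
  d2 <- multiplier_draws(fit2, 1, n_boot = 100, studentize = TRUE, seed = 6)
  expect_equal(d1, d2, tolerance = 1e-10)
  # non-studentized deviation for the scaled variable scales by c
  n1 <- loading_statistic(fit1, 1, null = 0, studentize = FALSE)
  n2 <- loading_statistic(fit2, 1, null = 0, studentize = FALSE)
  expect_equal(unname(n2$per_entry[1]), unname(7 * n1$per_entry[1]),
               tolerance = 1e-10)
})

test_that("omega_star reduces correctly in the scalar and constant-factor cases", {
  # K = 1: omega_star = Omega_f^2 * mean(u^2 f^2)
  pn <- make_panel(n_time = 30, p = 3, K = 1)
  fit <- fit_loadings(pn$panel)
  of <- fit$Omega_f_hat[1, 1]
  expect_equal(omega_star(fit, 2, 1),
               of^2 * mean(fit$U_hat[, 2]^2 * pn$panel$F[, 1]^2),
               tolerance = 1e-12)

  # constant unit factor: Omega_f = 1 and omega_star = sigma_hat_ij
  Fm <- matrix(1, 25, 1)
  Y <- matrix(rnorm(50), 25, 2) + 0.3
  fitc <- fit_loadings(factor_panel(Y, Fm))
  expect_equal(fitc$Omega_f_hat[1, 1], 1, tolerance = 1e-12)
  expect_equal(omega_star(fitc, 1, 1, 2, 1), fitc$Sigma_u_hat[1, 2],
               tolerance = 1e-12)

  # symmetry in swapping the pairs
  pn2 <- make_panel(n_time = 40, p = 4, K = 3)
  fit2 <- fit_loadings(pn2$panel)
  expect_equal(omega_star(fit2, 1, 2, 3, 1), omega_star(fit2, 3, 1, 1, 2),
               tolerance = 1e-12)
})

test_that("multi-factor test agrees with the studentized single-factor test
           when the factors have identity second moment", {
  sim <- simulate_panel(n_time = 2000, p = 10, K = 3, model = 1, seed = 31)
  # orthonormalize so F'F/T is exactly the identity
  Fo <- sim$panel$F %*% solve(chol(crossprod(sim$panel$F) / 2000))
  panel <- factor_panel(sim$panel$Y, Fo)
  fit <- fit_loadings(panel)
  null <- fit$B_hat[, 2] - seq(-0.2, 0.25, length.out = 10)
  single <- loading_statistic(fit, k = 2, null = null, studentize = TRUE)
  multi <- test_loadings_multi(panel, cbind(1:10, 2), null = null,
                               n_boot = 2, seed = 1, fit = fit)
  # the studentizers differ by a finite-sample factor that vanishes with T
  expect_equal(multi$statistic, single$statistic, tolerance = 0.05)
  expect_equal(multi$per_entry$deviation, unname(single$per_entry),
               tolerance = 0.1)
})

test_that("multi-factor test with null at the estimate never rejects", {
  sim <- simulate_panel(n_time = 100, p = 6, K = 3, model = 2, seed = 13)
  fit <- fit_loadings(sim$panel)
  pairs <- expand.grid(i = 1:6, k = 1:3)
  tst <- test_loadings_multi(sim$panel, pairs,
                             null = fit$B_hat[cbind(pairs$i, pairs$k)],
                             n_boot = 100, seed = 2, fit = fit)
  expect_equal(tst$statistic, 0, tolerance = 1e-10)
  expect_false(tst$reject)
})

test_that("multi-factor test holds its size over all (i,k) pairs", {
  # desk-scale size check of the simultaneous multi-factor test
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_panel(n_time = 400, p = 50, K = 3, model = 1,
                          seed = 5000 + r)
    pairs <- expand.grid(i = 1:50, k = 1:3)
    null <- sim$B[cbind(pairs$i, pairs$k)]
    tst <- test_loadings_multi(sim$panel, pairs, null = null,
                               n_boot = 500, seed = 6000 + r)
    rej[r] <- tst$reject
  }
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("extreme-value test matches its analytic quantile and decision rule", {
  pn <- make_panel(n_time = 80, p = 10, K = 2)
  fit <- fit_loadings(pn$panel)
  ex <- extreme_value_test(fit, k = 1, null = fit$B_hat[, 1], alpha = 0.05)
  # null at the estimate: centered statistic is far below the quantile
  expect_false(ex$reject)
  expect_equal(ex$critical_value, extreme_value_quantile(0.05))
  expect_error(extreme_value_test(fit, 1, G = 1:2), "at least 3")
})

test_that("marginal p-values follow the two-sided normal tail", {
  pn <- make_panel(n_time = 60, p = 5, K = 2)
  fit <- fit_loadings(pn$panel)
  # null at the estimate -> t = 0 -> p = 1
  pv <- marginal_p_values(fit, 1, null = fit$B_hat[, 1])
  expect_equal(unname(pv), rep(1, 5))
  # t = 1.959964 -> p ~ 0.05
  w <- factorinfer:::omega_ii(fit, 1)
  null <- fit$B_hat[, 1] - 1.959964 * sqrt(w) / sqrt(fit$n_time)
  pv2 <- marginal_p_values(fit, 1, null = null)
  expect_equal(unname(pv2), rep(0.05, 5), tolerance = 1e-5)
  # monotone decreasing in the statistic
  t_i <- loading_statistic(fit, 1, null = 0)$per_entry
  pv3 <- marginal_p_values(fit, 1, null = 0)
  expect_equal(order(t_i), order(-pv3))
})

test_that("a single entry past the separation boundary is detected", {
  # shift one entry by 3 sqrt(log|G|/T) sqrt(omega_ii): power above 0.9
  reps <- 100
  n_time <- 400
  G <- 1:200
  omega11 <- solve(factor_covariance(3, 0.6))[1, 1]  # sigma_ii = 1, model 2
  shift <- 3 * sqrt(log(length(G)) / n_time) * sqrt(omega11)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_panel(n_time, p = 200, model = 2, seed = 3000 + r)
    null <- sim$B[, 1]
    null[17] <- null[17] - shift
    rej[r] <- test_loadings(sim$panel, k = 1, null = null, n_boot = 500,
                            seed = 4000 + r)$reject
  }
  expect_gt(mean(rej), 0.9)
})

test_that("tidy/glance/autoplot on test objects are well-formed", {
  sim <- simulate_panel(n_time = 100, p = 8, model = 1, seed = 2)
  tst <- test_loadings(sim$panel, k = 1, null = sim$B[, 1],
                       n_boot = 100, seed = 5)
  expect_named(glance(tst),
               c("mode", "statistic", "critical_value", "alpha",
                 "studentized", "n_boot", "reject"))
  expect_equal(nrow(tidy(tst)), 8)
  expect_s3_class(autoplot(tst), "ggplot")
})
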
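# Full-size parameter recovery (n=3000 and n=12000 cohorts) lives in
# test-acceptance.R; the fits are shared through helper-cache.R. Here the
# fitter's mechanics are exercised on small cohorts.

test_that("analytic and numerical gradients of the likelihood agree", {
  sim <- simulate_cohort(cohort_config(n = 120, seed = 31))
  tab <- hlemc:::build_pair_table(sim$dataset)
  theta <- unname(params_to_vector(sim$truth))
  lg <- hlemc:::cpp_dataset_loglik_grad(theta, tab[, 1:7])
  gnum <- vapply(1:20, function(i) {
    e <- numeric(20); e[i] <- 1e-6
    (hlemc:::cpp_dataset_loglik(theta + e, tab[, 1:7]) -
       hlemc:::cpp_dataset_loglik(theta - e, tab[, 1:7])) / 2e-6
  }, 0)
  expect_equal(lg$loglik, hlemc:::cpp_dataset_loglik(theta, tab[, 1:7]))
  expect_equal(lg$gradient, gnum, tolerance = 1e-5)
})

test_that("centered-age reparameterization round-trips", {
  v <- unname(params_to_vector(default_truth()))
  expect_equal(hlemc:::unscale_theta(hlemc:::scale_theta(v)), v,
               tolerance = 1e-12)
  # Jacobian matches a finite-difference of the unscale map
  J <- hlemc:::unscale_jacobian()
  for (i in c(1, 2, 7, 20)) {
    e <- numeric(20); e[i] <- 1e-6
    fd <- (hlemc:::unscale_theta(v + e) - hlemc:::unscale_theta(v - e)) / 2e-6
    expect_equal(fd, J[, i], tolerance = 1e-9)
  }
})

test_that("fit converges, improves on init, and is a fixed point", {
  cf <- cached_sim_fit(3000)
  f1 <- cf$fit
  expect_true(f1$converged)
  expect_lte(f1$gradient_norm, 1e-4)
  expect_gte(f1$loglik, f1$loglik_init)
  # refit from the fitted point: parameters unchanged, loglik not lower
  f2 <- fit(cf$sim$dataset, init = f1$params_hat)
  expect_equal(params_to_vector(f2$params_hat),
               params_to_vector(f1$params_hat), tolerance = 1e-6)
  expect_gte(f2$loglik, f1$loglik - 1e-8)
})

test_that("fitting is deterministic given dataset, init and settings", {
  sim <- simulate_cohort(cohort_config(n = 300, seed = 17))
  f1 <- fit(sim$dataset)
  f3 <- fit(sim$dataset)
  expect_identical(params_to_vector(f3$params_hat),
                   params_to_vector(f1$params_hat))
  expect_identical(f3$loglik, f1$loglik)
  expect_identical(f3$gradient_norm, f1$gradient_norm)
  expect_gte(f1$loglik, f1$loglik_init)
})

test_that("unobserved transition types are bounded with a warning", {
  # no recovery in truth, tiny cohort -> no observed 1->0 endpoint pairs
  cfg <- cohort_config(n = 120, seed = 8, p_baseline_disabled = 0,
                       truth = make_params(alpha_01 = -50, alpha_10 = -50,
                                           alpha_02 = -4.5, alpha_12 = -4.5))
  sim <- simulate_cohort(cfg)
  tab <- hlemc:::build_pair_table(sim$dataset)
  expect_false(any(tab[, "s0"] == 1L))
  f <- fit(sim$dataset)
  expect_true(any(grepl("no_observed_transition\\(1,0\\)", f$warnings)))
  expect_true(any(grepl("no_observed_transition\\(1,2\\)", f$warnings)))
  # bounded at the default init, excluded from optimization
  expect_identical(unname(params_to_vector(f$params_hat)["alpha_10"]), -4)
  expect_true(all(is.na(f$standard_errors[11:20])))
})

test_that("non-finite likelihood at init raises an initialization error", {
  sim <- simulate_cohort(cohort_config(n = 50, seed = 5))
  # survival probabilities underflow to exactly 0 at this mortality logit
  bad <- make_params(alpha_02 = 5000, alpha_12 = 5000)
  expect_error(fit(sim$dataset, init = bad), "not finite")
})

test_that("SE seam reproduces the closed form of a quadratic objective", {
  # -loglik = 0.5 * x' A x with known A: covariance must be A^{-1} on the
  # scaled scale, mapped through the unscale Jacobian
  set.seed(19)
  B <- matrix(rnorm(400), 20)
  A <- crossprod(B) / 20 + diag(20)
  negll <- function(x) 0.5 * drop(x %*% A %*% x)
  out <- hlemc:::se_from_negloglik(negll, rep(0, 20))
  J <- hlemc:::unscale_jacobian()
  expect_equal(out$vcov, J %*% solve(A) %*% t(J), tolerance = 1e-5)
  expect_equal(out$se, sqrt(diag(J %*% solve(A) %*% t(J))), tolerance = 1e-5)
})

test_that("singular designs yield absent SEs with a warning", {
  # all-female cohort: the sex column never varies, so the observed
  # information is singular in the sex coefficients
  cfg <- cohort_config(n = 150, seed = 13, p_male = 0)
  sim <- simulate_cohort(cfg)
  expect_warning(
    out <- observed_information_se(sim$dataset, sim$truth),
    "not positive definite")
  expect_null(out)
})

test_that("SEs shrink like 1/sqrt(n) between n=3000 and n=12000", {
  small <- cached_sim_fit(3000)$fit
  big <- cached_sim_fit(12000)$fit
  ratio <- stats::median(small$standard_errors / big$standard_errors,
                         na.rm = TRUE)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("coefficient estimates are unbiased across 20 replicate cohorts", {
  reps <- 20L
  est <- matrix(NA_real_, reps, 20)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(cohort_config(n = 3000, seed = 5000 + r))
    est[r, ] <- unname(params_to_vector(fit(sim$dataset)$params_hat))
  }
  truth <- unname(params_to_vector(default_truth()))
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) <= 3 * mc_se))
})

test_that("fit JSON sidecar and text table round-trip", {
  sim <- simulate_cohort(cohort_config(n = 200, seed = 21))
  f <- fit(sim$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(f, path)
  back <- read_fit(path)
  expect_equal(params_to_vector(back$params_hat),
               params_to_vector(f$params_hat))
  expect_identical(back$converged, f$converged)
  expect_equal(back$standard_errors, f$standard_errors)
  tab <- format_fit_table(f)
  expect_identical(length(tab), 21L)
  expect_match(tab[2], "^alpha_01")
})
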
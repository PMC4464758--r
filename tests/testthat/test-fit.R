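test_that("ML fit recovers the generating parameters on complete data", {
  p <- tab1_params()
  rec <- complete_records(400, p, seed = 5)
  fit <- fpt_fit(rec, restarts = 2, seed = 1)
  expect_true(fit$converged)
  est <- fit$coefficients; se <- fit$se
  truth <- c(p$mu1, p$mu2 - p$mu1, p$sigma1_sq, p$sigma2_sq)
  expect_true(all(abs(est - truth) < 4 * se))
  expect_true(all(se > 0))
  expect_equal(unname(fit$ci95[, 1]), unname(est - 1.96 * se))
  # loglik at the optimum beats the truth (it is the maximiser)
  expect_gte(fit$loglik,
             fpt_loglik(rec, truth[1:2], truth[3:4]) - 1e-6)
})

test_that("equal-variance and propvar fits recover their submodels", {
  pe <- model_params(0.8, 0.3, 0.25, 0.3, B = 10)
  rec <- complete_records(300, pe, seed = 6)
  fe <- fpt_fit(rec, variance_mode = "equal", restarts = 1, seed = 2)
  expect_true(fe$converged)
  expect_true(all(abs(fe$coefficients - c(0.8, -0.55, 0.3)) < 4 * fe$se))

  q <- propvar_params(1, 2, 0.5, B = 10)
  recq <- complete_records(300, q, seed = 7)
  fq <- fpt_fit(recq, variance_mode = "propvar", restarts = 1, seed = 3)
  expect_true(fq$converged)
  expect_true(all(abs(fq$coefficients - c(1, 1, 0.5)) < 4 * fq$se))
})

test_that("fit handles right-censored records", {
  p <- tab1_params()
  rate <- calibrate_right_censoring(p, 0.2, n = 5000, seed = 71)
  pairs <- rfpt(300, p, seed = 72)[c("s", "r")]
  rec <- apply_scheme(pairs, censoring_scheme(right = rate), p, seed = 73)
  expect_gt(sum(rec$delta_r == 0), 20)
  fit <- fpt_fit(rec, restarts = 1, seed = 4)
  expect_true(fit$converged)
  truth <- c(p$mu1, p$mu2 - p$mu1, p$sigma1_sq, p$sigma2_sq)
  expect_true(all(abs(fit$coefficients - truth) < 4 * fit$se))
})

test_that("S-only fit recovers (mu1, sigma1_sq) and matches its objective", {
  p <- tab1_params()
  rec <- complete_records(400, p, seed = 8)
  fs <- fpt_fit_s(rec, restarts = 2, seed = 5)
  expect_true(fs$converged)
  expect_true(all(abs(fs$coefficients - c(1, 0.4)) < 4 * fs$se))
  expect_equal(fs$loglik,
               fpt_loglik_s(rec, fs$coefficients[1], fs$coefficients[2]),
               tolerance = 1e-8)
})

test_that("likelihood ratio test behaves on identical and nested models", {
  p <- tab1_params()
  rec <- complete_records(150, p, seed = 9)
  full <- fpt_fit(rec, post = ~1, variance_mode = "equal", restarts = 1,
                  seed = 6)
  expect_equal(fpt_lrt(full, full)$stat, 0)
  expect_equal(fpt_lrt(full, full)$p_value, 1)
  null <- fpt_fit(rec, post = ~0, variance_mode = "equal", restarts = 1,
                  seed = 6)
  out <- fpt_lrt(full, null)
  expect_equal(out$df, 1)
  expect_gte(out$stat, 0)
  expect_error(fpt_lrt(null, full))
})

test_that("boundary rescaling maps estimates and leaves test statistics alone", {
  p <- tab1_params()
  rec <- complete_records(120, p, seed = 10)
  f10_full <- fpt_fit(rec, post = ~1, variance_mode = "equal", B = 10,
                      restarts = 1, seed = 7)
  f10_null <- fpt_fit(rec, post = ~0, variance_mode = "equal", B = 10,
                      restarts = 1, seed = 7)
  f20_full <- fpt_fit(rec, post = ~1, variance_mode = "equal", B = 20,
                      restarts = 1, seed = 7)
  f20_null <- fpt_fit(rec, post = ~0, variance_mode = "equal", B = 20,
                      restarts = 1, seed = 7)
  # mu -> 2 mu, sigma^2 -> 4 sigma^2, identical loglik and LRT
  expect_equal(unname(f20_full$coefficients[1:2]),
               unname(2 * f10_full$coefficients[1:2]), tolerance = 1e-4)
  expect_equal(unname(f20_full$coefficients[3]),
               unname(4 * f10_full$coefficients[3]), tolerance = 1e-4)
  expect_equal(f20_full$loglik, f10_full$loglik, tolerance = 1e-7)
  expect_equal(fpt_lrt(f20_full, f20_null)$stat,
               fpt_lrt(f10_full, f10_null)$stat, tolerance = 1e-5)
})

test_that("uniform residuals are self-consistent and hit their CDF limits", {
  p <- tab1_params()
  rec <- complete_records(500, p, seed = 11)
  fit <- fpt_fit(rec, restarts = 1, seed = 8)
  u <- uniform_residuals(fit)
  expect_length(u, 500)
  expect_true(all(u >= 0 & u <= 1))
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
  expect_equal(attr(u, "n_excluded"), 0)
  # limits in r
  fit_lim <- fit
  fit_lim$records <- fit$records[1:3, ]
  fit_lim$X_pre <- fit$X_pre[1:3, , drop = FALSE]
  fit_lim$X_post <- fit$X_post[1:3, , drop = FALSE]
  fit_lim$records$r <- c(1e-8, 1e4, 50)
  u_lim <- uniform_residuals(fit_lim)
  expect_lt(u_lim[1], 1e-6)
  expect_gt(u_lim[2], 1 - 1e-6)
  # censored records are excluded and counted
  fit_c <- fit
  fit_c$records$delta_r[1:25] <- 0L
  u_c <- uniform_residuals(fit_c)
  expect_length(u_c, 475)
  expect_equal(attr(u_c, "n_excluded"), 25)
})
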
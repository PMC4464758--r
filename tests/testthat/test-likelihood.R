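test_that("complete data collapses the likelihood to sum log f_SR", {
  p <- tab1_params()
  rec <- complete_records(40, p, seed = 61)
  ll <- fpt_loglik(rec, beta = c(p$mu1, p$mu2 - p$mu1),
                   variance = c(p$sigma1_sq, p$sigma2_sq))
  expect_equal(ll, sum(dfpt_sr(rec$s, rec$r, p, log = TRUE)),
               tolerance = 1e-12)
})

test_that("a truncated record contributes the IG density / CDF", {
  p <- tab1_params()
  rec <- data.frame(s = 4.2, r = 0, delta_l = 1L, delta_r = 1L, nu = 0L)
  ll <- fpt_loglik(rec, beta = c(1, -0.9), variance = c(0.4, 0.026))
  expect_equal(ll, dinvgauss(4.2, 10, 100 / 0.4, log = TRUE),
               tolerance = 1e-12)
  rec$delta_l <- 0L
  ll2 <- fpt_loglik(rec, beta = c(1, -0.9), variance = c(0.4, 0.026))
  expect_equal(ll2, pinvgauss(4.2, 10, 100 / 0.4, log.p = TRUE),
               tolerance = 1e-12)
})

test_that("censoring integrals match adaptive quadrature", {
  p <- tab1_params()
  beta <- c(p$mu1, p$mu2 - p$mu1); variance <- c(p$sigma1_sq, p$sigma2_sq)
  # left censored: int_0^s f_SR(u, r) du
  rec2 <- data.frame(s = 4, r = 30, delta_l = 0L, delta_r = 1L, nu = 1L)
  expect_equal(fpt_loglik(rec2, beta, variance),
               log(integrate(function(u) dfpt_sr(u, 30, p), 0, 4,
                             rel.tol = 1e-12)$value),
               tolerance = 1e-8)
  # right censored: log[f_S(s) - int_0^r f_SR(s, u) du]
  rec3 <- data.frame(s = 4, r = 30, delta_l = 1L, delta_r = 0L, nu = 1L)
  direct <- dfpt_s(4, p) - integrate(function(u) dfpt_sr(4, u, p), 0, 30,
                                     rel.tol = 1e-12)$value
  expect_equal(fpt_loglik(rec3, beta, variance), log(direct),
               tolerance = 1e-6)
  # right censored so deep that the subtraction would cancel: tail route
  rec3b <- data.frame(s = 4, r = 400, delta_l = 1L, delta_r = 0L, nu = 1L)
  tail_direct <- integrate(function(u) dfpt_sr(4, u, p), 400, Inf,
                           rel.tol = 1e-10)$value
  expect_equal(fpt_loglik(rec3b, beta, variance), log(tail_direct),
               tolerance = 1e-5)
  # doubly censored: int_0^s int_r^inf f_SR du dv
  rec6 <- data.frame(s = 4, r = 30, delta_l = 0L, delta_r = 0L, nu = 1L)
  dbl <- integrate(function(u) {
    vapply(u, function(ui) {
      dfpt_s(ui, p) - integrate(function(v) dfpt_sr(ui, v, p), 0, 30,
                                rel.tol = 1e-11)$value
    }, numeric(1))
  }, 0, 4, rel.tol = 1e-10)$value
  expect_equal(fpt_loglik(rec6, beta, variance), log(dbl), tolerance = 1e-6)
})

test_that("left-censored term equals a Monte Carlo joint probability", {
  p <- tab1_params()
  d <- rfpt(1e5, p, seed = 62)
  s0 <- 5; r0 <- 40; h <- 5
  mc <- mean(d$s <= s0 & abs(d$r - r0) <= h) / (2 * h)
  mc_se <- sd((d$s <= s0 & abs(d$r - r0) <= h) / (2 * h)) / sqrt(nrow(d))
  rec <- data.frame(s = s0, r = r0, delta_l = 0L, delta_r = 1L, nu = 1L)
  # the window-averaged density, compared with the point value at the centre
  val <- exp(fpt_loglik(rec, c(1, -0.9), c(0.4, 0.026)))
  expect_lt(abs(mc - val), 3 * mc_se + 0.05 * val)
})

test_that("likelihood is additive and permutation invariant", {
  p <- tab1_params()
  rec <- complete_records(30, p, seed = 63)
  rec$delta_r[1:5] <- 0L
  beta <- c(1, -0.9); variance <- c(0.4, 0.026)
  ll <- fpt_loglik(rec, beta, variance)
  perm <- rec[sample.int(nrow(rec)), ]
  expect_equal(fpt_loglik(perm, beta, variance), ll, tolerance = 1e-10)
  ll_split <- fpt_loglik(rec[1:10, ], beta, variance) +
    fpt_loglik(rec[11:30, ], beta, variance)
  expect_equal(ll_split, ll, tolerance = 1e-10)
})

test_that("propvar variance mode equals the free likelihood at sigma_i^2 = k mu_i", {
  p <- tab1_params()
  rec <- complete_records(25, p, seed = 64)
  rec$delta_r[1:3] <- 0L
  k <- 0.3; mu1 <- 0.9; mu2 <- 0.15
  ll_pv <- fpt_loglik(rec, c(mu1, mu2 - mu1), k, variance_mode = "propvar")
  ll_free <- fpt_loglik(rec, c(mu1, mu2 - mu1), c(k * mu1, k * mu2),
                        variance_mode = "free")
  expect_equal(ll_pv, ll_free, tolerance = 1e-10)
})

test_that("inadmissible drifts hit the sentinel and bad records error", {
  p <- tab1_params()
  rec <- complete_records(10, p, seed = 65)
  expect_equal(fpt_loglik(rec, beta = c(-1, 0.5), variance = c(0.4, 0.026)),
               -1e10)
  expect_equal(fpt_loglik(rec, beta = c(1, -1.5), variance = c(0.4, 0.026)),
               -1e10)
  bad <- rec; bad$nu[1] <- 0L   # truncated but r > 0
  expect_error(fpt_loglik(bad, c(1, -0.9), c(0.4, 0.026)))
  bad2 <- rec; bad2$delta_l[1] <- 2
  expect_error(fpt_loglik(bad2, c(1, -0.9), c(0.4, 0.026)))
})

test_that("drift_map builds per-subject drifts from shared + change designs", {
  X_pre <- cbind(1, c(0, 1, 0))
  X_post <- matrix(c(1, 1, 1), 3)
  dm <- drift_map(c(1, 0.5, -0.8), X_pre, X_post)
  expect_equal(dm$mu1, c(1, 1.5, 1))
  expect_equal(dm$mu2, c(0.2, 0.7, 0.2))
  expect_length(attr(dm, "nonpositive"), 0)
  dm2 <- drift_map(c(0.1, 0.5, -0.8), X_pre, X_post)
  expect_true(length(attr(dm2, "nonpositive")) > 0)
  expect_error(drift_map(c(1, 2), X_pre, X_post))
})

test_that("S-only likelihood is the sum of log f_S and is unimodal in mu1", {
  p <- tab1_params()
  rec <- complete_records(100, p, seed = 66)
  expect_equal(fpt_loglik_s(rec, 1, 0.4),
               sum(dfpt_s(rec$s, p, log = TRUE)), tolerance = 1e-12)
  grid <- seq(0.4, 2.5, by = 0.05)
  ll <- vapply(grid, function(m) fpt_loglik_s(rec, m, 0.4), numeric(1))
  expect_true(all(is.finite(ll)))
  # one sign change in the first differences: unimodal on the grid
  expect_equal(sum(diff(sign(diff(ll))) != 0), 1)
})
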
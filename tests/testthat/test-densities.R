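test_that("f_S normalises, matches its closed-form moments and small-s limit", {
  p <- tab1_params()
  expect_equal(quad0inf(function(s) dfpt_s(s, p), scale = 10), 1,
               tolerance = 1e-8)
  ms <- moments_s(p)
  expect_equal(ms$mean, 5.2)
  expect_equal(quad0inf(function(s) s * dfpt_s(s, p), scale = 10), ms$mean,
               tolerance = 1e-8)
  m2 <- quad0inf(function(s) s^2 * dfpt_s(s, p), scale = 10)
  expect_equal(m2 - ms$mean^2, ms$var, tolerance = 1e-7)
  # f_S(0+) -> mu1 / B
  expect_equal(dfpt_s(1e-10, p), p$mu1 / p$B, tolerance = 1e-8)
  expect_error(dfpt_s(-1, p))
  expect_error(dfpt_s(0, p))
})

test_that("CV(S) closed form gives the reference values", {
  cv <- function(s1) moments_s(model_params(1, s1, 0.1, 0.026, B = 10))$cv
  expect_equal(round(cv(0.4), 2), 0.62)
  expect_equal(round(cv(0.1), 2), 0.59)
  expect_equal(round(cv(1), 2), 0.68)
  expect_equal(round(cv(2), 2), 0.77)
})

test_that("absorbed position density integrates to the IG survival", {
  p <- tab1_params()
  for (s in c(1, 5, 20)) {
    expect_equal(
      integrate(function(x) dfpt_x0a(x, s, p), -Inf, p$B,
                rel.tol = 1e-10)$value,
      pinvgauss(s, p$B / p$mu1, p$B^2 / p$sigma1_sq, lower.tail = FALSE),
      tolerance = 1e-6)
  }
  expect_equal(dfpt_x0a(p$B, 2, p), 0)
  expect_equal(dfpt_x0a(p$B + 1, 2, p), 0)
  # for small s the image term is negligible: free Gaussian limit
  s <- 0.01
  x <- c(-0.1, 0, 0.05)
  expect_equal(dfpt_x0a(x, s, p),
               dnorm(x, p$mu1 * s, sqrt(p$sigma1_sq * s)),
               tolerance = 1e-6)
})

test_that("stationary position density: normalisation, moments, CDF, branch", {
  p <- tab1_params()
  expect_equal(integrate(function(x) dfpt_x0(x, p), -Inf, p$B,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-7)
  mx <- moments_x0(p)
  expect_equal(mx$mean, 4.8)
  expect_equal(mx$var, (p$B^2 + 3 * p$sigma1_sq^2) / 12)
  expect_equal(integrate(function(x) x * dfpt_x0(x, p), -Inf, p$B,
                         rel.tol = 1e-10)$value, mx$mean, tolerance = 1e-8)
  expect_equal(integrate(function(x) (x - mx$mean)^2 * dfpt_x0(x, p), -Inf,
                         p$B, rel.tol = 1e-10)$value, mx$var,
               tolerance = 1e-7)
  # explicit 0 <= x < B branch
  x <- c(0.5, 3, 9)
  expect_equal(dfpt_x0(x, p),
               (1 - exp(2 * p$mu1 * (x - p$B) / p$sigma1_sq)) / p$B)
  # closed-form CDF against quadrature
  for (q in c(-2, 0, 4, 9.5)) {
    expect_equal(pfpt_x0(q, p),
                 integrate(function(x) dfpt_x0(x, p), -Inf, q,
                           rel.tol = 1e-10)$value, tolerance = 1e-7)
  }
})

test_that("f_R normalises and agrees with the mixture composition", {
  p <- tab1_params()
  expect_equal(quad0inf(function(r) dfpt_r(r, p), scale = 100), 1,
               tolerance = 1e-7)
  fr_num <- function(r) {
    integrate(function(x) {
      dinvgauss(r, (p$B - x) / p$mu2, (p$B - x)^2 / p$sigma2_sq) *
        dfpt_x0(x, p)
    }, -Inf, p$B, rel.tol = 1e-11)$value
  }
  for (r in c(1, 10, 100)) {
    expect_equal(dfpt_r(r, p), fr_num(r), tolerance = 1e-6)
  }
  expect_error(dfpt_r(0, p))
})

test_that("CV(R) by quadrature reproduces the reference scenario values", {
  expect_equal(round(moments_r(tab1_params())$cv, 2), 0.60)
  expect_equal(round(moments_r(model_params(1, 0.4, 0.1, 0.131))$cv, 2), 0.75)
})

test_that("joint density: marginalisation, normalisation, composition", {
  p <- tab1_params()
  # int f_SR dr = f_S
  for (s in c(1, 5, 20)) {
    expect_equal(quad0inf(function(r) dfpt_sr(s, r, p), scale = 100),
                 dfpt_s(s, p), tolerance = 1e-7)
  }
  # double integral = 1
  outer_int <- quad0inf(function(s) {
    vapply(s, function(si) quad0inf(function(r) dfpt_sr(si, r, p),
                                    scale = 100), numeric(1))
  }, scale = 10, rel.tol = 1e-8)
  expect_equal(outer_int, 1, tolerance = 1e-6)
  # numeric composition through the absorbed position density
  fsr_num <- function(s, r) {
    ET <- p$B / p$mu1
    integrate(function(x) {
      dinvgauss(r, (p$B - x) / p$mu2, (p$B - x)^2 / p$sigma2_sq) *
        dfpt_x0a(x, s, p)
    }, -Inf, p$B, rel.tol = 1e-11)$value / ET
  }
  for (s in c(2, 5, 20)) {
    for (r in c(1, 10, 50)) {
      expect_equal(dfpt_sr(s, r, p), fsr_num(s, r), tolerance = 1e-6)
    }
  }
})

test_that("log and linear density forms are consistent", {
  p <- tab1_params()
  s <- c(0.3, 2, 8, 30); r <- c(0.5, 12, 80, 200)
  expect_equal(exp(dfpt_s(s, p, log = TRUE)), dfpt_s(s, p), tolerance = 1e-12)
  expect_equal(exp(dfpt_r(r, p, log = TRUE)), dfpt_r(r, p), tolerance = 1e-12)
  expect_equal(exp(dfpt_sr(s, r, p, log = TRUE)), dfpt_sr(s, r, p),
               tolerance = 1e-12)
})

test_that("densities stay finite for very stiff exponents (2 mu1 B / sigma1^2 >= 800)", {
  stiff <- model_params(1, 0.025, 0.1, 0.026, B = 10)   # exponent 800
  expect_true(is.finite(dfpt_s(5, stiff, log = TRUE)))
  expect_true(is.finite(dfpt_sr(5, 40, stiff, log = TRUE)))
  expect_true(is.finite(dfpt_r(40, stiff, log = TRUE)))
  expect_equal(quad0inf(function(s) dfpt_s(s, stiff), scale = 10), 1,
               tolerance = 1e-7)
})

test_that("proportional-variance submodel collapses and summarises correctly", {
  q <- propvar_params(mu1 = 1, mu2 = 2, k = 0.5, B = 10)
  pq <- as_model_params(q)
  expect_equal(pq$sigma1_sq, 0.5)
  expect_equal(pq$sigma2_sq, 1.0)
  # Eq-form equality with the general density
  expect_equal(dfpt_sr(3, 7, q), dfpt_sr(3, 7, pq), tolerance = 1e-10)
  expect_equal(dfpt_sr(3, 7, q),
               q$mu1 * q$mu2 / q$B *
                 dinvgauss(q$mu1 * 3 + q$mu2 * 7, q$B, q$B^2 / q$k),
               tolerance = 1e-12)
  # depends on (s, r) only through mu1 s + mu2 r
  expect_equal(dfpt_sr(1, 4.5, q), dfpt_sr(5, 2.5, q), tolerance = 1e-12)

  ps <- propvar_summaries(q)
  expect_equal(ps$CV_S, ps$CV_R)
  expect_equal(ps$CV_S, (q$B + 3 * q$k) / (sqrt(3) * (q$B + q$k)))
  expect_equal(ps$cov_SR, (3 * q$k^2 - q$B^2) / (12 * q$mu1 * q$mu2))
  # CVs do not depend on the drifts
  ps2 <- propvar_summaries(propvar_params(0.3, 5, 0.5, 10))
  expect_equal(ps2$CV_S, ps$CV_S)
  # zero-correlation point at k = B / sqrt(3)
  expect_equal(propvar_summaries(propvar_params(1, 2, 10 / sqrt(3), 10))$corr_SR,
               0, tolerance = 1e-14)
  # closed-form moments of R vs quadrature of the propvar f_R
  mr <- moments_r(pq)
  expect_equal(mr$mean, ps$E_R, tolerance = 1e-7)
  expect_equal(mr$var, ps$Var_R, tolerance = 1e-6)
})

test_that("parameter constructors validate their domain", {
  expect_error(model_params(-1, 0.4, 0.1, 0.026))
  expect_error(model_params(1, 0, 0.1, 0.026))
  expect_error(propvar_params(1, 2, -0.5))
  expect_error(dfpt_sr(-1, 2, tab1_params()))
  expect_error(dfpt_sr(2, 0, tab1_params()))
})
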
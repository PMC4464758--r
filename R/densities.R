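# Closed-form laws of the observable quantities.  Internal log_* functions are
# fully vectorised over observations *and* parameters (the likelihood feeds
# per-subject drifts through them); exported d*/p* wrappers take an
# `fpt_params` object and follow base-R d/p conventions with a `log` argument.
# Every exp(a) * Phi(z) product is evaluated as exp(a + pnorm(z, log.p = TRUE))
# so the densities stay finite for 2*mu1*B/sigma1^2 well beyond 700.

# Sum of signed exponentials: log |sum_j S_j exp(L_j)| clamped to -Inf when the
# sum is <= 0.  L, S are matrices (rows = observations, cols = terms).
logsum_signed <- function(L, S) {
  m <- do.call(pmax, c(as.data.frame(L), na.rm = FALSE))
  v <- rowSums(S * exp(L - m))
  out <- ifelse(is.finite(m) & v > 0, m + log(v), -Inf)
  out[!is.finite(m) & m < 0] <- -Inf
  out
}

log_fS <- function(s, mu1, s1, B) {
  sd <- sqrt(s1 * s)
  l1 <- stats::pnorm((B - mu1 * s) / sd, log.p = TRUE)
  l2 <- 2 * mu1 * B / s1 + stats::pnorm((-B - mu1 * s) / sd, log.p = TRUE)
  log(mu1 / B) + logspace_sub(l1, l2)
}

log_fX0a <- function(x, s, mu1, s1, B) {
  lead <- -0.5 * log(2 * pi * s1 * s)
  t1 <- -(x - mu1 * s)^2 / (2 * s1 * s)
  t2 <- 2 * mu1 * B / s1 - (x - 2 * B - mu1 * s)^2 / (2 * s1 * s)
  out <- lead + logspace_sub(t1, t2)
  out[x >= B] <- -Inf
  out
}

log_fX0 <- function(x, mu1, s1, B) {
  out <- -log(B) + logspace_sub(mu1 * (x - abs(x)) / s1,
                                2 * mu1 * (x - B) / s1)
  out[x >= B] <- -Inf
  out
}

log_fR <- function(r, mu1, s1, mu2, s2, B) {
  sig2 <- sqrt(s2)
  sr <- sqrt(r)
  a <- 2 * mu1 * B / s1
  z1 <- (B - mu2 * r) / (sig2 * sr)
  z2 <- -mu2 * sr / sig2
  lT1 <- log(mu2 / B) +
    logspace_sub(stats::pnorm(z1, log.p = TRUE),
                 stats::pnorm(z2, log.p = TRUE))
  c0 <- (mu2 * s1 - 2 * mu1 * s2) / (B * s1)
  e <- 2 * mu1 * r * (mu1 * s2 - mu2 * s1) / s1^2
  w1 <- -(B * s1 + 2 * r * mu1 * s2 - mu2 * r * s1) / (s1 * sig2 * sr)
  w2 <- -(2 * mu1 * r * s2 - mu2 * r * s1) / (s1 * sig2 * sr)
  lc0 <- log(abs(c0))
  sgn <- sign(c0)
  n <- length(lT1 + r)
  L <- cbind(rep_len(lT1, n),
             rep_len(lc0 + e + a + stats::pnorm(w1, log.p = TRUE), n),
             rep_len(lc0 + e + stats::pnorm(w2, log.p = TRUE), n))
  S <- cbind(rep_len(1, n), rep_len(sgn, n), rep_len(-sgn, n))
  logsum_signed(L, S)
}

log_fSR <- function(s, r, mu1, s1, mu2, s2, B) {
  Sig <- s1 * s + s2 * r
  pref <- log(mu1 / B) - 0.5 * (log(2 * pi) + 3 * log(Sig)) -
    (B - mu1 * s - mu2 * r)^2 / (2 * Sig)
  den <- sqrt(s1) * sqrt(s2) * sqrt(s * Sig)
  A1 <- (B - mu1 * s) * s2 + mu2 * s1 * s
  A2 <- (-B - mu1 * s) * s2 + mu2 * s1 * s
  z1 <- sqrt(r) * A1 / den
  z2 <- sqrt(r) * A2 / den
  cc <- 2 * r * B * (mu1 * s2 - mu2 * s1) / (s1 * Sig)
  l1 <- log(abs(A1)) + stats::pnorm(z1, log.p = TRUE)
  l2 <- cc + log(abs(A2)) + stats::pnorm(z2, log.p = TRUE)
  n <- length(pref + l1)
  L <- cbind(rep_len(l1, n), rep_len(l2, n))
  S <- cbind(rep_len(sign(A1), n), rep_len(-sign(A2), n))
  rep_len(pref, n) + logsum_signed(L, S)
}

log_fSR_propvar <- function(s, r, mu1, mu2, k, B) {
  y <- mu1 * s + mu2 * r
  log(mu1) + log(mu2) - log(B) + dinvgauss(y, B, B^2 / k, log = TRUE)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", name))
  }
}

#' Density of the backward recurrence time S
#'
#' \eqn{S} is the time from the start of the latent process to the
#' intervention, with density \eqn{f_S(s) = \bar F_T(s) / E[T]} where
#' \eqn{T \sim IG(B/\mu_1, B^2/\sigma_1^2)} is the unperturbed first passage
#' time.  As \eqn{s \to 0^+}, \eqn{f_S(s) \to \mu_1 / B}.
#'
#' @param s vector of positive times.
#' @param p an [model_params()] or [propvar_params()] object.
#' @param log logical; return the log density.
#' @return (Log) density values.
#' @examples
#' p <- model_params(1, 0.4, 0.1, 0.026)
#' dfpt_s(5.2, p)
#' @export
dfpt_s <- function(s, p, log = FALSE) {
  p <- as_params(p)
  check_positive(s, "s")
  lf <- log_fS(s, p$mu1, p$sigma1_sq, p$B)
  if (log) lf else exp(lf)
}

#' Distribution function of S
#'
#' Evaluated by Gauss-Legendre quadrature of [dfpt_s()] on \eqn{(0, s)}.
#'
#' @inheritParams dfpt_s
#' @param q vector of non-negative times.
#' @return \eqn{P(S \le q)}.
#' @export
pfpt_s <- function(q, p) {
  p <- as_params(p)
  stopifnot(all(q >= 0))
  out <- numeric(length(q))
  pos <- q > 0
  if (any(pos)) {
    out[pos] <- gl_integral0(
      function(x, idx) exp(log_fS(x, p$mu1, p$sigma1_sq, p$B)),
      q[pos], n = 120L)
  }
  pmin(out, 1)
}

#' Closed-form moments of S
#'
#' @inheritParams dfpt_s
#' @return A list with `mean`, `var` and `cv` (coefficient of variation).
#' @examples
#' moments_s(model_params(1, 0.4, 0.1, 0.026))$cv  # 0.62 at B = 10
#' @export
moments_s <- function(p) {
  p <- as_params(p)
  mu1 <- p$mu1; s1 <- p$sigma1_sq; B <- p$B
  list(mean = (B * mu1 + s1) / (2 * mu1^2),
       var = ((B * mu1 + 3 * s1) / (2 * mu1^2))^2 / 3,
       cv = (B * mu1 + 3 * s1) / (sqrt(3) * (B * mu1 + s1)))
}

#' Sub-density of the position X(0) at intervention, jointly with survival
#'
#' `dfpt_x0a(x, s, p)` is the density of the process position at the
#' intervention after running for time `s` in the presence of the absorbing
#' boundary (an image-method difference of two Gaussians); it integrates over
#' \eqn{x \in (-\infty, B)} to the survival probability \eqn{P(T > s)}, and is
#' 0 at and above the boundary.
#'
#' @param x vector of positions (`< B` for a positive value).
#' @param s running time (`> 0`).
#' @inheritParams dfpt_s
#' @return (Log) density values.
#' @export
dfpt_x0a <- function(x, s, p, log = FALSE) {
  p <- as_params(p)
  check_positive(s, "s")
  lf <- log_fX0a(x, s, p$mu1, p$sigma1_sq, p$B)
  if (log) lf else exp(lf)
}

#' Stationary density and distribution of the position X(0)
#'
#' The position of the process at an independently placed intervention time,
#' marginalised over \eqn{S}.  The density lives on \eqn{(-\infty, B)}, has a
#' kink at 0, and for \eqn{0 \le x < B} reduces to
#' \eqn{(1/B)[1 - \exp(2\mu_1 (x - B)/\sigma_1^2)]}.
#'
#' @param x,q vector of positions.
#' @inheritParams dfpt_s
#' @return `dfpt_x0` the (log) density, `pfpt_x0` the closed-form distribution
#'   function, `moments_x0` a list with `mean` and `var`.
#' @export
dfpt_x0 <- function(x, p, log = FALSE) {
  p <- as_params(p)
  lf <- log_fX0(x, p$mu1, p$sigma1_sq, p$B)
  if (log) lf else exp(lf)
}

#' @rdname dfpt_x0
#' @export
pfpt_x0 <- function(q, p) {
  p <- as_params(p)
  mu1 <- p$mu1; s1 <- p$sigma1_sq; B <- p$B
  cc <- 2 * mu1 / s1
  a <- cc * B
  F0 <- (1 - exp(-a)) / (B * cc)
  out <- numeric(length(q))
  lo <- q <= 0
  out[lo] <- exp(cc * q[lo]) * (1 - exp(-a)) / (B * cc)
  mid <- q > 0 & q < B
  out[mid] <- F0 + q[mid] / B -
    (exp(cc * (q[mid] - B)) - exp(-a)) / (B * cc)
  out[q >= B] <- 1
  out
}

#' @rdname dfpt_x0
#' @export
moments_x0 <- function(p) {
  p <- as_params(p)
  mu1 <- p$mu1; s1 <- p$sigma1_sq; B <- p$B
  list(mean = (B * mu1 - s1) / (2 * mu1),
       var = (B^2 * mu1^2 + 3 * s1^2) / (12 * mu1^2))
}

#' Density of the residual time R after the intervention
#'
#' The marginal law of the time from the intervention to the first boundary
#' crossing, obtained by mixing the conditional first-passage law
#' \eqn{R | X(0) = x \sim IG((B-x)/\mu_2, (B-x)^2/\sigma_2^2)} over the
#' stationary position density; a four-term closed form.
#'
#' @param r vector of positive times.
#' @inheritParams dfpt_s
#' @return (Log) density values.
#' @export
dfpt_r <- function(r, p, log = FALSE) {
  p <- as_params(p)
  check_positive(r, "r")
  lf <- log_fR(r, p$mu1, p$sigma1_sq, p$mu2, p$sigma2_sq, p$B)
  if (log) lf else exp(lf)
}

#' Moments of R by adaptive quadrature
#'
#' No closed form exists for the moments of \eqn{R} in the free-parameter
#' model; they are computed by adaptive quadrature of [dfpt_r()] on a
#' transformed semi-infinite domain (relative tolerance `1e-9`).
#'
#' @inheritParams dfpt_s
#' @return A list with `mean`, `var` and `cv`.
#' @examples
#' moments_r(model_params(1, 0.4, 0.1, 0.026))$cv  # approx 0.60
#' @export
moments_r <- function(p) {
  p <- as_params(p)
  f <- function(r) exp(log_fR(r, p$mu1, p$sigma1_sq, p$mu2, p$sigma2_sq, p$B))
  scale <- p$B / p$mu2
  m1 <- integrate_0inf(function(r) r * f(r), scale = scale)
  m2 <- integrate_0inf(function(r) r^2 * f(r), scale = scale)
  list(mean = m1, var = m2 - m1^2, cv = sqrt(m2 - m1^2) / m1)
}

#' Joint density of (S, R)
#'
#' The closed-form joint density of the backward recurrence time and the
#' residual time.  For `fpt_params` this is the general two-term expression;
#' for [propvar_params()] it uses the proportional-variance collapse
#' \eqn{f_{(S,R)}(s,r) = (\mu_1\mu_2/B) f_{IG(B, B^2/k)}(\mu_1 s + \mu_2 r)},
#' which depends on \eqn{(s, r)} only through \eqn{\mu_1 s + \mu_2 r}.  The two
#' agree to near machine precision when \eqn{\sigma_i^2 = k\mu_i}.
#'
#' @param s,r vectors of positive times.
#' @inheritParams dfpt_s
#' @return (Log) joint density values.
#' @examples
#' p <- model_params(1, 0.4, 0.1, 0.026)
#' dfpt_sr(5, 50, p)
#' @export
dfpt_sr <- function(s, r, p, log = FALSE) {
  check_positive(s, "s")
  check_positive(r, "r")
  if (inherits(p, "fpt_propvar")) {
    lf <- log_fSR_propvar(s, r, p$mu1, p$mu2, p$k, p$B)
  } else {
    p <- as_params(p)
    lf <- log_fSR(s, r, p$mu1, p$sigma1_sq, p$mu2, p$sigma2_sq, p$B)
  }
  if (log) lf else exp(lf)
}

#' Closed-form summaries of the proportional-variance submodel
#'
#' Means, variances, coefficients of variation and the covariance/correlation
#' of \eqn{(S, R)} under \eqn{\sigma_i^2 = k\mu_i}.  The CVs of \eqn{S} and
#' \eqn{R} coincide, \eqn{(B + 3k)/(\sqrt{3}(B + k))}, and the correlation
#' \eqn{(3k^2 - B^2)/(B + 3k)^2} is positive, zero or negative according to
#' whether \eqn{k} is below, at or above \eqn{B/\sqrt{3}}.
#'
#' @param q a [propvar_params()] object.
#' @return A named list with `E_S`, `Var_S`, `CV_S`, `E_R`, `Var_R`, `CV_R`,
#'   `cov_SR`, `corr_SR`.
#' @export
propvar_summaries <- function(q) {
  stopifnot(inherits(q, "fpt_propvar"))
  B <- q$B; k <- q$k
  cv <- (B + 3 * k) / (sqrt(3) * (B + k))
  list(E_S = (B + k) / (2 * q$mu1),
       Var_S = (B + 3 * k)^2 / (12 * q$mu1^2),
       CV_S = cv,
       E_R = (B + k) / (2 * q$mu2),
       Var_R = (B + 3 * k)^2 / (12 * q$mu2^2),
       CV_R = cv,
       cov_SR = (3 * k^2 - B^2) / (12 * q$mu1 * q$mu2),
       corr_SR = (3 * k^2 - B^2) / (B + 3 * k)^2)
}
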
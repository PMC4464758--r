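# Exact and path-based samplers for (S, X(0), R), plus observation schemes
# (right/left censoring, truncation) that turn latent pairs into analysis-ready
# records.

# Numeric CDF of S tabulated on a dense grid and inverted monotonically.
# Eq-(7)-type densities have no closed inverse CDF; the grid reaches the
# 1 - 1e-8 quantile (log-spaced, 8192 points), beyond which the residual mass
# is invisible at Monte Carlo sample sizes.
s_cdf_grid <- function(p, n_grid = 8192L, tail_prob = 1e-8) {
  ms <- moments_s(p)
  hi <- ms$mean + 12 * sqrt(ms$var)
  f <- function(s) exp(log_fS(s, p$mu1, p$sigma1_sq, p$B))
  total <- function(h) integrate_0inf(f, scale = ms$mean)  # = 1 up to quadrature
  repeat {
    tail <- stats::integrate(function(u) {
      x <- hi + u / (1 - u) * ms$mean
      f(x) * ms$mean / (1 - u)^2
    }, 0, 1, rel.tol = 1e-10, abs.tol = 0, stop.on.error = FALSE)$value
    if (tail < tail_prob) break
    hi <- hi * 2
    if (hi > 1e12 * ms$mean) stop("failed to bracket the upper tail of S")
  }
  lo <- hi * 1e-8
  grid <- c(0, exp(seq(log(lo), log(hi), length.out = n_grid)))
  dens <- c(p$mu1 / p$B, f(grid[-1]))
  cdf <- cumtrapz_cdf(grid, dens)
  list(s = grid, F = cdf / max(cdf))
}

sample_s <- function(n, p, grid = NULL) {
  grid <- grid %||% s_cdf_grid(p)
  u <- stats::runif(n)
  keep <- !duplicated(grid$F)
  stats::approx(grid$F[keep], grid$s[keep], xout = u, rule = 2)$y
}

# X(0) | S = s by rejection.  The image-method sub-density factors as
#   f^a(x, s) = phi(x; mu1 s, sigma1^2 s) * [1 - exp(-2B(B - x)/(sigma1^2 s))]
# on x < B, so proposing from the free Gaussian *truncated at B* (exact, via
# inverse CDF on the log scale, stable arbitrarily deep in the tail) and
# accepting with the bracketed probability is exact with O(1) acceptance
# uniformly in s; a free (untruncated) Gaussian envelope would instead have
# acceptance rate P(T > s), which vanishes for s far beyond E[T].
sample_x0_given_s <- function(s, p, max_rounds = 10000L) {
  n <- length(s)
  x <- numeric(n)
  todo <- seq_len(n)
  rounds <- 0L
  while (length(todo) > 0) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop(sprintf(
        "X(0)|S rejection sampler did not finish after %d rounds (%d left)",
        max_rounds, length(todo)))
    }
    st <- s[todo]
    mu <- p$mu1 * st
    sd <- sqrt(p$sigma1_sq * st)
    lFB <- stats::pnorm(p$B, mu, sd, log.p = TRUE)
    lu <- log(stats::runif(length(todo))) + lFB
    prop <- mu + sd * stats::qnorm(lu, log.p = TRUE)
    w <- -expm1(-2 * p$B * (p$B - prop) / (p$sigma1_sq * st))
    acc <- stats::runif(length(todo)) < w
    x[todo[acc]] <- prop[acc]
    todo <- todo[!acc]
  }
  x
}

#' Exact sampling of (S, X(0), R) from the perturbed Wiener model
#'
#' Draws the backward recurrence time \eqn{S} by inverting a numerically
#' tabulated CDF of its closed-form density, the intervention-time position
#' \eqn{X(0) | S} by rejection from the free Gaussian envelope, and the
#' residual time \eqn{R | X(0) = x} exactly from
#' \eqn{IG((B-x)/\mu_2, (B-x)^2/\sigma_2^2)}.
#'
#' @param n number of subjects.
#' @param p an [model_params()] or [propvar_params()] object.
#' @param seed optional integer; if given, `set.seed(seed)` is called first so
#'   identical seeds give identical output.
#' @return A data frame with columns `s`, `x0`, `r`.
#' @examples
#' d <- rfpt(500, model_params(1, 0.4, 0.1, 0.026), seed = 1)
#' colMeans(d)
#' @export
rfpt <- function(n, p, seed = NULL) {
  p <- as_params(p)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- sample_s(n, p)
  x0 <- sample_x0_given_s(s, p)
  r <- rinvgauss(n, (p$B - x0) / p$mu2, (p$B - x0)^2 / p$sigma2_sq)
  data.frame(s = s, x0 = x0, r = r)
}

#' Euler-Maruyama path oracle for (S, R)
#'
#' An independent, discretisation-based sampler used to cross-check the exact
#' sampler.  For each subject a renewal stream of first-passage intervals with
#' parameters \eqn{(\mu_1, \sigma_1^2)} is simulated step by step; an
#' intervention time is placed uniformly in a window far enough into the stream
#' for the age distribution to have equilibrated (length-biased interval
#' selection), and the interrupted path is then continued with
#' \eqn{(\mu_2, \sigma_2^2)} until it crosses the boundary.  Crossings are
#' detected at grid times, giving the well-known \eqn{O(\sqrt{dt})} upward
#' bias in crossing times; choose `dt` small against \eqn{E[T] = B/\mu_1}.
#' Truncation cannot occur in this construction: a crossing before the
#' intervention simply restarts the renewal interval, so every emitted pair has
#' `r > 0`.
#'
#' @inheritParams rfpt
#' @param dt time step; default \eqn{E[T] / 10^4}.  A warning is given if the
#'   per-step crossing drift `mu1 * dt` exceeds `B/2`.
#' @param equilibration number of mean interval lengths to let the stream run
#'   before the intervention window opens (default 10).
#' @return A data frame with columns `s`, `r`.
#' @export
rfpt_path <- function(n, p, dt = NULL, seed = NULL, equilibration = 10) {
  p <- as_params(p)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ET <- p$B / p$mu1
  dt <- dt %||% (ET / 1e4)
  if (dt <= 0) stop("dt must be > 0")
  if (p$mu1 * dt + 3 * sqrt(p$sigma1_sq * dt) > p$B / 2) {
    warning("dt is large relative to the crossing scale; expect severe bias")
  }
  sd1 <- sqrt(p$sigma1_sq * dt)
  sd2 <- sqrt(p$sigma2_sq * dt)
  block <- 2048L
  out_s <- numeric(n)
  out_r <- numeric(n)
  for (i in seq_len(n)) {
    u <- stats::runif(1, equilibration * ET, 2 * equilibration * ET)
    u_step <- ceiling(u / dt)
    # renewal stream with (mu1, sigma1) until the step count reaches u_step
    step0 <- 0L    # step at which the current interval started
    x <- 0
    step <- 0L
    x_at_u <- NA_real_
    repeat {
      inc <- stats::rnorm(block, p$mu1 * dt, sd1)
      path <- x + cumsum(inc)
      cross <- which(path >= p$B)
      hit <- if (length(cross)) cross[1] else NA_integer_
      if (!is.na(hit) && step + hit < u_step) {
        # interval completed before the intervention: restart
        step0 <- step + hit
        step <- step + hit
        # discard the rest of the block; fresh interval from 0
        x <- 0
        next
      }
      if (step + block >= u_step && (is.na(hit) || step + hit >= u_step)) {
        x_at_u <- path[u_step - step]
        step <- u_step
        break
      }
      step <- step + block
      x <- path[block]
    }
    out_s[i] <- (u_step - step0) * dt
    # continue with (mu2, sigma2) until crossing
    r_steps <- 0L
    x <- x_at_u
    repeat {
      inc <- stats::rnorm(block, p$mu2 * dt, sd2)
      path <- x + cumsum(inc)
      cross <- which(path >= p$B)
      if (length(cross)) {
        r_steps <- r_steps + cross[1]
        break
      }
      r_steps <- r_steps + block
      x <- path[block]
    }
    out_r[i] <- r_steps * dt
  }
  data.frame(s = out_s, r = out_r)
}
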
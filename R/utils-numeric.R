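# Internal numerics: log-space arithmetic, fixed-order Gauss-Legendre panels,
# cumulative trapezoids and a central-difference Hessian.  All density code in
# the package funnels exp(a) * pnorm(b) products through these helpers so that
# terms with a up to ~800 stay finite.

# log(exp(a) - exp(b)) for a >= b elementwise; -Inf where the difference
# underflows or is non-positive.
logspace_sub <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep(-Inf, n)
  ok <- is.finite(a) & b < a
  out[ok] <- a[ok] + log1p(-exp(b[ok] - a[ok]))
  out[is.nan(out)] <- -Inf
  out
}

logspace_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log of s1*exp(l1) + s2*exp(l2) with signs s1, s2 in {-1, 0, 1}.
# Returns -Inf where the sum is <= 0 (clamped; callers only use this where the
# exact quantity is a non-negative density).
signed_logspace_sum <- function(l1, s1, l2, s2) {
  m <- pmax(l1, l2)
  v <- s1 * exp(l1 - m) + s2 * exp(l2 - m)
  out <- ifelse(v > 0, m + log(v), -Inf)
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Cached Gauss-Legendre nodes/weights on [-1, 1].
gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n = 100L) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  gl_cache[[key]]
}

# Vectorised Gauss-Legendre integral of f over (0, upper_i) for a vector of
# upper limits.  `f` must accept (x, idx) where idx repeats the record index,
# and return values aligned with x.
gl_integral0 <- function(f, upper, n = 100L) {
  rule <- gl_rule(n)
  k <- length(rule$x)
  m <- length(upper)
  half <- upper / 2
  # nodes: m x k matrix flattened column-major
  x <- rep(half, times = k) * (1 + rep(rule$x, each = m))
  idx <- rep.int(seq_len(m), k)
  vals <- f(x, idx)
  w <- rep(rule$w, each = m)
  as.vector(rowsum(vals * w, idx)) * half
}

# Integral of f over (lower_i, Inf) via x = lower + t/(1-t) * scale_i.
gl_integral_tail <- function(f, lower, scale, n = 100L) {
  rule <- gl_rule(n)
  k <- length(rule$x)
  m <- length(lower)
  t <- (rule$x + 1) / 2           # in (0,1)
  w <- rule$w / 2
  tt <- rep(t, each = m)
  idx <- rep.int(seq_len(m), k)
  sc <- rep(scale, times = k)
  x <- rep(lower, times = k) + sc * tt / (1 - tt)
  jac <- sc / (1 - tt)^2
  vals <- f(x, idx) * jac
  as.vector(rowsum(vals * rep(w, each = m), idx))
}

# Adaptive quadrature over (0, Inf) through the substitution t = u/(1-u),
# used by the moment routines (spec'd relative tolerance 1e-9).
integrate_0inf <- function(f, rel.tol = 1e-9, scale = 1) {
  g <- function(u) {
    x <- scale * u / (1 - u)
    f(x) * scale / (1 - u)^2
  }
  stats::integrate(g, 0, 1, rel.tol = rel.tol, abs.tol = 0,
                   subdivisions = 400L, stop.on.error = FALSE)$value
}

# Central-difference Hessian with per-coordinate relative steps.  Step sizes
# trade truncation error (~h^2) against the ~1e-8 absolute noise floor of the
# quadrature-based likelihood terms.
num_hessian <- function(fn, x, rel_step = 1e-2, floor_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), floor_step)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Monotone numeric CDF on a grid by trapezoidal accumulation.
cumtrapz_cdf <- function(x, dens) {
  n <- length(x)
  inc <- c(0, diff(x) * (dens[-1] + dens[-n]) / 2)
  cummax(cumsum(inc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
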
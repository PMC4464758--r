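# Shared fixtures: the reference simulation scenario (CV(S) = 0.62,
# CV(R) approx 0.60) and small record builders.

tab1_params <- function() model_params(1, 0.4, 0.1, 0.026, B = 10)

complete_records <- function(n, p, seed) {
  d <- rfpt(n, p, seed = seed)
  data.frame(s = d$s, r = d$r, delta_l = 1L, delta_r = 1L, nu = 1L)
}

# adaptive quadrature over (0, Inf) used as an independent check
quad0inf <- function(f, scale = 1, rel.tol = 1e-9) {
  stats::integrate(function(u) {
    x <- scale * u / (1 - u)
    f(x) * scale / (1 - u)^2
  }, 0, 1, rel.tol = rel.tol, abs.tol = 0, subdivisions = 500L)$value
}
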
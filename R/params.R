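#' Model parameters for the perturbed Wiener process
#'
#' The latent process is a Brownian motion started at 0 with drift
#' \eqn{\mu_1 > 0} and squared diffusion coefficient \eqn{\sigma_1^2} up to the
#' intervention (time 0), and \eqn{(\mu_2, \sigma_2^2)} afterwards, absorbed at
#' the boundary \eqn{B > 0}.  Only two of \eqn{(x_0, B, \sigma)} are
#' identifiable from hitting times, so the start is fixed at 0 and \eqn{B} is a
#' user-chosen space scale: rescaling \eqn{B \to cB} together with
#' \eqn{\mu \to c\mu}, \eqn{\sigma^2 \to c^2\sigma^2} leaves the laws of
#' \eqn{S} and \eqn{R} unchanged.  The default `B = 10` is the scale used
#' throughout the package's simulation studies.
#'
#' @param mu1,mu2 drifts before/after the intervention (space units per time,
#'   `> 0`).
#' @param sigma1_sq,sigma2_sq squared diffusion coefficients before/after
#'   (space units squared per time, `> 0`).
#' @param B absorbing boundary (space units, `> 0`).
#' @return An object of class `fpt_params`.
#' @seealso [propvar_params()] for the proportional-variance submodel.
#' @examples
#' model_params(mu1 = 1, sigma1_sq = 0.4, mu2 = 0.1, sigma2_sq = 0.026)
#' @export
model_params <- function(mu1, sigma1_sq, mu2, sigma2_sq, B = 10) {
  vals <- c(mu1 = mu1, sigma1_sq = sigma1_sq, mu2 = mu2,
            sigma2_sq = sigma2_sq, B = B)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all of mu1, sigma1_sq, mu2, sigma2_sq, B must be finite and > 0")
  }
  structure(as.list(vals), class = "fpt_params")
}

#' Proportional-variance submodel parameters
#'
#' Fixes \eqn{\sigma_i^2 = k \mu_i} (a Weber's-law style scaling of noise with
#' signal strength), under which the joint density of \eqn{(S, R)} collapses to
#' an inverse Gaussian in \eqn{\mu_1 s + \mu_2 r}, and \eqn{CV(S) = CV(R)}
#' depends on \eqn{k} and \eqn{B} only.
#'
#' @param mu1,mu2 drifts before/after the intervention (`> 0`).
#' @param k proportionality constant (`> 0`).
#' @param B absorbing boundary (`> 0`).
#' @return An object of class `fpt_propvar` (also inherits the full
#'   parameterisation via [as_model_params()]).
#' @examples
#' q <- propvar_params(mu1 = 1, mu2 = 2, k = 0.5)
#' propvar_summaries(q)
#' @export
propvar_params <- function(mu1, mu2, k, B = 10) {
  vals <- c(mu1 = mu1, mu2 = mu2, k = k, B = B)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all of mu1, mu2, k, B must be finite and > 0")
  }
  structure(as.list(vals), class = "fpt_propvar")
}

#' Expand proportional-variance parameters to the full parameterisation
#'
#' @param q an `fpt_propvar` object.
#' @return The equivalent `fpt_params` with `sigma_i_sq = k * mu_i`.
#' @export
as_model_params <- function(q) {
  stopifnot(inherits(q, "fpt_propvar"))
  model_params(mu1 = q$mu1, sigma1_sq = q$k * q$mu1,
               mu2 = q$mu2, sigma2_sq = q$k * q$mu2, B = q$B)
}

#' @export
print.fpt_params <- function(x, ...) {
  cat("Perturbed Wiener model parameters\n")
  cat(sprintf("  pre-intervention : mu1 = %g, sigma1^2 = %g\n",
              x$mu1, x$sigma1_sq))
  cat(sprintf("  post-intervention: mu2 = %g, sigma2^2 = %g\n",
              x$mu2, x$sigma2_sq))
  cat(sprintf("  boundary B = %g (x0 = 0)\n", x$B))
  invisible(x)
}

#' @export
print.fpt_propvar <- function(x, ...) {
  cat("Proportional-variance Wiener model (sigma_i^2 = k mu_i)\n")
  cat(sprintf("  mu1 = %g, mu2 = %g, k = %g, B = %g\n",
              x$mu1, x$mu2, x$k, x$B))
  invisible(x)
}

as_params <- function(p) {
  if (inherits(p, "fpt_propvar")) as_model_params(p)
  else if (inherits(p, "fpt_params")) p
  else stop("expected an fpt_params or fpt_propvar object")
}
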
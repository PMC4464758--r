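# Observation schemes: independent right/left censoring and truncation
# (an event before the intervention), applied to latent (S, R) pairs.

spec_to_sampler <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    if (!is.finite(x) || x <= 0) {
      stop(sprintf("%s rate must be a finite positive number", what))
    }
    rate <- x
    return(function(n) stats::rexp(n, rate))
  }
  stop(sprintf("%s must be NULL, a positive exponential rate, or function(n)",
               what))
}

#' Censoring and truncation scheme
#'
#' Describes how latent `(S, R)` pairs are turned into observed records.
#' Censoring is independent of the latent process.  Each of `right`, `left`
#' and `truncation` may be `NULL` (absent), a single positive number (the rate
#' of an exponential censoring/exposure time), or a `function(n)` returning
#' `n` strictly positive draws.
#'
#' Truncation is generated from the study design rather than from the renewal
#' stream: a fresh unperturbed crossing time `T ~ IG(B/mu1, B^2/sigma1^2)` is
#' drawn together with an independent exposure window `E` (the planned
#' start-to-intervention time); the subject is truncated when `T < E`, in
#' which case the event precedes the intervention, `r` is set to 0 and the
#' right-censoring indicator to 1.
#'
#' @param right,left right/left censoring time specification.
#' @param truncation exposure-window specification enabling truncation.
#' @return An object of class `fpt_scheme`.
#' @examples
#' censoring_scheme(right = 0.01)
#' @export
censoring_scheme <- function(right = NULL, left = NULL, truncation = NULL) {
  structure(list(right = spec_to_sampler(right, "right censoring"),
                 left = spec_to_sampler(left, "left censoring"),
                 truncation = spec_to_sampler(truncation, "truncation exposure")),
            class = "fpt_scheme")
}

check_censor_times <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s times must be finite and strictly positive", what))
  }
  x
}

#' Apply an observation scheme to latent pairs
#'
#' Turns latent `(s, r)` pairs (from [rfpt()] or [rfpt_path()]) into records
#' `(s, r, delta_l, delta_r, nu)`.  `delta_l`/`delta_r` are 1 when the
#' corresponding time is fully observed, 0 under censoring; `nu` is 0 under
#' truncation, in which case `r = 0` and `delta_r = 1` by convention.  For a
#' truncated subject whose study entry falls after the process start
#' (`C^l < T`), the recorded time is the span from entry to the event and the
#' record is additionally left censored; if the drawn event would precede
#' study entry entirely, the subject is kept as an uncensored truncation
#' (generator convention).
#'
#' @param pairs data frame with columns `s`, `r`.
#' @param scheme an [censoring_scheme()] object.
#' @param p model parameters (needed to draw truncation crossing times).
#' @param seed optional integer seed.
#' @return A data frame with columns `s`, `r`, `delta_l`, `delta_r`, `nu`.
#' @export
apply_scheme <- function(pairs, scheme, p, seed = NULL) {
  stopifnot(inherits(scheme, "fpt_scheme"),
            all(c("s", "r") %in% names(pairs)))
  p <- as_params(p)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pairs)
  out <- data.frame(s = pairs$s, r = pairs$r,
                    delta_l = 1L, delta_r = 1L, nu = 1L)

  if (!is.null(scheme$truncation)) {
    Tdraw <- rinvgauss(n, p$B / p$mu1, p$B^2 / p$sigma1_sq)
    expo <- check_censor_times(scheme$truncation(n), "truncation exposure")
    tr <- Tdraw < expo
    out$nu[tr] <- 0L
    out$s[tr] <- Tdraw[tr]
    out$r[tr] <- 0
    out$delta_r[tr] <- 1L
    attr(out, "exposure") <- expo
    attr(out, "T_latent") <- Tdraw
  }

  if (!is.null(scheme$left)) {
    cl <- check_censor_times(scheme$left(n), "left censoring")
    ntr <- out$nu == 1L
    lc <- ntr & out$s > cl
    out$delta_l[lc] <- 0L
    out$s[lc] <- cl[lc]
    if (!is.null(scheme$truncation)) {
      # truncated + left censored: entry-to-event span, when entry precedes it
      expo <- attr(out, "exposure")
      tr <- out$nu == 0L
      span <- out$s - (expo - cl)      # T - (E - C^l)
      tl <- tr & cl < out$s & span > 0
      out$delta_l[tl] <- 0L
      out$s[tl] <- span[tl]
    }
  }

  if (!is.null(scheme$right)) {
    cr <- check_censor_times(scheme$right(n), "right censoring")
    ntr <- out$nu == 1L
    rc <- ntr & out$r > cr
    out$delta_r[rc] <- 0L
    out$r[rc] <- cr[rc]
  }
  attr(out, "exposure") <- NULL
  attr(out, "T_latent") <- NULL
  out
}

#' Calibrate an exponential right-censoring rate to a target fraction
#'
#' Simulates residual times from the model and solves for the exponential rate
#' under which the expected right-censored fraction matches `target`.
#'
#' @param p model parameters.
#' @param target desired fraction of right-censored records, in (0, 1).
#' @param n Monte Carlo sample size used for calibration.
#' @param seed optional integer seed.
#' @return The exponential rate.
#' @export
calibrate_right_censoring <- function(p, target, n = 1e4, seed = NULL) {
  stopifnot(target > 0, target < 1)
  p <- as_params(p)
  r <- rfpt(n, p, seed = seed)$r
  frac <- function(lrate) mean(1 - exp(-exp(lrate) * r)) - target
  lo <- log(1e-8 / stats::median(r)); hi <- log(1e4 / stats::median(r))
  exp(stats::uniroot(frac, lower = lo, upper = hi, tol = 1e-10)$root)
}
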
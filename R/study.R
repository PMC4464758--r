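# Simulation-study harness: repeated simulate -> fit -> aggregate runs
# (parameter recovery, censoring sweeps, joint-vs-marginal efficiency,
# type-I error of the drift-equality LRT).

#' Simulation scenario
#'
#' @param p model parameters ([model_params()] or [propvar_params()]).
#' @param n subjects per replicate.
#' @param reps number of replicates (the full-scale study uses 1000).
#' @param scheme an [censoring_scheme()] or `NULL` for complete data.
#' @param variance_mode variance structure assumed by the fitted model.
#' @param seed integer; replicate `j` uses seed `seed + j`.
#' @return A list of class `fpt_scenario`.
#' @export
fpt_scenario <- function(p, n = 100, reps = 1000, scheme = NULL,
                         variance_mode = "free", seed = 1) {
  stopifnot(reps >= 1, n >= 1)
  structure(list(p = p, n = n, reps = reps, scheme = scheme,
                 variance_mode = variance_mode, seed = as.integer(seed)),
            class = "fpt_scenario")
}

true_param_vector <- function(p, variance_mode) {
  if (inherits(p, "fpt_propvar")) {
    stopifnot(variance_mode == "propvar")
    return(c("(Intercept)" = p$mu1, "post:(Intercept)" = p$mu2 - p$mu1,
             k = p$k))
  }
  switch(variance_mode,
         free = c("(Intercept)" = p$mu1, "post:(Intercept)" = p$mu2 - p$mu1,
                  sigma1_sq = p$sigma1_sq, sigma2_sq = p$sigma2_sq),
         equal = c("(Intercept)" = p$mu1, "post:(Intercept)" = p$mu2 - p$mu1,
                   sigma_sq = p$sigma1_sq),
         stop("variance_mode must match the parameter object"))
}

# Natural-scale truth on the reporting scale used in the tables:
# (mu1, sigma1_sq, mu2, sigma2_sq)-style, derived from the beta params.
reported_estimates <- function(fit) {
  est <- fit$coefficients; se <- fit$se
  mu1 <- est[1]; mu2 <- est[1] + if (fit$m > 0) est[2] else 0
  i2 <- if (fit$m > 0) 2L else 1L
  v12 <- if (fit$m > 0) fit$vcov[1, 2] else 0
  se_mu2 <- sqrt(fit$vcov[1, 1] + (if (fit$m > 0) fit$vcov[2, 2] else 0) +
                   2 * v12)
  vn <- variance_names(fit$variance_mode)
  out_est <- c(mu1 = unname(mu1), mu2 = unname(mu2),
               stats::setNames(est[fit$n_beta + seq_along(vn)], vn))
  out_se <- c(mu1 = unname(se[1]), mu2 = unname(se_mu2),
              stats::setNames(se[fit$n_beta + seq_along(vn)], vn))
  list(est = out_est, se = out_se)
}

reported_truth <- function(p, variance_mode) {
  if (inherits(p, "fpt_propvar")) {
    return(c(mu1 = p$mu1, mu2 = p$mu2, k = p$k))
  }
  switch(variance_mode,
         free = c(mu1 = p$mu1, mu2 = p$mu2, sigma1_sq = p$sigma1_sq,
                  sigma2_sq = p$sigma2_sq),
         equal = c(mu1 = p$mu1, mu2 = p$mu2, sigma_sq = p$sigma1_sq))
}

#' Parameter-recovery simulation study
#'
#' Runs `reps` replicates of simulate (exact sampler + optional observation
#' scheme) -> fit -> collect, and aggregates per parameter: mean estimate,
#' empirical SE, median asymptotic SE, and the coverage of the nominal-95%
#' Wald intervals, in percent.  Replicates whose fit fails to converge (or
#' errors) are excluded and counted.
#'
#' @param scenario an [fpt_scenario()].
#' @param restarts optimisation starts per replicate (a cheap
#'   moment-initialised single start is reliable for complete data).
#' @return An object of class `fpt_study`: a data frame of per-parameter
#'   summaries with attributes `n_failed` and `reps`.
#' @examples
#' sc <- fpt_scenario(model_params(1, 0.4, 0.1, 0.026), n = 50, reps = 5)
#' run_table1(sc)
#' @export
run_table1 <- function(scenario, restarts = 1) {
  stopifnot(inherits(scenario, "fpt_scenario"))
  p <- scenario$p
  truth <- reported_truth(p, scenario$variance_mode)
  est <- se <- matrix(NA_real_, scenario$reps, length(truth),
                      dimnames = list(NULL, names(truth)))
  failed <- 0L
  for (j in seq_len(scenario$reps)) {
    dat <- rfpt(scenario$n, p, seed = scenario$seed + j)
    dat <- if (is.null(scenario$scheme)) {
      data.frame(s = dat$s, r = dat$r, delta_l = 1L, delta_r = 1L, nu = 1L)
    } else {
      apply_scheme(dat[c("s", "r")], scenario$scheme, p)
    }
    fit <- tryCatch(
      fpt_fit(dat, variance_mode = scenario$variance_mode, B = p$B,
              restarts = restarts, seed = scenario$seed + j),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$se)) {
      failed <- failed + 1L
      next
    }
    rep_j <- reported_estimates(fit)
    est[j, ] <- rep_j$est[names(truth)]
    se[j, ] <- rep_j$se[names(truth)]
  }
  ok <- stats::complete.cases(est)
  est <- est[ok, , drop = FALSE]; se <- se[ok, , drop = FALSE]
  cover <- 100 * colMeans(abs(est - rep(truth, each = nrow(est))) <=
                            1.96 * se)
  out <- data.frame(parameter = names(truth), truth = unname(truth),
                    average = colMeans(est),
                    empirical_se = apply(est, 2, stats::sd),
                    asymptotic_se = apply(se, 2, stats::median),
                    coverage_pct = unname(cover), row.names = NULL)
  structure(out, class = c("fpt_study", "data.frame"),
            n_failed = failed, reps = scenario$reps, n = scenario$n)
}

#' @export
print.fpt_study <- function(x, digits = 4, ...) {
  cat(sprintf("Simulation study: %d replicates (n = %d per replicate), %d excluded\n",
              attr(x, "reps"), attr(x, "n") %||% NA_integer_,
              attr(x, "n_failed")))
  print.data.frame(round_df(x), digits = digits, row.names = FALSE)
  invisible(x)
}

round_df <- function(x) {
  x[] <- lapply(x, function(col) if (is.numeric(col)) signif(col, 5) else col)
  x
}

#' Effect of right censoring on estimation
#'
#' Sweeps a grid of target right-censoring fractions; for each fraction an
#' exponential censoring rate is calibrated by simulation and a
#' [run_table1()]-style study is run.  A fraction of 0 reproduces the
#' complete-data study exactly (same seeds).
#'
#' @param scenario base [fpt_scenario()] (its `scheme` is ignored).
#' @param fractions numeric vector of target right-censoring fractions.
#' @inheritParams run_table1
#' @return A data frame of per-parameter summaries stacked over fractions.
#' @export
run_censoring_study <- function(scenario, fractions = c(0, 0.2, 0.4),
                                restarts = 1) {
  out <- lapply(fractions, function(fr) {
    sch <- if (fr == 0) NULL else {
      rate <- calibrate_right_censoring(scenario$p, fr,
                                        seed = scenario$seed)
      censoring_scheme(right = rate)
    }
    sc <- scenario
    sc$scheme <- sch
    res <- run_table1(sc, restarts = restarts)
    cbind(censor_fraction = fr, as.data.frame(res),
          n_failed = attr(res, "n_failed"))
  })
  do.call(rbind, out)
}

#' Efficiency of the joint likelihood over the S-only likelihood
#'
#' For each value of `mu2`, simulates complete data and fits both the joint
#' `(S, R)` likelihood and the marginal S-only likelihood, recording the
#' empirical and median asymptotic SEs of the pre-intervention parameters.
#'
#' @param mu2_grid post-intervention drifts to sweep.
#' @param mu1,sigma1_sq,sigma2_sq,B remaining parameters.
#' @param n,reps,seed replicate design.
#' @return A data frame with one row per `mu2`, with empirical/asymptotic SEs
#'   of `mu1` under both objectives.
#' @export
run_efficiency_study <- function(mu2_grid = c(0.5, 1, 2), mu1 = 1,
                                 sigma1_sq = 0.4, sigma2_sq = 0.1, B = 10,
                                 n = 100, reps = 200, seed = 1) {
  rows <- lapply(mu2_grid, function(mu2) {
    p <- model_params(mu1, sigma1_sq, mu2, sigma2_sq, B)
    est_j <- se_j <- est_s <- se_s <- rep(NA_real_, reps)
    for (j in seq_len(reps)) {
      d <- rfpt(n, p, seed = seed + j)
      dat <- data.frame(s = d$s, r = d$r, delta_l = 1L, delta_r = 1L, nu = 1L)
      fj <- tryCatch(fpt_fit(dat, B = B, restarts = 1, seed = seed + j),
                     error = function(e) NULL)
      fs <- tryCatch(fpt_fit_s(dat, B = B, restarts = 1, seed = seed + j),
                     error = function(e) NULL)
      if (!is.null(fj) && fj$converged) {
        est_j[j] <- fj$coefficients[1]; se_j[j] <- fj$se[1]
      }
      if (!is.null(fs) && fs$converged) {
        est_s[j] <- fs$coefficients[1]; se_s[j] <- fs$se[1]
      }
    }
    data.frame(mu2 = mu2,
               mean_mu1_joint = mean(est_j, na.rm = TRUE),
               mean_mu1_sonly = mean(est_s, na.rm = TRUE),
               emp_se_joint = stats::sd(est_j, na.rm = TRUE),
               emp_se_sonly = stats::sd(est_s, na.rm = TRUE),
               asym_se_joint = stats::median(se_j, na.rm = TRUE),
               asym_se_sonly = stats::median(se_s, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Type-I error of the drift-equality likelihood ratio test
#'
#' Simulates under `mu1 = mu2` with equal variances, fits the null
#' (`post = ~0`) and full (`post = ~1`) equal-variance models, and returns the
#' fraction of replicates rejecting `H0: mu1 = mu2` at the 5% level.
#'
#' @param mu,sigma_sq,B parameters of the null model.
#' @param n,reps,seed replicate design.
#' @return A list with `rejection_rate`, `reps_used` and the vector of
#'   p-values.
#' @export
run_lrt_study <- function(mu = 1, sigma_sq = 0.4, B = 10, n = 100,
                          reps = 200, seed = 1) {
  p <- model_params(mu, sigma_sq, mu, sigma_sq, B)
  pvals <- rep(NA_real_, reps)
  for (j in seq_len(reps)) {
    d <- rfpt(n, p, seed = seed + j)
    dat <- data.frame(s = d$s, r = d$r, delta_l = 1L, delta_r = 1L, nu = 1L)
    full <- tryCatch(fpt_fit(dat, post = ~1, variance_mode = "equal", B = B,
                             restarts = 1, seed = seed + j),
                     error = function(e) NULL)
    null <- tryCatch(fpt_fit(dat, post = ~0, variance_mode = "equal", B = B,
                             restarts = 1, seed = seed + j),
                     error = function(e) NULL)
    if (is.null(full) || is.null(null) || !full$converged || !null$converged)
      next
    pvals[j] <- fpt_lrt(full, null)$p_value
  }
  ok <- !is.na(pvals)
  list(rejection_rate = mean(pvals[ok] < 0.05), reps_used = sum(ok),
       p_values = pvals)
}
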
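#' Generate synthetic datasets emulating each analysis input
#'
#' Seeded generators for the data shapes the package consumes:
#' `"table1-row"` gives complete records from the reference simulation
#' scenario; `"censored"` adds calibrated ~20% exponential right censoring;
#' `"truncated"` adds an exposure-window truncation mechanism; and
#' `"veteran-like"` produces a synthetic table in the veteran column layout
#' (137 rows, 9 right censored) for exercising [analyze_veteran()] without
#' the real data.  The same `kind` and `seed` always give identical output.
#'
#' @param kind one of `"table1-row"`, `"veteran-like"`, `"censored"`,
#'   `"truncated"`.
#' @param seed integer seed.
#' @param n number of records (ignored for `"veteran-like"`, fixed at 137).
#' @param path optional file path; if given, the data are written as
#'   tab-delimited text with a header.
#' @return The generated data frame (invisibly if `path` is given).
#' @examples
#' head(generate_fixture("table1-row", seed = 1, n = 20))
#' @export
generate_fixture <- function(kind = c("table1-row", "veteran-like",
                                      "censored", "truncated"),
                             seed = 1, n = 100, path = NULL) {
  kind <- match.arg(kind)
  p <- model_params(1, 0.4, 0.1, 0.026)
  out <- switch(
    kind,
    "table1-row" = {
      d <- rfpt(n, p, seed = seed)
      data.frame(s = d$s, r = d$r, delta_l = 1L, delta_r = 1L, nu = 1L)
    },
    "censored" = {
      rate <- calibrate_right_censoring(p, 0.2, n = 5000, seed = seed)
      pairs <- rfpt(n, p, seed = seed + 1)
      apply_scheme(pairs[c("s", "r")], censoring_scheme(right = rate), p,
                   seed = seed + 2)
    },
    "truncated" = {
      pairs <- rfpt(n, p, seed = seed + 1)
      # exposure comparable to E[T] so a visible fraction is truncated
      apply_scheme(pairs[c("s", "r")],
                   censoring_scheme(truncation = p$mu1 / p$B), p,
                   seed = seed + 2)
    },
    "veteran-like" = {
      set.seed(seed)
      n <- 137L
      celltype <- factor(sample(c("squamous", "smallcell", "adeno", "large"),
                                n, replace = TRUE),
                         levels = c("squamous", "smallcell", "adeno", "large"))
      age <- round(stats::runif(n, 35, 80))
      prior <- sample(c(0, 10), n, replace = TRUE, prob = c(0.7, 0.3))
      karno <- round(stats::runif(n, 10, 99) / 10) * 10
      trt <- sample(1:2, n, replace = TRUE)
      level <- c(squamous = 0.028, smallcell = 0.038, adeno = 0.052,
                 large = 0.035)[as.character(celltype)]
      mu1 <- level + 1e-4 * age - 0.0146 * (prior > 0)
      mu2 <- mu1 + 0.0014 * (100 - karno) - 0.022 * (trt == 2) -
        0.028 * (trt == 1)
      mu2 <- pmax(mu2, 5e-3)
      sig <- 0.215
      B <- 10
      s <- r <- numeric(n)
      for (i in seq_len(n)) {
        pi <- model_params(mu1[i], sig, mu2[i], sig, B)
        di <- rfpt(1, pi)
        s[i] <- di$s; r[i] <- di$r
      }
      status <- rep(1L, n)
      cens <- sample.int(n, 9)
      status[cens] <- 0L
      r[cens] <- r[cens] * stats::runif(9)
      data.frame(trt = trt, celltype = celltype,
                 time = round(pmax(r, 1)), status = status, karno = karno,
                 diagtime = pmax(round(s / 30.4), 1), age = age,
                 prior = prior)
    })
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
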
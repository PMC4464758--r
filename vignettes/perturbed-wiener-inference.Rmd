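---
title: "Inference for a Wiener process perturbed at an intervention time"
author: "fptwiener"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for a Wiener process perturbed at an intervention time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fptwiener)
```

## The model

A latent risk or degradation process $X(t)$ is a Brownian motion started at
$x_0 = 0$ with drift $\mu_1 > 0$ and squared diffusion coefficient
$\sigma_1^2$, absorbed at a boundary $B > 0$.  At an intervention time that is
independent of the process, the parameters switch to $(\mu_2, \sigma_2^2)$.
Per subject we observe only two durations: the *backward recurrence time* $S$
from the start of the process to the intervention, and the *residual time*
$R$ from the intervention to the first boundary crossing.  The position
$X(0)$ at the intervention is never observed, which is what makes $S$ and $R$
dependent and the inference problem non-standard.

Were there no intervention, the crossing time $T$ would be inverse Gaussian,
$T \sim IG(B/\mu_1,\, B^2/\sigma_1^2)$.  Stationary point-process theory
gives $S$ the length-biased law $f_S(s) = \bar F_T(s) / E[T]$, the absorbed
position at the intervention an image-method sub-density, and $R \mid X(0)=x$
the first-passage law $IG((B-x)/\mu_2, (B-x)^2/\sigma_2^2)$.  Mixing these
yields closed forms for the marginal of $R$ and the joint density of
$(S, R)$; all of them are implemented in `dfpt_s()`, `dfpt_x0a()`,
`dfpt_x0()`, `dfpt_r()` and `dfpt_sr()`, each with a log form.

Only two of $(x_0, B, \sigma)$ are identifiable from hitting times, so $x_0$
is fixed at 0 and $B$ is a user-chosen space unit: replacing $B$ by $cB$
while mapping $\mu \mapsto c\mu$, $\sigma^2 \mapsto c^2\sigma^2$ leaves the
laws of $S$ and $R$ — and hence likelihood differences, test statistics and
residuals — untouched.  The package default is $B = 10$, the scale on which
the reference simulation scenario
$(\mu_1, \sigma_1^2, \mu_2, \sigma_2^2) = (1, 0.4, 0.1, 0.026)$ produces
$CV(S) = 0.62$ and $CV(R) \approx 0.60$:

```{r cv}
p <- model_params(1, 0.4, 0.1, 0.026, B = 10)
moments_s(p)$cv
moments_r(p)$cv
```

### The proportional-variance submodel

Weber's-law reasoning (noise scales with signal strength) motivates
$\sigma_i^2 = k \mu_i$.  Under this restriction the joint density collapses
to an inverse Gaussian in $\mu_1 s + \mu_2 r$, $CV(S) = CV(R)$ depends only
on $k$ and $B$, and $\mathrm{Corr}(S, R) = (3k^2 - B^2)/(B + 3k)^2$ changes
sign at $k = B/\sqrt 3$ (`propvar_params()`, `propvar_summaries()`).

## Numerical design

* **Stiff exponentials.**  Every density contains products
  $\exp(a)\,\Phi(z)$ with $a = 2\mu_1 B/\sigma_1^2$ potentially in the
  hundreds.  All such products are evaluated as
  $\exp\{a + \log\Phi(z)\}$ with `pnorm(..., log.p = TRUE)`, and signed
  sums of such terms are combined in log space.  The densities are finite
  (in log form) for $a$ at least up to 800.
* **Quadrature.**  Moments with no closed form (`moments_r()`) use adaptive
  quadrature on the transformed domain $t = u/(1-u)$ with relative tolerance
  $10^{-9}$.  The censoring integrals inside the likelihood use fixed-order
  Gauss–Legendre panels (100 nodes, `pracma::gaussLegendre`), which are
  vectorised across subjects and — unlike adaptive rules — are smooth in the
  parameters, so the numerical Hessian is not polluted by adaptivity noise.
  Right-censored contributions are computed as
  $f_S(s_i) - \int_0^{r_i} f_{(S,R)}(s_i, r)\,dr$, reusing the closed
  marginal; when that subtraction would cancel (survival below $10^{-6}$ of
  $f_S$) the tail integral is recomputed directly on a transformed
  semi-infinite domain.
* **Sampling.**  $S$ is drawn by inverting a tabulated CDF (8192 log-spaced
  points up to the $1 - 10^{-8}$ quantile, monotone interpolation), because
  $f_S$ has no closed inverse.  $X(0) \mid S = s$ uses rejection with a
  *boundary-truncated* Gaussian proposal and acceptance probability
  $1 - \exp\{-2B(B - x)/(\sigma_1^2 s)\}$; this is exact and has $O(1)$
  acceptance uniformly in $s$.  (A free-Gaussian envelope, though also exact,
  has acceptance rate $P(T > s)$ and stalls for $s$ far beyond $E[T]$ —
  the truncated proposal is the same construction with the hopeless region
  removed.)  $R \mid X(0)$ and all other IG draws use the
  Michael–Schucany–Haas transformation.  No IG distribution functions were
  available among the installed packages, so `dinvgauss()`/`pinvgauss()`/
  `qinvgauss()`/`rinvgauss()` are provided in-package.
* **Degenerate inputs.**  `dfpt_x0a()` is 0 at and above the boundary;
  densities error on non-positive times; truncated records must carry
  `r = 0`, `delta_r = 1`.

## Censoring, truncation and the likelihood

Records are $(s_i, r_i, \delta^l_i, \delta^r_i, \nu_i)$: left/right
censoring indicators (1 = fully observed) and a truncation indicator
($\nu_i = 0$ when the crossing happened *before* the intervention, in which
case $R$ is undefined and set to 0).  The log-likelihood (`fpt_loglik()`)
sums six contribution types: the joint density for complete records;
$\int_0^{s_i}$, $\int_{r_i}^\infty$ and the double integral for the censored
patterns; and the IG density/CDF of the unperturbed crossing time for
truncated records.  A truncation-with-right-censoring cross term cannot
arise: $\nu_i = 0$ forces $\delta^r_i = 1$, and the record validator enforces
this rather than adding a term.

Covariates act linearly on the drifts: $\mu_{1i} = x_i^{\mathrm{pre}}\beta$,
and the post-intervention drift adds *change* terms,
$\mu_{2i} = \mu_{1i} + x_i^{\mathrm{post}}\gamma$ — so a treatment
coefficient is directly the shift relative to the subject's own untreated
drift, the comparison that usually requires a placebo arm.  The truncated
terms use the subject-specific $\mu_{1i}$.  Three variance structures are
supported: free $(\sigma_1^2, \sigma_2^2)$, equal $\sigma^2$, and
proportional $k$ (where $\sigma^2_{ji} = k\mu_{ji}$ varies with the subject).

Any parameter point giving a subject a drift below $10^{-10}$ returns a
$-10^{10}$ sentinel (with a slope back towards feasibility), which keeps
unconstrained optimisers in bounds without hard failures.

## Fitting

`fpt_fit()` maximises the likelihood with `nlminb` (PORT), variances on the
log scale, and per-coordinate scaling $\sim 1/|\theta|$ — coefficient
magnitudes span several orders when covariates mix indicators with ages or
performance scores, and unscaled quasi-Newton steps stall in the small
coordinates.  Initialisation is method-of-moments: for intercept-only models,
$E[S] = (B\mu_1 + \sigma_1^2)/(2\mu_1^2)$ and its variance partner invert to
$\mu_1 = B/(3\bar s - \sqrt 3\, \mathrm{sd}(s))$,
$\sigma_1^2 = \mu_1^2(\sqrt 3\, \mathrm{sd}(s) - \bar s)$, with the mirrored
expressions on the $r$-sample for $(\mu_2, \sigma_2^2)$.  With covariates,
crude per-subject drifts $\tilde\mu_{1i} = B/(2 s_i)$ and
$\tilde\mu_{2i} = (B/2)/r_i$ (the small-variance approximations, winsorised
at the 5th percentile) are regressed on the designs — this matters because
between-subject drift heterogeneity inflates the marginal CV, and a
constant-drift start then sits in the basin of a spurious large-variance
optimum.  Multi-start keeps the best of: the moment start, a deterministic
$0.1\times$-variance start (the moment variance is biased upward under
heterogeneity), and seeded multiplicative jitters $\times U(0.5, 2)$; if a
start is infeasible the change coefficients are halved until the drifts are
admissible, and a BFGS polish clears spurious non-convergence exits.

Standard errors come from the observed information — the central-difference
Hessian (relative steps $10^{-2}$, balancing truncation error against the
$\sim 10^{-8}$ noise floor of the quadrature terms) of the negative
log-likelihood at the optimum, on the natural parameter scale — in place of
the expected Fisher information; 95% intervals are
$\hat\phi \pm 1.96\,\mathrm{SE}$.  `fpt_lrt()` computes
$-2\log(L_0/L_{\mathrm{full}})$ against $\chi^2_m$; `fpt_fit_s()` maximises
the S-only marginal likelihood for efficiency comparisons.

Model checking uses uniform residuals: for each fully observed subject,
$u_i = P(R < r_i \mid S = s_i, \text{covariates})$ at the fitted parameters,
standard uniform under a correct model.  The conditional (on $s_i$) rather
than marginal probability is used because it is the checkable statement when
each subject has its own covariates and an observed $s_i$; right-censored
and truncated subjects are excluded and counted.

## What the generators emulate — and what they do not

`rfpt()` draws i.i.d. $(S, X(0), R)$ triples exactly from the stationary
model: subjects whose intervention falls into a typical realisation of the
renewal stream.  `censoring_scheme()`/`apply_scheme()` add independent
exponential (or user-supplied) censoring, and generate truncation from a
study-design construction: a fresh crossing time $T \sim IG$ against an
independent exposure window, truncating when $T < E$.  The renewal stream
itself can never produce truncation (a crossing before the intervention
restarts the interval — confirmed by the path oracle emitting only $r > 0$),
so truncation frequency is governed by the exposure distribution, which the
likelihood never needs to know under independent censoring.  For a truncated
subject whose study entry falls after the process start the recorded time is
the entry-to-event span; if the drawn event would precede entry entirely the
subject is kept as an uncensored truncation — one convention among several
the observation rules leave open.

`rfpt_path()` is a deliberately independent cross-check: an Euler–Maruyama
renewal stream with a uniformly placed intervention (after ten mean
intervals of equilibration), continued with the post-intervention parameters
until crossing.  Crossings are detected at grid times, giving the standard
$O(\sqrt{dt})$ upward bias; with the default $dt = E[T]/10^4$ this bias is
far below Monte Carlo error at the sample sizes used in the tests
($n \le 2000$, where tests use $dt = E[T]/2000$ for speed).

What the synthetic data do *not* emulate: dependence between the
intervention time and the process (assumed independent), time-varying
covariates, dependent censoring, and — in the veteran-like fixture — the
empirical covariate joint distribution of the real trial (covariates are
drawn independently).  Passing tests therefore validate the estimators under
the model's own assumptions, not robustness to their violation.

## Study harnesses and problem sizes

`run_table1()` reproduces the reference recovery study
(simulate → fit → aggregate; asymptotic SEs summarised by the median across
replicates, matching how the reference table is described).  The package's
tests run it at 200 replicates of $n = 100$, which takes well under a minute
and pins the averages to within 3 Monte Carlo SEs of the published
1000-replicate values; the full 1000-replicate run is a few minutes on one
core.  `run_lrt_study()` (type-I error of the drift-equality LRT, checked at
200 replicates against a 99% binomial band around 5%),
`run_efficiency_study()` (joint vs S-only SEs across a $\mu_2$ grid of
$\{0.5, 1, 2\}$ at 200 replicates), and `run_censoring_study()` (calibrated
exponential right censoring at 0/20/40%) follow the same pattern.  These
replicate counts are the package's test-scale defaults: large enough that
every qualitative conclusion and every 3-MC-SE band is stable under the
fixed seeds, small enough to keep the whole suite in a coffee break.

## The veteran analysis

`analyze_veteran()` reproduces the lung-cancer trial analysis: disease
duration (months $\times$ 30.4 → days) as $S$, survival time (days) as $R$
with 9 of 137 subjects right censored, equal variances, $B = 10$.  The
pre-intervention drift is parametrised by absolute cell-type levels (no
intercept), age and prior therapy ($p = 6$); the post-intervention changes
are $100 - \mathrm{karno}$ (so larger = sicker; performance status is
measured *at* randomisation and therefore cannot influence $\mu_1$, a
choice the data themselves support) and the two treatment arms as changes
relative to no treatment ($m = 3$).  Prior therapy is recoded 0/1 from the
source table's 0/10 — the published coefficient scale is only consistent
with 0/1 coding.  Nested fits for the test table are warm-started from the
full-model coefficients.  Because deaths before randomisation are
unrecorded, truncation cannot be corrected for, and the report prints the
resulting caveat: $\hat\mu_1$ (and the cell-type levels) are expected to be
biased downward, making the estimated treatment effects conservative.

The per-covariate $\chi^2$ statistics in the reference report do not state
whether they are Wald or likelihood-ratio values; the package reports LRTs
(consistent with how the drift-equality test is described) and the Wald
statistics alongside.  For these data the two agree closely for the
decisive covariates.

## Known limitations

* Interval censoring, frailty/random effects, Bayesian and bootstrap
  inference are out of scope; asymptotic Wald intervals are known to
  under-cover for the diffusion variances at $n = 100$.
* The S-only fit ignores censoring and truncation (it is an efficiency
  benchmark, not an analysis tool).
* The exposure-window truncation generator is one plausible study design;
  the likelihood is agnostic to it, but simulated truncation *rates* depend
  on the chosen exposure law.
* Non-Wiener diffusions (e.g. mean-reverting processes) are not supported;
  the numeric composition used in the tests would, however, extend to any
  process with computable absorbed densities.
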
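Package: fptwiener
Title: First-Passage-Time Inference for a Wiener Process Perturbed at an
    Intervention Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood inference for a latent Brownian motion whose
    drift and diffusion coefficient change at an externally timed intervention,
    observed only through the backward recurrence time S (process start to
    intervention) and the residual time R (intervention to first boundary
    crossing).  Provides closed-form densities and moments for S, the process
    position at intervention, R and the joint law of (S, R); exact and
    path-based samplers; a censored/truncated log-likelihood with linear
    covariate effects on the drifts; asymptotic standard errors, likelihood
    ratio tests and uniform-residual model checks; and a simulation-study
    harness together with an analysis of the Veterans' Administration lung
    cancer trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
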
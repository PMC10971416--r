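Package: cbtmech
Title: Hierarchical Bayesian Analysis of Cognitive Mechanisms of Brief
    Psychotherapy Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing randomized experiments on cognitive
    mechanisms of cognitive-behavioural therapy components. Implements
    hierarchical Bayesian models of reward-effort choice (linear
    subjective-value model with Bernoulli-logit likelihood) and of causal
    attribution (latent internal/global attribution tendencies for positive
    and negative events), each with multivariate-normal subject parameters
    across two sessions and a group-level intervention effect at session
    two. Also provides joint graded-response-model (IRT) and behavioural
    moderation models, simulation-based calibration of the samplers,
    model-based test-retest reliability, posterior predictive accuracy and
    pseudo-R2 fit metrics, heterogeneity-of-treatment-effects decomposition
    of change scores, repeated-measures interaction power analysis, and a
    fully seeded synthetic-cohort generator for all supported designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
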
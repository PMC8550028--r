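Package: wevis
Title: Generative Models of Visibility and Confidence in Binary Identification Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares static generative models of graded visibility and
    confidence judgments in binary identification (e.g., masked orientation
    discrimination) tasks. Implements eight model families as joint distributions
    over the identification response and an ordinal rating given stimulus identity
    and strength: the signal detection theory (SDT) rating model, noisy SDT, the
    weighted evidence and visibility (WEV) model, the two-channel model,
    postdecisional accumulation, constant noise and decay, the response-congruent
    evidence model, and a two-dimensional Bayesian observer with lapses; each under
    constant, identity-dependent, or strength-dependent variance of the decision
    variable. Provides per-participant maximum-likelihood fitting (coarse grid
    search plus restarted Nelder-Mead simplex), AICc/BIC model comparison with
    paired JZS Bayes factors and highest-density intervals, Goodman-Kruskal gamma
    diagnostics of the rating-strength association by accuracy, model-recovery
    bootstrap simulation, and a synthetic-experiment generator for masked
    orientation designs with visual-analogue ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
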
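Package: freeoperant
Title: Simulation and Analysis of Real-World Free-Operant Habit Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale simulator and analysis stack for a gamified
    real-world free-operant habit-induction paradigm. Implements the task
    state machine (variable-ratio gold schedule with a failure guarantee,
    fixed daily outcome pattern, outcome masking, warehouse devaluation and
    control manipulations, and a costly cave mini-task), a synthetic
    participant generator producing session-clustered entry logs with
    tunable devaluation sensitivity, the behavioral adaptation index and
    engagement metrics, overdispersed mixed-effects count regressions
    (Poisson, observation-level random effect, NB1, NB2) fitted by adaptive
    Gauss-Hermite quadrature with leave-one-out cross-validated model
    selection, finite Gaussian mixture clustering of the adaptation index,
    rank-based regression with Wilcoxon scores, and a hybrid
    model-based/model-free reinforcement-learning model for the two-step
    task with MAP estimation and parameter-recovery tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    numDeriv,
    statmod,
    stats,
    utils,
    yaml
Suggests:
    glmmTMB,
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
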
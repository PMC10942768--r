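Package: effortdisc
Title: Effort-Discounting Models of Prosocial Choice Under Acute Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for binary work/rest effort-based
    decision tasks with self and other reward recipients. Implements a family
    of twelve effort-discounting choice models (linear, hyperbolic and
    parabolic discounting crossed with shared or recipient-specific discount
    and softmax temperature parameters), maximum-likelihood fitting with
    bounded multi-start optimisation, BIC model comparison, parameter-recovery
    validation, and trial-level subjective-value regressor construction.
    Also provides a factorial trial-schedule generator, synthetic-participant
    generators (choices, social value orientation angles, perceived-stress and
    salivary-cortisol time series, grip-force traces), area-under-the-curve
    with respect to ground summaries of stress series with missing-sample
    interpolation, and the behavioural statistics used around such tasks:
    proportion of prosocial work choices, mixed-effects logistic choice
    regression with type-III Wald tests, and moderation analysis with
    simple-slopes probing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lme4,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
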
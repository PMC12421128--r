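Package: aacpomdp
Title: POMDP Modeling of Approach-Avoidance Conflict Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational modeling of behavior on an approach-avoidance
    conflict (AAC) runway task. Implements a two-parameter partially
    observable Markov decision process (POMDP) choice model with decision
    uncertainty (softmax temperature) and emotion conflict (aversion value)
    parameters, maximum a posteriori estimation with a Laplace posterior
    approximation, entropy-based choice-uncertainty statistics and their
    correlation with response times, ICC(3,1) longitudinal reliability,
    a synthetic cohort generator for parameter-recovery studies, a stacked
    ensemble diagnostic classifier (elastic net, k-nearest neighbors and
    bagged AdaBoost with nested cross-validation and up-sampling), and a
    mixed-model power analysis by simulation under follow-up attrition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    class,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
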
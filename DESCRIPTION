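Package: gpsbehaviour
Title: Inferring Animal Behaviour from High-Frequency GPS Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies animal behaviour from high-frequency GNSS fixes using
    per-interval movement metrics (step distance and turning angle), CART
    decision trees with cost-complexity pruning and repeated k-fold
    cross-validated size selection, and confusion-matrix validation.
    Couples GPS fix tables to ethogram-coded observation logs, provides
    permutation ANOVA with Bonferroni pairwise post-hoc tests for movement
    metrics, and ships a trajectory simulator that emulates
    behaviour-specific kinematics and habitat-specific GPS positional error
    so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    rpart,
    yaml
Config/testthat/edition: 3
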
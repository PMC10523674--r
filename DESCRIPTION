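Package: tenscal
Title: Closed-Loop Reinforcement-Learning Calibration of TENS Sensory Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic calibration of transcutaneous electrical nerve
    stimulation (TENS) parameters for somatosensory feedback. Two Deep
    Q-Network agents search a pulse-amplitude/pulse-width grid to elicit
    target low- and high-intensity somatotopic sensations. The package
    provides the Markov decision process (13 sensation states, 9
    parameter-delta actions, level-specific reward tables), a psychometric
    virtual-subject generator built on the Weiss-Lapicque strength-duration
    law, a data-driven simulated-subject environment (linear interaction
    regression, random-subspace KNN ensemble, exponential-kernel Gaussian
    process classifier), the closed-loop calibration orchestration with
    smart initialization and agent chaining, brute-force and scripted-ramp
    baselines, and a benchmark harness with nonparametric statistics
    (Friedman, Wilcoxon signed-rank with Bonferroni correction,
    Mann-Whitney).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
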
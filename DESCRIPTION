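Package: dolsim
Title: Evolutionary Simulation of Self-Organized Division of Labor
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of task allocation in
    social-insect colonies whose workers choose between two tasks with small
    evolvable neural networks (feedforward, or recurrent with self-feedback),
    a generalization of fixed response thresholds. Implements colony work
    phases with self-organizing stimulus dynamics and task-switching costs,
    haploid inheritance with two independently segregating linkage blocks,
    Gaussian mutation, fitness-proportional reproduction based on a weighted
    geometric mean of task output, a normalized worker-specialization
    statistic, evolutionary-branching diagnostics, replicate runners, and
    plain-text logging with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
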
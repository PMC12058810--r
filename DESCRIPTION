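Package: fixverse
Title: Multiverse Analysis of Fixation Cleaning Pipelines for Reading
    Eye-Movement Data
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how data-cleaning and modeling decisions
    affect the word frequency effect in sentence-reading eye-movement
    experiments.  Implements a parameterized four-stage fixation cleaning
    function (short-fixation merging, same-word run merging, temporal
    cutoffs, optional deletion of fixations outside interest areas),
    trial-level filtering, single fixation duration extraction, SD-based
    outlier trimming against grand, subject, and subject-by-condition
    means, three crossed random-intercept mixed-model variants (identity,
    log, and Gamma with identity link), enumeration and execution of full
    analysis multiverses, specification-curve and decision-dashboard
    assembly, and permutation-based multiverse inference.  A synthetic-data
    generator produces fixation reports with ex-Gaussian durations,
    subject and item random intercepts, a frequency effect loading on both
    the mean and the distribution tail, and injectable artifact fixations,
    so the whole pipeline is testable without access to raw eye-tracker
    recordings.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    jsonlite,
    graphics,
    grDevices,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
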
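Package: pdtrace
Title: Web-Based Motor Screening for Parkinson Disease from Cursor Tracing
    and Keyboard Tapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for screening Parkinson disease from
    structured web-test motor behavior. Defines screen-relative tracing
    stimuli (line, sine wave, Archimedean spiral) as parametric ribbons, a
    validated JSON session-log data model for mouse-trace and keyboard-tapping
    trials, a seeded generative simulator of PD-like and control-like
    sessions, a 28-feature extractor covering tracing stability, response
    time, and false-press behavior, and a repeated 80:20 train-test
    evaluation protocol with extra-trees feature ranking and several
    classifier families. Results are returned as tibbles with broom-style
    tidy() and glance() methods and ggplot2 trace-reconstruction figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    nnet,
    pROC,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
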
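Package: vwpdpa
Title: Divergence Point Analysis for Visual World Paradigm Eye-Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for timecourse analysis of visual world paradigm (VWP)
    eye-tracking experiments: mapping raw gaze samples to image regions of
    interest, binning looks into fixation proportions on a 20 ms grid aligned
    to a duration-normalized sentence frame, filtering trials and
    participants, and estimating divergence points (the onset of a sustained
    difference between two objects' fixation-proportion curves) by bin-wise
    t tests with a consecutive-bin criterion and a nonparametric bootstrap
    over participants. Includes between-group latency contrasts with
    percentile confidence intervals, a synthetic gaze-data generator with
    known ground-truth divergence latencies for end-to-end validation, and a
    configurable simulate-preprocess-analyse-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
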
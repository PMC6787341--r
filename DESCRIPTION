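Package: tbimarkers
Title: Biomarker Pipelines for Repeated Mild Traumatic Brain Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipelines for the biomarker readouts used in rodent
    repeated mild traumatic brain injury (RmTBI) studies. Implements
    reverse-phase protein microarray (RPPM) dilution-series quantification
    with a five-parameter logistic master curve, false-discovery-rate
    outlier rejection, shared-parameter local block fits and y-intercept
    protein readout; diffusion-tensor scalar maps (FA, RD, AD, trace) and
    track-weighted images (track density, average pathlength, mean
    curvature) from streamline tractograms with region-of-interest
    summaries; and factorial group statistics (between-subjects two-way
    ANOVA with Type III sums of squares, Bonferroni post-hoc comparisons,
    and a 2x2 mixed-design ANOVA). Ships synthetic-data generators with
    known ground truth for every input so each stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
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
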
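Package: bingetools
Title: Lickometer Microstructure, Binge-Eating Phenotyping and Fear-Conditioning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native analysis pipeline for stress-induced binge-like
    eating experiments in rats. Segments lickometer lick trains into licking
    clusters and computes the six standard microstructure metrics (total licks,
    number of clusters, cluster size, cluster duration, meal duration, first
    lick latency), globally or within tone-aligned session epochs; classifies
    binge-eating-prone (BEP) and binge-eating-resistant (BER) phenotypes by the
    per-session intake tertile rule; computes body-weight-normalized intake
    (kcal/kg) and baseline-normalized intake and freezing scores for fear
    conditioning sessions; quantifies background-corrected optical density in
    polygon regions of interest on dark-field in situ hybridization images;
    provides one- and two-way ANOVA with Bonferroni post hoc comparisons and
    unpaired t-tests; and generates fully synthetic experiments (lick trains,
    cohort intakes, freezing trajectories, grain-noise images) with planted,
    recoverable effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tiff
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
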
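Package: microhct
Title: Hematocrit Quantification from Images of Centrifuged Capillary Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures hematocrit from photographs of spun microhaematocrit
    capillary tubes by the three-marker pixel-ratio method, models the
    capture geometry (camera pitch, yaw, roll, height and setback) with a
    pinhole projection to predict parallax bias, renders seeded synthetic
    tube images with known ground truth, recovers interface markers
    automatically from such images, and provides the method-comparison and
    reliability statistics used to validate image-based hematocrit readings
    (Bland-Altman limits of agreement, intraclass correlation with typical
    error, repeated-measures ANOVA with partial eta squared, Bonferroni
    paired t tests, Cohen's d). Includes a record store with spreadsheet
    export and an in-silico replication of the capture-angle validity
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
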
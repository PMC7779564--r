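Package: coeruleus
Title: Threshold-Based Locus Coeruleus Mapping from Magnetisation-Transfer MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated, threshold-based segmentation of the locus
    coeruleus (LC) in magnetisation-transfer (MT) weighted brain volumes,
    construction of a population probabilistic atlas from individual binary
    masks, and unbiased contrast-to-noise (CNR) extraction within fixed
    atlas volumes. Includes a synthetic phantom cohort generator that
    emulates the statistical structure of an MT study (rod-shaped low-MTR
    nuclei with rostrocaudal amplitude and width gradients, caudally
    increasing spatial jitter, repeat averaging), reference-region
    evaluation with asymmetry testing, slice-wise morphometry, spatial
    variability profiles, and cohort-level age and sex statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
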
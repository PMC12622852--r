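Package: scarvalid
Title: Copy-Number Scar HRD Classification and Analytical Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates allele-specific copy-number profiles and SNP allele
    frequencies for homologous recombination deficient (HRD) and proficient
    tumors, extracts genomic scar features (breakpoints per chromosome arm,
    segment-size spectrum, copy-number oscillation, genome-wide LOH) genome-wide
    and within telomeric/centromeric arm portions, trains a gradient-boosted
    scar classifier with a sensitivity-calibrated positivity cutoff, and
    implements the analytical-validation toolkit for such an assay:
    Wilson score intervals, limit-of-blank false-positive rate, dilution-series
    limit of detection with VAF-derived adjusted tumor purity, positive and
    negative percent agreement, factorial-design reproducibility and
    repeatability, and interfering-substance percent agreement.
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
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
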
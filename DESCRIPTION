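Package: hdfreq
Title: Population Frequency of Expanded HTT CAG Repeats and Clinical
    Ascertainment of Huntington's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the population frequency spectrum of HTT CAG trinucleotide
    repeats from clinically ascertained Huntington's disease cohorts. Fits a
    log-linear exponential decay law to allele-count histograms, extends it
    into the pathogenic repeat range, and anchors it to reported disease
    prevalence. Age-adjusts birth frequencies with parametric log-normal
    onset and mortality models combined with actuarial life-table survival,
    marginalises the adjusted frequencies over population-pyramid age
    structures, and estimates the clinical ascertainment rate of symptomatic
    expanded-repeat carriers. Includes a calibrated synthetic-data generator
    for cohorts, life tables and population censuses so the entire pipeline
    is testable without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
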
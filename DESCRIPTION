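Package: geovuln
Title: Socio-Environmental Vulnerability Mapping for Geriatric Depression Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for data-driven socio-environmental
    vulnerability mapping of geriatric depression risk: circular-buffer
    built-environment feature extraction from raster layers (percentage
    residential, percentage vegetation, average and standard deviation of
    building height within 400 m of each subject's address), crude odds
    ratios with Wald confidence intervals from 2x2 tables, multivariable
    binomial logistic regression fitted by an internally implemented
    iteratively reweighted least squares engine, construction of an
    odds-ratio-weighted vulnerability index, spatial mapping of the index
    at planning-unit scale, and validation of the mapped index against the
    cohort outcome. A synthetic-city module simulates rasters, planning
    units, and a geocoded elderly cohort with configurable true effects so
    the whole pipeline is testable end to end without restricted survey
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
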
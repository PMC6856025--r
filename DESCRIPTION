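Package: dpkbe
Title: Dermatopharmacokinetic Bioequivalence from Stratum Corneum Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tape-stripping (stratum corneum sampling)
    studies of topical drug products: per-site drug amounts with
    limit-of-quantification handling, stratum corneum mass and thickness,
    clearance flux and first-order rate constants, average and
    reference-scaled average bioequivalence assessment of log-normal drug
    amounts, Monte-Carlo power simulation for replicate-site designs, a
    slab-diffusion model for lag-time inversion and steady-state flux
    extrapolation, and the C*-concept estimate of drug concentration at the
    cutaneous site of action. Includes a synthetic-study generator so every
    stage of the pipeline can be exercised without raw clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
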
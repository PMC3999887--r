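Package: varlca
Title: Unsupervised Integration of SNP Call Sets by Bayesian Latent Class Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines SNP call sets produced by multiple variant callers (and
    optional variant databases such as dbSNP or COSMIC exported as VCF) into a
    single integrated call set, without any gold-standard training data. Each
    evidence source is modelled as a binary rater in a two-class latent class
    model; a conjugate Gibbs sampler (with an EM maximum-likelihood fitter as a
    fast alternative) estimates the background variant rate and each source's
    false-positive and false-negative rates from the table of agreement
    patterns alone. Per-pattern posterior probabilities of being a true variant
    are then computed in closed form and the union call set is filtered by a
    posterior-probability cutoff. Includes VCF input/output, a synthetic
    call-set generator with known truth for calibration and parameter-recovery
    testing, and sensitivity / transition-transversion (Ti/Tv) evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
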
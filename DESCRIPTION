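Package: duplexsens
Title: Sensitivity Modeling for Duplex-Sequencing ctDNA Assays with Priming Agents
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for quantifying how cell-free DNA
    "priming agents" improve circulating tumor DNA (ctDNA) detection from
    tumor-informed SNV fingerprint panels. Implements a binomial generative
    model of per-site mutant duplex counts, an SNV-count threshold detection
    classifier, burden-stratified sensitivity estimation, an exact
    Poisson-binomial detection-probability oracle, bootstrap panel-size
    downsampling, binomial tumor-fraction downscaling, a parametric-bootstrap
    binomial goodness-of-fit check, and a synthetic-cohort generator that
    emulates duplex count tables from tumor-bearing mice under control and
    primed conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
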
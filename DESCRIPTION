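Package: hospsample
Title: Simulating Random and Purposive Sampling Strategies for Hospital Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates probabilistic and purposive strategies for selecting a
    sample of hospitals from a finite population before data collection starts.
    Given a population of hospitals with a type stratum (academic, teaching,
    general), an organizational region, a bed count and annual counts of three
    blood products (red cells, plasma, platelets), the package simulates five
    stratified selection strategies (largest hospitals, maximum variation,
    simple random, regional variation, and two-region sampling), fits Poisson
    regression prediction models on each sample, predicts blood use for every
    hospital in the population, and summarizes representativeness as
    hospital-level and national-level prediction errors over replicated Monte
    Carlo draws. A calibrated synthetic-population generator is included so
    that designs can be explored when the real population data are
    confidential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
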
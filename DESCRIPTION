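Package: dsefficiency
Title: Statistical Efficiency of Conventional Distance Sampling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the statistical efficiency of conventional
    distance sampling (CDS) on line transects. Provides half-normal and
    hazard-rate detection functions with analytic gradients, conditional
    maximum likelihood fitting of detection parameters, the CDS, known-theta
    and strip-transect abundance estimators, the asymptotic variance penalty
    factor F attributable to unknown detection parameters (with full Fisher
    information and inverse blocks), survey sample-size calculations from a
    target coefficient of variation, and a replicate simulation harness with
    Dirichlet-process overdispersed object locations for comparing CDS with
    strip-transect estimation by mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
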
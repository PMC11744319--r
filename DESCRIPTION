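Package: stomaspec
Title: Opponent-Channel Modelling and Grey-Card Experiment Simulation for
    Stomatopod Colour Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling colour processing in the stomatopod
    (mantis shrimp) midband retina and for simulating and analysing von
    Frisch grey-card discrimination experiments under coloured
    illumination. Provides a small spectral algebra (resampling, filter
    stacking, neutral-density attenuation), visual-pigment templates and a
    12-channel midband retina model, photoreceptor quantum catches with
    per-row log-opponent activity profiles and contrast differences, a
    competing channel-activation ("binning") pattern comparator, a
    generator of synthetic stimulus and illumination spectra, a
    three-choice behavioural experiment simulator with staged
    priming/training/testing rules, and the associated choice statistics:
    chi-square goodness of fit against the one-in-three random expectation
    and binomial logit mixed models with individual random intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
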
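Package: maizePRN
Title: Physiological Reaction Norms for Flowering Time Plasticity in Maize
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models flowering time plasticity in maize multi-environment
    trials as a physiological reaction norm: thermal time from crop
    emergence to anthesis expressed as a bilinear (hinge) or two-level
    linear function of the daylength each genotype senses when it becomes
    photoperiod-sensitized. Provides thermal-time accumulation with linear
    and beta temperature-response functions, the CBM astronomical daylength
    model with a civil-twilight coefficient, prediction of the basic
    vegetative phase from phyllochron and final leaf number, envirotyping
    of sensed daylength across trial networks, latent-variable adjustment
    of thermal times via photoperiod-insensitive control genotypes,
    profile-least-squares hinge regression and the LD-SD linear method for
    estimating flowering time per se, critical photoperiod and photoperiod
    sensitivity, and a forward simulator of trial networks with known
    ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
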
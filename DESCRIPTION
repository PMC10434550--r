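Package: apneaox
Title: Compartmental Oxygen Transport Modelling for Obstructive Sleep Apnea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates alveolar, pulmonary-capillary, systemic arterial and
    systemic venous oxygenation from a time-dependent alveolar-volume
    breathing input, using an oxygen-hemoglobin dissociation curve fit,
    Lagrangian blood-parcel transport through the pulmonary capillaries,
    and Fick-principle tissue consumption. Includes generators for normal,
    apneic, hypopneic and hyperventilatory breathing patterns, a nasal
    pressure to lung volume conversion pipeline for polysomnography
    recordings, apnea-hypopnea index (AHI) arithmetic, and hypoxia burden
    scoring against a wakefulness baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
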
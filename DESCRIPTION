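Package: vesselvib
Title: Quantification of Flow-Induced Vascular Wall Vibrations in Arteriovenous Fistulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for time-resolved vessel-wall fields on
    triangulated surface meshes, aimed at hemodialysis arteriovenous fistulas.
    Computes high-pass (25 Hz) wall vibration amplitude and surface strain maps,
    99th-percentile vibration traces, displacement spectrograms with narrowband
    detection, wall shear stress indices (TAWSS, OSI, spectral power index) and
    the Q-criterion, aggregates metrics over cross-sectional slices of the
    juxta-anastomotic vein, and compares patient groups with linear and Gamma
    mixed-effects models. Includes a calibrated synthetic vessel-wall motion
    generator emulating the patency, stenosis and dilatation spectral regimes
    so that every stage can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmmTMB,
    jsonlite,
    lme4,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
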
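Package: microswim
Title: Biophysical Models of Microswimmer Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models of self-propulsion at low Reynolds number for the four
    classical groups of unicellular microswimmers. Implements resistive-force
    theory for flagellated prokaryotes rotating a helical filament (including
    inference of the flagellar motor torque from swimming speed and
    morphology), planar travelling-wave propulsion for flagellated eukaryotes
    and spermatozoa, and three coarse-grained models of ciliary propulsion
    (constant tangential surface stress, constant force per cilium, and a
    prolate squirmer with prescribed surface velocity). Ships a typed data
    model and parser for the mean/range/bound value notation used in
    published motility compilations, readers and writers for organism record
    tables, seeded synthetic-cohort generators for parameter-recovery
    studies, and an estimation pipeline that turns organism records into
    Reynolds numbers, motor torques, per-cilium forces, surface stresses and
    effective surface velocities with full imputation provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
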
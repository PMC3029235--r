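Package: phagoflow
Title: Axisymmetric Two-Phase Flow Model of Neutrophil Phagocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanical simulation of phagocytic target engulfment by
    a neutrophil, built on the reactive interpenetrating flow formalism: the
    cytoplasm is a mixture of a viscous cytoskeletal network phase and a
    cytosolic solvent phase that interconvert (polymerization/depolymerization)
    and move relative to each other under interphase drag. A moving-boundary
    axisymmetric quadrilateral finite-element mesh tracks the cell; cortical
    tension, membrane-cytoskeleton disjoining (protrusive) stress, and
    membrane-cytoskeleton attraction at the adherent patch drive deformation.
    Scenario presets reproduce the distinct mechanical programs of zymosan
    (protrusive push) and antibody-coated-bead (enveloping embrace)
    phagocytosis; observables extract target push-out distance, engulfment
    time, and inward target speed from trajectories, and a synthetic-benchmark
    generator emulates experiment-like noisy target traces for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
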
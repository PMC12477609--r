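Package: quadsig
Title: G-Quadruplex Folding Signatures from Single UV Absorbance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes G-quadruplex (G4) DNA conformations
    from a single UV absorbance spectrum. The folded-state spectrum, expressed
    in molar extinction coefficients, is subtracted from an unfolded-state
    spectrum calculated from sequence with a nearest-neighbor extinction model,
    yielding a conformation-dependent folding difference signature (the
    Eps2Fold approach). Signatures are classified by principal component
    analysis against a bundled 30-structure reference panel annotated with
    guanine-orientation structural descriptors (glycosidic bond angles, GBA
    stacks, tetrad handedness, groove combinations). Companion geometry tools
    compute glycosidic chi torsions, syn/anti assignments, signed inter-guanine
    twist angles and stacking-overlap classes from atomic models, and a
    synthetic-data module generates class-labelled signatures for testing and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
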
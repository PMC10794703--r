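Package: fibrilstab
Title: Stability, Geometry and Polymorph Tracing of Amyloid Fibril Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream structural analysis of cryo-EM amyloid
    fibril models, developed around transthyretin (ATTR) fibril polymorphs.
    Computes solvation-based fibril stabilization energies from buried
    solvent-accessible surface area (Shrake-Rupley) and atomic solvation
    parameters; handles helical symmetry (twist, rise, crossover distance,
    symmetry expansion and parameter re-estimation); superposes fibril folds
    (Kabsch) for overall and per-residue r.m.s.d. comparison over a common
    core; traces refined cryo-EM particle segments back to filaments to
    quantify polymorph co-occurrence; and generates synthetic fibril models
    and particle tables so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
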
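Package: HelixScan
Title: Local Helix Geometry, Helix Typing and Perturbation Analysis for
    Membrane-Protein Transmembrane Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes local helix parameters (twist, rise per residue, virtual
    torsion, local bending angle, helical radius and axis direction cosines)
    from C-alpha traces of transmembrane helices, assigns alpha, 3-10 and
    pi-helical segments from the per-step parameters, classifies each helix
    into one of nine perturbation types (linear, curved, kinked and
    interspersed 3-10/pi variants, with and without proline), inventories
    backbone N-H...O hydrogen bonds and the unpaired carbonyl groups created
    by perturbations together with their intra- and inter-helical
    stabilisation, and measures pairwise inter-helical crossing angles.
    Includes a synthetic-helix generator producing C-alpha traces and full
    backbones with analytically known geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
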
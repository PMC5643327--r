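Package: flagsym
Title: Helical Lattice Geometry and Structural Comparison of Bacterial
    Flagellar Filaments
Version: 0.1.0
Authors@R:
    person("flagsym", "maintainers", email = "flagsym@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural analysis of bacterial flagellar
    filaments and other helical polymers.  Decomposes a one-start helical
    symmetry (rise, twist) into n-start families with handedness, strand
    pitch and layer-line positions; constructs unrolled helical nets and
    seam-perturbed lattices with a multi-subunit asymmetric unit; builds
    atomic filament models from a protomer by applying screw symmetry;
    compares filaments by Kabsch superposition, per-domain and
    multi-subunit packing RMSD, buried interface area and residue-pair
    distances; and converts supercoil pitch and diameter measurements to
    centerline curvature and twist.  Includes seeded synthetic-data
    generators (idealized two-domain protomers, two-state L/R variants,
    noisy filaments and waveform traces) so every analysis is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
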
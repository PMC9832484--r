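Package: elptools
Title: Phase-Behavior Classification and Hydrogel Characterization for
    Elastin-Like Polypeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rational design of elastin-like polypeptides
    (ELPs). Builds full ELP sequences from block formulas and computes
    sequence-level properties (Kyte-Doolittle hydropathy, average molecular
    mass, residue composition); featurizes molecular-dynamics trajectories
    into per-time-point tables of molecular descriptors (radius of gyration,
    superposed backbone RMSD, hydrogen-bond counts, Shrake-Rupley solvent
    accessible surface area, hydration-shell water counts, secondary-structure
    fractions, switched nonbonded interaction energies); classifies ELPs by
    the presence or absence of LCST phase behavior with a NIPALS PLS-DA model
    validated by nested (double) leave-one-ELP-out cross-validation; and
    quantifies ELP hydrogels via rubber-elasticity mesh size, FRAP recovery
    fitting, Stokes-Einstein and in-gel diffusivities, and five-Gaussian
    amide-I band deconvolution. Includes seed-deterministic synthetic
    generators for descriptor datasets, polymer-in-water trajectories, FRAP
    traces and infrared spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    bio3d,
    mixOmics,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
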
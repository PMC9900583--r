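Package: conformIR
Title: Gas-Phase Peptide Conformers and IR Action Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for determining gas-phase peptide structure from
    infrared action spectroscopy and molecular modelling. Extracts IR
    cross-section spectra from IRMPD-VUV ion counts, predicts IR spectra from
    harmonic stick spectra (empirical frequency scaling, instrument-width
    Gaussian broadening, Boltzmann-weighted composites) and from molecular
    dynamics dipole trajectories (Hann-windowed power spectral density with
    finite-trajectory make-up broadening), calibrates and corrects the
    integrator-induced frequency blue shift of finite-time-step dynamics, and
    characterises conformers structurally: backbone torsion classification and
    descriptive naming, hydrogen-bond assignment from electron-density grids
    (NCI criteria) or geometry, pseudo-ring orders (C5, C7, C10 turns),
    conformer distance by minimal root-sum-square atom displacement (MRSSAD)
    with symmetry-aware reindexing, threshold conformer graphs with minimal
    spanning forests, and Boltzmann abundances from Gibbs energies. Includes a
    velocity-Verlet model-dynamics engine and synthetic-data generators for
    every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
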
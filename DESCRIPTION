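Package: flexsaxs
Title: Coarse-Grained Conformational Sampling and Minimal-Ensemble SAXS
    Fitting for Multidomain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the solution-state flexibility of
    multidomain proteins, such as cellulosomal scaffoldins and their
    enzyme complexes, from small-angle X-ray scattering (SAXS) data.
    Provides standard SAXS curve analytics (Guinier fitting, Kratky and
    dimensionless Kratky transforms, regularized indirect Fourier
    transform for P(r) and Dmax), a one-bead-per-residue coarse-grained
    representation of rigid folded domains joined by flexible linkers,
    replica-exchange Monte Carlo sampling of conformational pools,
    Debye-formula scattering profiles per conformer, and chi-square
    fitting with free scale and offset, including selection of
    equal-weight minimal ensembles of conformers that jointly fit an
    experimental curve. A synthetic-data module generates two-state
    compact/extended mixtures with realistic noise for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
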
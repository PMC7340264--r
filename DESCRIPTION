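Package: xtalcut
Title: Paired-Refinement Analysis of the High-Resolution Cutoff of
    Diffraction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated paired refinement for deciding how far the
    high-resolution limit of a macromolecular diffraction data set should
    be extended. Provides reflection-data containers and text-format I/O
    (merged amplitudes/intensities with CCP4-style free flags, unmerged
    XDS-ASCII-style intensities), resolution-shell geometry, merging
    statistics (multiplicity, completeness, mean I/sigma, Rmerge, Rmeas,
    Rpim, CC1/2 with significance, CC*), direct-summation structure
    factors, a deterministic least-squares toy refinement backend, model
    agreement statistics (Rwork, Rfree, Rgap, CCwork, CCfree), the
    paired-refinement ladder with matched-resolution comparisons,
    complete k-fold cross-validation over free-reflection sets, and a
    synthetic-data generator with a planted information limit for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'xtalcut-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cell.R'
    'reflections.R'
    'reflections-io.R'
    'merging.R'
    'model.R'
    'scattering.R'
    'refine.R'
    'model-stats.R'
    'protocol.R'
    'crossval.R'
    'synthetic.R'
    'report.R'
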
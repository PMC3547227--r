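Package: reflQC
Title: Quality Control and Merging Statistics for Unmerged X-ray
    Diffraction Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale reimplementation of the data-reduction quality
    pipeline used when comparing diffraction data from different
    diffractometers and processing packages: parsing and auditing of
    instrument image-header metadata in two detector dialects (R-AXIS
    image plate and Bruker CCD keyword styles) including overflow pixel
    codecs, Laue-class (4/mmm, mmm) symmetry operators and
    asymmetric-unit mapping, merging statistics (R_merge, R_meas, R_pim,
    completeness, redundancy, mean I/sigma) in resolution shells,
    SADABS-style (K, g) intensity error-model refinement with chi-square
    normalisation and 4-sigma outlier rejection, ice-ring detection and
    resolution-window exclusion, Wilson B-factor estimation, and
    Laue-class discrimination from internal agreement. A synthetic
    unmerged-reflection generator with Wilson-distributed intensities, a
    physical detector noise model, tunable tetragonal-symmetry breaking
    and ice contamination provides ground truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
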
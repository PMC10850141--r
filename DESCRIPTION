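Package: copepodamides
Title: Targeted Screening, Annotation and Quantification of Copepodamides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for targeted mass-spectrometric analysis of copepodamides,
    the taurine-conjugated lipid alarm cues of copepods. Enumerates the
    CA/dhCA homolog library from molecular formula arithmetic, annotates
    precursor-ion-scan peaks by diagnostic-fragment and neutral-loss matching,
    designs multiple reaction monitoring (MRM) transition lists, quantifies
    per-individual amounts by single-point calibration with prosome
    length-to-dry-mass conversion, and analyses composition with from-scratch
    implementations of Bray-Curtis dissimilarity, PERMANOVA, PERMDISP and
    non-metric multidimensional scaling, plus ANCOVA with partial eta squared.
    Includes a synthetic-data generator emulating freshwater and marine
    copepod communities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
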
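Package: mrmscreen
Title: MRM Transition Design and Interference Screening for Modified Nucleosides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts multiple-reaction-monitoring (MRM) transitions for
    modified ribonucleosides analysed by triple-quadrupole LC-MS/MS, using the
    protonated-nucleoside precursor (MH+) and protonated-nucleobase product
    (BH2+) convention, and screens nucleoside panels for three classes of
    misidentification: structural isomers sharing a channel, mass-analogs
    within instrument resolution, and isotopologue crosstalk between channels
    one or two mass units apart. Includes an exact monoisotopic mass engine,
    an isotope-pattern convolution engine with fragment-conditional crosstalk
    intensities, a bundled catalog of commonly monitored modified nucleosides,
    a synthetic chromatogram simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
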
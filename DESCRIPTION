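Package: veshock
Title: Virtual-Electrode Responses of Trabeculated Endocardium to Monophasic Shocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidomain and monodomain simulation of low-energy monophasic
    defibrillation shocks interacting with synthetic endocardial anatomy.
    Generates labelled structured grids emulating an endocardial wall with
    attached ridges and detached trabeculae inside a conductive blood cavity,
    assigns rule-based fibre orientation from Laplace solves, advances a human
    ventricular ionic model augmented with electroporation and a
    large-polarisation potassium current, and reproduces pacing, shock and
    reentry protocols.  Analysis tools quantify virtual-electrode polarity
    patterns, activation and hyperpolarisation fractions, scroll-wave filament
    counts, electrode resistance and shock energy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
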
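Package: ghkclamp
Title: Simulation and Analysis of Whole-Cell Voltage-Clamp Currents in
    Sodium-Selective Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying benzamil-sensitive, sodium-selective
    whole-cell currents such as those carried by the epithelial sodium
    channel (ENaC) in inner-ear epithelia. Provides solution chemistry and
    equilibrium electrochemistry (Nernst potentials, bi-ionic
    Goldman-Hodgkin-Katz permeability ratios, Henderson liquid-junction
    potentials, Ca-EGTA buffering, ideal osmolarity), a synthetic-data
    generator that simulates episodic voltage-clamp recordings from a
    GHK-current membrane model with voltage-dependent open-channel block,
    rundown, leak, series-resistance error, capacitive transients and
    recording noise, a current-voltage analysis pipeline (sweep extraction,
    steady-state averaging, junction-potential and series-resistance
    voltage correction, reversal voltage, terminal conductances,
    drug-sensitive difference currents, paired bi-ionic reversal-voltage
    shifts), and cohort statistics (mean +/- SEM summaries and paired or
    unpaired Student t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
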
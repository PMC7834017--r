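Package: btkconf
Title: Conformational Analysis of Kinase Inhibitor Allostery from HDX-MS and NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential hydrogen/deuterium-exchange mass spectrometry (HDX-MS)
    analysis for detecting long-range conformational effects of active-site
    inhibitors and resistance mutations on full-length Bruton's tyrosine kinase
    (BTK). Builds peptide-level deuterium difference maps against an apo
    reference, classifies differences with fixed modest/major thresholds,
    localizes changes to residues via overlapping peptides, and classifies
    inhibitor response as regulatory-displacing or kinase-local. Companion
    tools estimate active/inactive conformational populations from the W395
    indole reporter region of 1D NMR traces by two-Lorentzian area fitting,
    analyze covalent-inhibitor stoichiometric titrations, and couple
    conformational populations to normalized autophosphorylation activity.
    Includes a synthetic-data generator (Linderstrom-Lang exchange kinetics
    over a two-state conformational ensemble) so every stage is testable
    against known ground truth.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
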
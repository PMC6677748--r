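Package: statorna
Title: Sodium Conduction Analysis for the Flagellar Stator Complex
Version: 0.1.0
Authors@R: person("Stator", "Analysis Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sodium-ion conduction studies of the
    PomA/PomB flagellar stator complex: multi-model PDB trajectory input,
    per-residue ion and water contact-fraction maps, Na+ coordination-number
    profiles, chain-sliding and membrane hydrophobic-thickness metrics,
    steered-MD force-profile aggregation with peak statistics, and ATR-FTIR
    difference-spectroscopy processing with Hill binding fits and
    carboxylate coordination-mode classification. Includes synthetic-data
    generators (scripted binding trajectories, pseudo-lipid membranes, a 1D
    overdamped Langevin steered-MD surrogate, and Gaussian-band FTIR models)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
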
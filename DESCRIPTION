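Package: npcbarrier
Title: Coarse-Grained Energetics of Transport Through the Nuclear Pore Complex
Version: 0.1.0
Authors@R:
    person("npcbarrier", "developers", email = "npcbarrier@example.org",
           role = c("aut", "cre"))
Description: A one-bead-per-amino-acid implicit-solvent model of intrinsically
    disordered FG-nucleoporins grafted inside a rigid, eightfold-symmetric
    nuclear pore scaffold, together with rigid model cargoes that optionally
    carry hydrophobic binding spots. Provides Langevin dynamics, umbrella
    sampling with WHAM unbiasing into potential-of-mean-force profiles, the
    energy-barrier statistic and density/radial analyses used to characterise
    the permeability barrier of the pore, and a closed-form transport model
    G(D, n) describing the barrier as a function of cargo diameter and surface
    hydrophobicity. Includes a synthetic-fixture generator producing FG-like
    sequences and scaled-down pores for desk-scale work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
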
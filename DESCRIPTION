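Package: rinstab
Title: Residue Interaction Network Features for Protein Stability
    Change Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the folding free-energy change (delta-delta-G, kcal/mol)
    of single amino-acid substitutions from a protein structure. A structure
    is parsed from PDB format, annotated with three-state secondary structure
    and relative solvent accessibility, and converted into a residue
    interaction network with typed edges (hydrogen bond, generic contact,
    pi-pi stack, pi-cation, salt bridge). Node centralities on per-bond-type
    subnetworks, neighbour composition, evolutionary conservation from a
    user-supplied alignment and simple knowledge-based potentials are
    assembled into a fixed 184-slot descriptor per mutation, which feeds a
    single-hidden-layer neural regressor trained with validation-split early
    stopping. Includes the evaluation statistics used for stability
    predictors (Pearson, Spearman, Kendall, standard error, residual-based
    outlier trimming), curation filters for mutation tables, deterministic
    synthetic structure generators for testing, and a comparative workflow
    that aligns a mesophile/thermophile protein pair and scans all aligned
    substitutions in both directions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    digest,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
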
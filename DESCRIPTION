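Package: covarcomp
Title: Comparing Amino Acid Covariation Between Protein Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies amino acid covariation in multiple sequence alignments
    with a mutual-information statistic corrected for background signal (MIp)
    and doubly column-normalized (Zpx), selects highly covarying residue
    pairs, and compares two alignments over the same column frame (for
    example natural homologs versus sequences designed onto the same fold):
    percent overlap of covarying pairs with hypergeometric significance,
    amino acid pair propensities and their correlation, classification of
    amino acid pair transitions into physical covariation mechanisms, and
    structural context (C-beta burial, minimum heavy-atom contact distances,
    interface and active-site flags, ensemble RMSD). A synthetic-data module
    generates alignments with planted covariation of chosen mechanism and toy
    structures, so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
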
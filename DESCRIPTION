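Package: protprops
Title: Physicochemical Properties and Comparison of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes ProtParam-style physicochemical properties of protein
    amino-acid sequences: length, average molecular weight, theoretical
    isoelectric point (pI) by bisection of the Henderson-Hasselbalch net
    charge, amino-acid and atomic composition, molecular formula, charged
    residue counts, aliphatic index and grand average of hydropathicity
    (GRAVY). Compares two proteins for thermostability (aliphatic index)
    and hydrophobicity (GRAVY), and renders plain-text reports, TSV tables
    and composition charts. Handles the ambiguity codes B, X and Z with
    explicit partial-report semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
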
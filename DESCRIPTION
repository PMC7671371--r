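Package: protcleave
Title: In Silico Protein Digestion with a User-Extensible Protease Grammar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protease-induced cleavage sites on protein sequences and
    simulates enzymatic digestion for bottom-up proteomics. Proteases are
    modelled as recursive cleavage rules in Schechter-Berger P1/P1'
    coordinates; new proteases can be declared in a small text grammar with
    'or' sets, positional parentheses and exception rules. Digestion runs in
    sequential (each protease independently) or concurrent (all proteases
    together, to fixpoint) mode, with per-protease probabilistic missed
    cleavage. Every generated peptide is annotated with its length, average
    molecular mass and isoelectric point estimated from rearranged
    Henderson-Hasselbalch equations by binary search. Reads (multi-)FASTA and
    FASTQ protein files and writes FASTA, CSV or TSV peptide tables; ships a
    catalog of protease definitions and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
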
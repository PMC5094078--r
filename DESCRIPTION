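Package: cnidimmune
Title: Innate Immune Gene Family Profiling for Actiniarian Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transcripts from annotated cnidarian (sea anemone)
    transcriptomes into conserved innate immune gene families (TLR, NLR,
    MyD88, IL-1R-like, NF-kB) and accessory lectin/complement families
    (CniFL, MASP, SRCR, C-type lectin) using a protein domain-architecture
    grammar over Pfam family and clan annotations.  Detects novel
    TIR-domain-bearing architectures (including the NG1/NG2/NG3 and
    TIR-only classes), subtypes membrane-bound NLRs from predicted
    transmembrane helices, builds conservative (complete-ORF) and total
    gene count tables with complement presence/absence flags, and
    estimates pairwise synonymous and nonsynonymous substitution rates
    (dN/dS) from codon alignments with per-gene averaging.  A synthetic
    transcriptome generator with planted ground truth makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
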
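Package: smiclm
Title: K-mer SMILES Tokenization and Desk-Scale Chemical Language Models for Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing therapeutic peptides and small molecules as
    SMILES strings at desk scale: an atom-level SMILES pre-tokenizer and a
    frequency-mined k-mer tokenizer with greedy longest-match encoding; a
    corpus-curation cascade (small-molecule filters, peptide confidence
    filters, cluster-representative selection, balanced epoch sampling) and an
    internal peptide-to-SMILES builder; a family of BERT-style transformer
    encoders with rotary position embeddings, SwiGLU feed-forward blocks and
    pre-layer normalization, pretrained with span-masked language modeling and
    multi-task regression to physicochemical descriptors; and a downstream
    harness with finetuning, layer-wise linear probing, a path-fingerprint
    random-forest baseline, and standard metrics. Synthetic-data generators
    make every component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
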
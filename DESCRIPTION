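Package: sisTF
Title: Transcription-Factor Prediction by Statistical Information Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supervised identification of transcription factors from binary
    Pfam/GO feature profiles. Proteins are encoded as binary feature vectors,
    per-category feature weights are derived from information content of
    joint occurrence probabilities, features are ranked by mutual weight
    difference, and queries are classified by a nearest-neighbour rule on
    weighted cosine similarity scores, with leave-one-out cross-validation
    driving the feature-count cutoff. Includes readers for HMMER domtblout
    and tabular BLAST output with rule-based GO-term transfer, rule-based
    construction of four training categories (transcription factors,
    transmembrane proteins, enzymes, others) from protein metadata with
    homology propagation, a caller for strictly maternal transcripts from
    normalized expression matrices, and deterministic synthetic-data
    generators for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'sisTF-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotations.R'
    'fixtures.R'
    'io.R'
    'labeling.R'
    'metrics.R'
    'mf.R'
    'model-io.R'
    'pipeline.R'
    'sis.R'
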
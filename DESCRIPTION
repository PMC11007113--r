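Package: DSNetax
Title: Species-Level Annotation of 16S rRNA Gene Sequences with a
    Deep-Shallow Split-Attention Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for species-level taxonomic annotation of full-length
    bacterial 16S rRNA gene sequences. Implements SILVA-style database
    preprocessing (random resolution of IUPAC ambiguity codes and
    abundance-based replication of rare species), stratified train/test
    splitting, overlapping k-mer tokenization with a fixed DNA vocabulary,
    a masked-language-model transformer embedder that turns k-mer streams
    into per-token word vectors, and a parallel deep-shallow classifier
    whose deep branch stacks Split-Attention (ResNeSt-style) blocks and
    whose shallow branch is a short convolutional network; branch features
    are fused for classification. Includes top-k and long-tail (head/tail)
    evaluation, an ablation harness, and a synthetic-community generator
    so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Classification, Metagenomics, Microbiome, Sequencing, Software
RoxygenNote: 7.3.3
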
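Package: siamfcn
Title: Pairwise Dynamic Functional-Connectivity Similarity for Few-Shot
    Early-MCI Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional connectivity networks
    from ROI BOLD time series, weights the vectorized FC series with a
    learnable self-attention mechanism, measures subject-to-subject similarity
    by per-ROI-pair cosine similarity, trains the attention parameters in a
    Siamese configuration under a contrastive loss, and evaluates the
    resulting similarity classifier in an episodic 2-way K-shot protocol.
    Includes a synthetic two-group BOLD cohort generator with planted
    group-dependent dynamic connectivity for end-to-end testing, tools for
    average similarity matrices and discriminative ROI-pair ranking, and
    plain-text readers and writers for scans, cohort manifests, checkpoints
    and metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, signal, withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'RoiTimeSeries-class.R'
    'dynfcn.R'
    'attention.R'
    'similarity.R'
    'training.R'
    'fewshot.R'
    'synthdata.R'
    'io.R'
    'pipeline.R'
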
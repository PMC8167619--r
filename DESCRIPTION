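Package: bilingrad
Title: Attention-Based Classification of Bilingual Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for labeling pneumonia status from bilingual (Korean/English)
    free-text radiology reports. Provides mixed-script tokenization and a
    pneumonia-lexeme inclusion filter, character n-gram (subword) skip-gram
    embeddings trained on monolingual corpora, unsupervised Korean-to-English
    embedding alignment by orthogonal Procrustes with CSLS neighbor retrieval,
    a bidirectional LSTM classifier with additive attention over three labels
    (negative, positive, obscure), one-vs-rest evaluation metrics (precision,
    recall, F1, AUROC, AUPRC, accuracy, Cohen's kappa), attention-weight report
    highlighting, and a seeded synthetic bilingual corpus generator so the full
    pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stringi,
    glmnet,
    Matrix,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
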
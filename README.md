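# bilingrad

Labeling pneumonia from bilingual (Korean/English) radiology reports.

In many non-English-speaking hospitals, free-text radiology reports mix two
scripts: disease nouns are written in English ("consolidation", "GGO") while
most verbs and qualifiers are Korean ("의심", "없음"). Assigning each report a
document-level pneumonia label — **negative**, **positive**, or **obscure**
(uncertain from the text) — turns such archives into usable outcome data for
EHR research. `bilingrad` implements a complete, tested pipeline for this
problem:

1. **Preprocessing** — mixed-script tokenization (maximal runs of Hangul,
   Latin, or digit characters) and the pneumonia-lexeme inclusion filter:
   reports are kept only if they contain one of the stems `pneumoni-`,
   `consolid-`, `infiltra-`, `bronchiole-`, `hazi-`, `hazzi-`, `opacit-`
   (matched at token start) or the whole token `GGO`.
2. **Subword embeddings** — skip-gram with negative sampling where each word
   vector is the mean of its character n-gram vectors, so out-of-vocabulary
   surface forms still get sensible representations. The hot loop is
   compiled (Rcpp) and bit-reproducible under a fixed seed.
3. **Kor2Eng transfer** — an orthogonal map from the Korean into the English
   embedding space, learned **without parallel data**: a supervision-free
   seed dictionary (shared surface forms or frequency ranks), the
   closed-form orthogonal Procrustes solution
   `W = U Vᵀ` from the SVD of `Sᵀ T`, and iterative refinement with
   CSLS-scored mutual nearest neighbours,
   `csls(x, y) = 2 cos(x, y) − r_T(x) − r_S(y)`.
4. **Classifier** — a bidirectional LSTM over the encoded tokens, additive
   attention `score_t = uᵀ tanh(W_a h_t + W_e x_t + b_a)` softmax-normalized
   into weights `α_t`, a context vector `c = [Σ α_t h_t ; Σ α_t x_t]`, and a
   3-class softmax. Training is class-balanced cross-entropy with Adam,
   early stopping, and hand-derived gradients checked against finite
   differences.
5. **Evaluation and explanation** — one-vs-rest precision/recall/F1, AUROC
   (midrank Mann–Whitney), AUPRC (average precision), accuracy, Cohen's κ,
   and attention heat maps of each report (HTML/ANSI).

Hospital report corpora are not distributable, so the package ships a
seeded synthetic bilingual corpus generator that emulates the setting
(mixed-script reports, a 4005/895/550-style class imbalance, cue-phrase
driven labels, and distributionally parallel monolingual corpora with a
ground-truth dictionary for *evaluating* the mapping). Every stage is
exercised end-to-end on generated data.

## A worked example

```r
library(bilingrad)

cfg  <- synth_config(n_reports = 2000, cue_noise = 0, seed = 42)
corp <- generate_corpus(cfg)
mono <- generate_monolingual_corpora(cfg)

# subword embeddings per script
ec    <- embedding_config(dim = 24, ngram_min = 5, ngram_max = 6,
                          epochs = 20, min_count = 5, seed = 42)
emb_l <- train_subword_embeddings(mono$latin, ec)
ec$seed <- 43L
emb_h <- train_subword_embeddings(mono$hangul, ec)

# unsupervised Korean-to-English mapping
seeds <- seed_dictionary(emb_h, emb_l, "frequency", max_pairs = 60)
map   <- train_mapping(emb_h, emb_l, seeds, iterations = 5, k = 10,
                       top_n = 60, reference = mono$dictionary)
print(map)
#> Kor2Eng mapping: dim 24 | 5 refinement iteration(s)
#>   induced dictionary: 46 pairs; CSLS k = 10
#>   orthogonality error: 1.33e-15
#>   precision@1 by iteration: 0.500 0.515 0.500 0.500 0.486 0.486

# train and evaluate the attention Bi-LSTM
sp    <- stratified_split(keyword_filter(corp$reports), 0.2, seed = 42)
model <- attn_bilstm(sp$train, emb_l, emb_h, map,
                     config = classifier_config(seed = 42))
preds <- predict(model, sp$test)
evaluate(preds, sp$test$label)
#> | Class | Precision, n/N (%) | Recall, n/N (%) | F1 (%) | AUROC | AUPRC |
#> |---|---|---|---|---|---|
#> | Negative | 297/297 (100.0) | 297/297 (100.0) | 100 | 1.00 | 1.00 |
#> | Positive | 63/63 (100.0) | 63/63 (100.0) | 100 | 1.00 | 1.00 |
#> | Obscure | 41/41 (100.0) | 41/41 (100.0) | 100 | 1.00 | 1.00 |
#> Accuracy: 100.00% (401/401); kappa vs reference: 1.000
```

On this cue-deterministic synthetic corpus (every label is signalled by an
unambiguous cue phrase) the classifier recovers the labels essentially
perfectly; the interesting quantities are the mapping's dictionary
precision@1 (how well Korean words retrieve their English mates without any
parallel supervision) and the attention weights, which should highlight the
cue and disease-noun tokens:

```r
ann <- annotate(sp$test[1, ], preds[[1]])
top_k(ann, 3)          # highest-attention tokens
#>         surface   weight_raw
#> 21         없음 9.999996e-01
#> 5  infiltration 2.545087e-07
#> 23         left 1.366447e-07
writeLines(render_annotated(ann, "ansi"))   # shaded terminal rendering
```

Here the negation cue "없음" ("absent") receives essentially all of the
attention mass on a correctly classified negative report, with the
pneumonia lexeme "infiltration" next — the highlighted-words behaviour the
attention layer exists to provide.

The full chain (generate, filter, embed, align, train, evaluate, explain)
is also available as one call — `run_all(pipeline_config(seed = 1), "out/")`
— or from a shell via `inst/cli/bilingrad.R`.

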
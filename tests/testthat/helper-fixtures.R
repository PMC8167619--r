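# shared fixtures built in code (no stored data)

# a tiny subword embedding assembled by hand: random gram vectors, word
# vectors = mean of gram vectors, exactly as the trainer composes them
toy_embedding <- function(words, dim = 8, nmin = 3, nmax = 4, seed = 1) {
  set.seed(seed)
  gram_lists <- lapply(words, extract_ngrams, nmin = nmin, nmax = nmax)
  ngrams <- unique(unlist(gram_lists))
  ngram_vec <- matrix(rnorm(length(ngrams) * dim), length(ngrams), dim,
                      dimnames = list(ngrams, NULL))
  gidx <- setNames(seq_along(ngrams), ngrams)
  word_grams <- lapply(gram_lists, function(g) unname(gidx[g]))
  word_vec <- t(vapply(word_grams, function(g) {
    colMeans(ngram_vec[g, , drop = FALSE])
  }, numeric(dim)))
  rownames(word_vec) <- words
  structure(list(words = words, word_vec = word_vec, ngrams = ngrams,
                 ngram_vec = ngram_vec, word_grams = word_grams,
                 counts = rev(seq_along(words)),
                 config = embedding_config(dim = dim, ngram_min = nmin,
                                           ngram_max = nmax),
                 loss = NULL, oov_capable = TRUE),
            class = "subword_embedding")
}

# wrap a plain matrix (rownames = words) as a word-only embedding
matrix_embedding <- function(mat) {
  structure(list(words = rownames(mat), word_vec = mat,
                 ngrams = character(0),
                 ngram_vec = matrix(0, 0, ncol(mat)), word_grams = NULL,
                 counts = NULL, config = embedding_config(dim = ncol(mat)),
                 loss = NULL, oov_capable = FALSE),
            class = "subword_embedding")
}

# small labeled corpus + everything needed to train a classifier quickly
small_pipeline_fixture <- function(n = 400, seed = 7, cue_noise = 0,
                                   order_coded = FALSE, dim = 16,
                                   epochs = 25) {
  cfg <- synth_config(n_reports = n, cue_noise = cue_noise, seed = seed)
  corp <- generate_corpus(cfg, order_coded = order_coded)
  mono <- generate_monolingual_corpora(cfg)
  ec <- embedding_config(dim = dim, ngram_min = 5, ngram_max = 6,
                         epochs = epochs, min_count = 2, seed = seed)
  emb_l <- train_subword_embeddings(mono$latin, ec)
  ec$seed <- ec$seed + 1L
  emb_h <- train_subword_embeddings(mono$hangul, ec)
  seeds <- seed_dictionary(emb_h, emb_l, "frequency", max_pairs = 60)
  mapping <- train_mapping(emb_h, emb_l, seeds, iterations = 2, k = 10,
                           top_n = 50)
  list(config = cfg, corpus = corp, mono = mono,
       emb_l = emb_l, emb_h = emb_h, mapping = mapping)
}
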
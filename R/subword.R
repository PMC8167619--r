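#' Subword embedding hyperparameters
#'
#' @param dim Vector dimension.
#' @param ngram_min,ngram_max Character n-gram range (inclusive); boundary
#'   markers `<` and `>` are added before slicing, and the marked whole word
#'   is always kept as its own key.
#' @param window Maximum skip-gram context window (the effective window per
#'   position is sampled uniformly in `1:window`).
#' @param negatives Negative samples per context pair.
#' @param epochs Training passes over the corpus.
#' @param min_count Words rarer than this are dropped from the vocabulary.
#' @param learning_rate Initial SGD learning rate (linearly decayed).
#' @param seed Integer seed; training is single-threaded and bit-reproducible.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 100L, ngram_min = 3L, ngram_max = 6L,
                             window = 5L, negatives = 5L, epochs = 5L,
                             min_count = 1L, learning_rate = 0.05, seed = 1L) {
  stopifnot(dim >= 1, ngram_min >= 2, ngram_min <= ngram_max, window >= 1,
            negatives >= 1, epochs >= 1, min_count >= 1, learning_rate > 0)
  structure(list(dim = as.integer(dim), ngram_min = as.integer(ngram_min),
                 ngram_max = as.integer(ngram_max), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 min_count = as.integer(min_count),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedding_config")
}

#' Character n-grams of a boundary-marked word
#'
#' The word is wrapped as `<word>` and all character n-grams with lengths in
#' `[nmin, nmax]` are enumerated left-to-right in increasing-n order; the
#' marked whole word is appended as its own key (once — it may already be in
#' the enumeration when `nmax` reaches the marked length). Operates on
#' Unicode characters, so Hangul syllables count as single characters.
#'
#' @param word Non-empty string.
#' @param nmin,nmax N-gram length range.
#' @return Character vector of n-grams including the whole-word key.
#' @examples
#' extract_ngrams("ggo", 3, 3)   # "<gg" "ggo" "go>" "<ggo>"
#' @export
extract_ngrams <- function(word, nmin, nmax) {
  if (!nzchar(word)) stop("word must be non-empty")
  if (nmin > nmax) stop("nmin must be <= nmax")
  marked <- paste0("<", word, ">")
  chars <- stringi::stri_split_boundaries(marked, type = "character")[[1]]
  L <- length(chars)
  grams <- character(0)
  for (n in seq(nmin, nmax)) {
    if (n > L) break
    grams <- c(grams, vapply(seq_len(L - n + 1), function(i) {
      paste0(chars[i:(i + n - 1)], collapse = "")
    }, character(1)))
  }
  unique(c(grams, marked))
}

#' Train subword skip-gram embeddings
#'
#' Skip-gram with negative sampling in which each input word vector is the
#' mean of its character n-gram vectors (the boundary-marked whole word is
#' one of the "n-grams"), so that any surface form — including words never
#' seen in training — can be composed from shared subword units. The hot
#' loop is compiled; a fixed seed reproduces the tables exactly.
#'
#' @param corpus A list of character token vectors (one sentence each).
#' @param config An [embedding_config()].
#' @return An object of class `subword_embedding` with fields `words`,
#'   `word_vec` (composed word vectors, one row per word, most frequent
#'   first), `ngrams`, `ngram_vec`, `counts`, `config`, `loss`
#'   (per-epoch mean negative log-likelihood) and `oov_capable`.
#' @export
train_subword_embeddings <- function(corpus, config = embedding_config()) {
  stopifnot(is.list(corpus), inherits(config, "embedding_config"))
  tokens <- unlist(corpus, use.names = FALSE)
  if (!length(tokens)) stop("empty corpus")
  counts <- table(tokens)
  counts <- counts[counts >= config$min_count]
  if (!length(counts)) stop("empty effective vocabulary after min_count pruning")
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  words <- names(counts)[ord]
  wcounts <- as.numeric(counts)[ord]
  widx <- seq_along(words)
  names(widx) <- words

  sentences <- lapply(corpus, function(s) {
    ids <- unname(widx[s])
    as.integer(ids[!is.na(ids)])
  })
  sentences <- sentences[lengths(sentences) > 0]
  if (!length(sentences)) stop("empty effective vocabulary after min_count pruning")

  gram_lists <- lapply(words, extract_ngrams,
                       nmin = config$ngram_min, nmax = config$ngram_max)
  ngrams <- unique(unlist(gram_lists, use.names = FALSE))
  gidx <- seq_along(ngrams)
  names(gidx) <- ngrams
  word_grams <- lapply(gram_lists, function(g) as.integer(unname(gidx[g])))

  fit <- sgns_train_cpp(sentences, word_grams, length(words), length(ngrams),
                        wcounts, config$dim, config$window, config$negatives,
                        config$epochs, config$learning_rate, config$seed)
  ngram_vec <- fit$ngram_vec
  rownames(ngram_vec) <- ngrams
  word_vec <- t(vapply(word_grams, function(g) {
    colMeans(ngram_vec[g, , drop = FALSE])
  }, numeric(config$dim)))
  rownames(word_vec) <- words

  structure(list(words = words, word_vec = word_vec, ngrams = ngrams,
                 ngram_vec = ngram_vec, word_grams = word_grams,
                 counts = wcounts, config = config, loss = fit$epoch_loss,
                 oov_capable = TRUE),
            class = "subword_embedding")
}

#' @export
print.subword_embedding <- function(x, ...) {
  cat("Subword embedding:", length(x$words), "words,",
      length(x$ngrams), "n-grams, dim", ncol(x$word_vec), "\n")
  cat("  OOV composition:", if (isTRUE(x$oov_capable)) "enabled" else
    "disabled (word-only table)", "\n")
  invisible(x)
}

#' Compose the vector of a surface word
#'
#' In-vocabulary words return their stored composed vector (the mean of the
#' whole-word and n-gram vectors). Out-of-vocabulary words are composed as
#' the mean of their *known* n-gram vectors; if no n-gram is known (or the
#' embedding was loaded without its n-gram table) a zero vector is returned,
#' flagged via `attr(v, "empty")`.
#'
#' @param emb A `subword_embedding`.
#' @param word Non-empty string.
#' @return Numeric vector of length `dim` with attributes `oov` (logical)
#'   and `empty` (`TRUE` when no information was available).
#' @export
embedding_vector <- function(emb, word) {
  stopifnot(inherits(emb, "subword_embedding"), nzchar(word))
  i <- match(word, emb$words)
  if (!is.na(i)) {
    v <- emb$word_vec[i, ]
    attr(v, "oov") <- FALSE
    attr(v, "empty") <- FALSE
    return(v)
  }
  d <- ncol(emb$word_vec)
  if (isTRUE(emb$oov_capable)) {
    g <- extract_ngrams(word, emb$config$ngram_min, emb$config$ngram_max)
    known <- match(g, emb$ngrams)
    known <- known[!is.na(known)]
    if (length(known)) {
      v <- colMeans(emb$ngram_vec[known, , drop = FALSE])
      attr(v, "oov") <- TRUE
      attr(v, "empty") <- FALSE
      return(v)
    }
  }
  v <- numeric(d)
  attr(v, "oov") <- TRUE
  attr(v, "empty") <- TRUE
  v
}

#' Save/load embeddings in word2vec text format
#'
#' `save_embeddings()` writes the composed word vectors in the standard
#' word2vec text format (header `"n_words dim"`, then one word and `dim`
#' floats per line) plus an n-gram sidecar at `<path>.ngrams` in the same
#' format with an extended header carrying the n-gram range.
#' `load_embeddings()` restores both; loading a plain word2vec file without
#' a sidecar (e.g. externally pre-trained vectors) yields a word-only
#' embedding with OOV composition disabled.
#'
#' @param emb A `subword_embedding`.
#' @param path File path for the word vectors.
#' @return `load_embeddings()` returns a `subword_embedding`; round-trips
#'   are exact to 1e-6 per coordinate.
#' @export
save_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "subword_embedding"))
  .write_vec_file(emb$words, emb$word_vec, path, header_extra = NULL)
  if (isTRUE(emb$oov_capable)) {
    .write_vec_file(emb$ngrams, emb$ngram_vec, paste0(path, ".ngrams"),
                    header_extra = c(emb$config$ngram_min, emb$config$ngram_max))
  }
  invisible(path)
}

.write_vec_file <- function(keys, mat, path, header_extra = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(nrow(mat), ncol(mat), header_extra), collapse = " "), con)
  body <- paste(keys, apply(mat, 1, function(r) {
    paste(sprintf("%.9g", r), collapse = " ")
  }))
  writeLines(body, con)
}

.read_vec_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1 != n) stop("embedding file header promises ", n,
                                   " rows but file has ", length(lines) - 1)
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1)
  mat <- matrix(0, n, d)
  for (i in seq_len(n)) {
    vals <- as.numeric(parts[[i]][-1])
    if (length(vals) != d) {
      stop("row ", i, " has ", length(vals), " values but header says dim ", d)
    }
    mat[i, ] <- vals
  }
  rownames(mat) <- keys
  list(keys = keys, mat = mat, extra = hdr[-(1:2)])
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  w <- .read_vec_file(path)
  sidecar <- paste0(path, ".ngrams")
  if (file.exists(sidecar)) {
    g <- .read_vec_file(sidecar)
    nmin <- as.integer(g$extra[1]); nmax <- as.integer(g$extra[2])
    cfg <- embedding_config(dim = ncol(w$mat), ngram_min = nmin, ngram_max = nmax)
    gidx <- seq_along(g$keys); names(gidx) <- g$keys
    word_grams <- lapply(w$keys, function(word) {
      gg <- extract_ngrams(word, nmin, nmax)
      as.integer(unname(gidx[gg][!is.na(gidx[gg])]))
    })
    structure(list(words = w$keys, word_vec = w$mat, ngrams = g$keys,
                   ngram_vec = g$mat, word_grams = word_grams,
                   counts = NULL, config = cfg, loss = NULL,
                   oov_capable = TRUE),
              class = "subword_embedding")
  } else {
    cfg <- embedding_config(dim = ncol(w$mat))
    structure(list(words = w$keys, word_vec = w$mat, ngrams = character(0),
                   ngram_vec = matrix(0, 0, ncol(w$mat)), word_grams = NULL,
                   counts = NULL, config = cfg, loss = NULL,
                   oov_capable = FALSE),
              class = "subword_embedding")
  }
}
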
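# row-wise unit normalization; zero rows stay zero
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

.emb_matrix <- function(x) {
  if (inherits(x, "subword_embedding")) x$word_vec
  else if (is.matrix(x)) x
  else stop("expected a subword_embedding or a matrix with rownames")
}

#' Orthogonal Procrustes alignment
#'
#' Returns the orthogonal matrix `W` minimizing `||source %*% W - target||_F`
#' over all orthogonal matrices, given row-aligned point sets: the closed
#' form `W = U V'` from the SVD of `source' target`.
#'
#' @param source,target Numeric `n x d` matrices with rows paired.
#' @return A `d x d` orthogonal matrix.
#' @export
procrustes <- function(source, target) {
  stopifnot(is.matrix(source), is.matrix(target),
            all(dim(source) == dim(target)))
  d <- ncol(source)
  if (nrow(source) < d) {
    stop("need at least d = ", d, " point pairs, got ", nrow(source))
  }
  m <- crossprod(source, target)
  if (qr(m)$rank < d) {
    warning("rank-deficient cross-covariance; Procrustes solution is not unique")
  }
  s <- svd(m)
  s$u %*% t(s$v)
}

#' CSLS-ranked nearest neighbors
#'
#' Cross-domain similarity local scaling: the plain cosine between a mapped
#' source vector and a target is corrected by the mean cosine of each side to
#' its `k` nearest neighbors in the other domain,
#' `csls(x, y) = 2 cos(x, y) - r_T(x) - r_S(y)`. The correction demotes
#' "hub" targets that are close to everything, a known failure mode of plain
#' nearest-neighbor retrieval across embedding spaces.
#'
#' @param query A unit `d`-vector (a mapped source word).
#' @param targets Unit-row `m x d` matrix of target vectors.
#' @param k Neighborhood size (`1 <= k <= m`).
#' @param sources Unit-row matrix of all mapped source vectors, used to
#'   compute each target's neighborhood term `r_S`.
#' @return A data frame `(index, score)` in descending score order, ties
#'   broken by lower index.
#' @export
csls_neighbors <- function(query, targets, k, sources) {
  stopifnot(is.numeric(query), is.matrix(targets), is.matrix(sources),
            length(query) == ncol(targets), ncol(sources) == ncol(targets))
  m <- nrow(targets)
  if (k < 1 || k > m) stop("k must be in 1..", m)
  cs <- drop(targets %*% query)                       # cos(query, each target)
  r_t <- mean(sort(cs, decreasing = TRUE)[seq_len(k)])
  st <- sources %*% t(targets)                        # sources x targets cosines
  r_s <- apply(st, 2, function(col) {
    mean(sort(col, decreasing = TRUE)[seq_len(min(k, length(col)))])
  })
  score <- 2 * cs - r_t - r_s
  ord <- order(-score, seq_len(m))
  data.frame(index = ord, score = score[ord])
}

# full CSLS score matrix between mapped sources and targets (both unit rows)
.csls_matrix <- function(mapped, targets, k) {
  cs <- mapped %*% t(targets)
  kq <- min(k, ncol(cs))
  r_t <- apply(cs, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(kq)]))
  kr <- min(k, nrow(cs))
  r_s <- apply(cs, 2, function(col) mean(sort(col, decreasing = TRUE)[seq_len(kr)]))
  2 * cs - outer(r_t, rep(1, ncol(cs))) - outer(rep(1, nrow(cs)), r_s)
}

#' Induce a bilingual dictionary from a mapped embedding pair
#'
#' Applies `transform` to the (unit-normalized) source vectors, scores all
#' source-target pairs by CSLS, and keeps the mutual nearest neighbors:
#' pairs where each word is the other's best candidate. This is how the
#' unsupervised mapping bootstraps training pairs without any parallel data.
#'
#' @param source_emb,target_emb `subword_embedding`s or plain matrices with
#'   rownames.
#' @param transform `d x d` matrix carrying source vectors into target space.
#' @param k CSLS neighborhood size.
#' @param max_pairs Keep at most this many pairs (highest scores first).
#' @param top_n Restrict induction to the `top_n` most frequent words on
#'   each side (embedding rows are stored most-frequent-first); rare words
#'   have unreliable vectors and would otherwise pollute the dictionary.
#' @return Data frame `(source, target, score)` sorted by descending score.
#' @export
induce_dictionary <- function(source_emb, target_emb, transform, k = 10,
                              max_pairs = 10000, top_n = Inf) {
  S <- .emb_matrix(source_emb); Tm <- .emb_matrix(target_emb)
  if (!nrow(S) || !nrow(Tm)) stop("empty vocabulary")
  if (is.finite(top_n)) {
    S <- S[seq_len(min(top_n, nrow(S))), , drop = FALSE]
    Tm <- Tm[seq_len(min(top_n, nrow(Tm))), , drop = FALSE]
  }
  stopifnot(ncol(S) == nrow(transform), ncol(Tm) == ncol(transform))
  if (all(transform == 0)) {
    warning("zero transform: induced dictionary is degenerate")
  }
  mapped <- .unit_rows(.unit_rows(S) %*% transform)
  tg <- .unit_rows(Tm)
  sc <- .csls_matrix(mapped, tg, k)
  best_t <- max.col(sc, ties.method = "first")       # best target per source
  best_s <- max.col(t(sc), ties.method = "first")    # best source per target
  mutual <- which(best_s[best_t] == seq_len(nrow(sc)))
  if (!length(mutual)) {
    return(data.frame(source = character(), target = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    source = rownames(S)[mutual],
    target = rownames(Tm)[best_t[mutual]],
    score = sc[cbind(mutual, best_t[mutual])],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  head(out, max_pairs)
}

#' Seed dictionary for the first Procrustes step
#'
#' Three supervision-free (or weakly supervised) initializations:
#' `"identical"` pairs words whose normalized surfaces occur in both
#' vocabularies (digits and shared Latin medical terms); `"frequency"` pairs
#' the i-th most frequent words of each corpus, which works when the corpora
#' are distributionally comparable; `"tsv"` reads a user-provided 2-column
#' dictionary.
#'
#' @param source_emb,target_emb `subword_embedding`s (their row order is
#'   most-frequent-first, which `"frequency"` mode relies on).
#' @param mode `"identical"`, `"frequency"`, or `"tsv"`.
#' @param tsv_path Path to a 2-column TSV (source, target) for `"tsv"` mode.
#' @param max_pairs Cap on the number of seed pairs.
#' @return Data frame `(source, target)`.
#' @export
seed_dictionary <- function(source_emb, target_emb,
                            mode = c("identical", "frequency", "tsv"),
                            tsv_path = NULL, max_pairs = 30) {
  mode <- match.arg(mode)
  sw <- rownames(.emb_matrix(source_emb))
  tw <- rownames(.emb_matrix(target_emb))
  if (mode == "identical") {
    shared <- intersect(normalize_token(sw), normalize_token(tw))
    if (!length(shared)) {
      stop("no identical surface forms across vocabularies; ",
           "try mode = 'frequency' or a supervised TSV")
    }
    out <- data.frame(source = shared, target = shared, stringsAsFactors = FALSE)
  } else if (mode == "frequency") {
    n <- min(length(sw), length(tw), max_pairs)
    out <- data.frame(source = sw[seq_len(n)], target = tw[seq_len(n)],
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(tsv_path)) stop("tsv mode needs tsv_path")
    d <- read.csv(tsv_path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    out <- data.frame(source = d[[1]], target = d[[2]], stringsAsFactors = FALSE)
    out <- out[out$source %in% sw & out$target %in% tw, , drop = FALSE]
  }
  head(out[!duplicated(out$source), , drop = FALSE], max_pairs)
}

#' Learn an unsupervised cross-lingual mapping (Kor2Eng)
#'
#' Alternates orthogonal Procrustes on the current dictionary with mutual
#' CSLS nearest-neighbor dictionary induction, starting from a
#' supervision-free seed. Vectors are unit-normalized, mean-centered and
#' re-normalized before mapping (the standard preprocessing for this family
#' of methods; centering removes the shared offset that otherwise dominates
#' cosine geometry). The learned transform carries Hangul word vectors into
#' the Latin embedding space; the inverse direction is its transpose.
#'
#' @param source_emb,target_emb `subword_embedding`s or matrices with
#'   rownames.
#' @param seed_pairs Data frame `(source, target)`, e.g. from
#'   [seed_dictionary()].
#' @param iterations Number of refinement rounds (0 = pure Procrustes on the
#'   seed pairs).
#' @param k CSLS neighborhood size.
#' @param max_pairs Dictionary size cap during refinement.
#' @param top_n Frequency cutoff for dictionary induction (see
#'   [induce_dictionary()]).
#' @param reference Optional ground-truth dictionary `(source, target)` used
#'   only to record precision@1 per iteration — never to train.
#' @return An object of class `kor2eng` with fields `transform`,
#'   `induced_dictionary`, `csls_k`, `iterations_run`, and `history`
#'   (per-iteration dictionary size and, if a reference was given,
#'   precision@1).
#' @export
train_mapping <- function(source_emb, target_emb, seed_pairs, iterations = 5,
                          k = 10, max_pairs = 10000, top_n = Inf,
                          reference = NULL) {
  prep <- function(m) {
    m <- .unit_rows(m)
    .unit_rows(scale(m, center = TRUE, scale = FALSE))
  }
  S <- prep(.emb_matrix(source_emb))
  Tm <- prep(.emb_matrix(target_emb))
  d <- ncol(S)
  stopifnot(ncol(Tm) == d, iterations >= 0)
  pairs <- seed_pairs
  history <- data.frame(iteration = integer(), n_pairs = integer(),
                        precision = numeric())
  W <- NULL
  for (it in 0:iterations) {
    si <- match(pairs$source, rownames(S))
    ti <- match(pairs$target, rownames(Tm))
    ok <- !is.na(si) & !is.na(ti)
    si <- si[ok]; ti <- ti[ok]
    if (length(si) < d) {
      stop("dictionary collapsed to ", length(si), " pairs (< d = ", d,
           ") at iteration ", it)
    }
    W <- procrustes(S[si, , drop = FALSE], Tm[ti, , drop = FALSE])
    pairs <- induce_dictionary(S, Tm, W, k = k, max_pairs = max_pairs,
                               top_n = top_n)
    history <- rbind(history, data.frame(
      iteration = it, n_pairs = nrow(pairs),
      precision = if (is.null(reference)) NA_real_ else
        mapping_precision(pairs, reference)
    ))
  }
  structure(list(transform = W, induced_dictionary = pairs, csls_k = k,
                 iterations_run = iterations, history = history),
            class = "kor2eng")
}

#' Precision@1 of a dictionary against a reference
#'
#' Fraction of pairs whose source occurs in the reference and whose target
#' matches the reference translation.
#'
#' @param pairs Data frame `(source, target)`.
#' @param reference Data frame with the ground-truth pairs in its first two
#'   columns (e.g. the synthetic generator's `dictionary`).
#' @return A number in `[0, 1]` (NA when no pair's source is covered).
#' @export
mapping_precision <- function(pairs, reference) {
  ref <- setNames(as.character(reference[[2]]), as.character(reference[[1]]))
  src <- as.character(pairs$source)
  covered <- src %in% names(ref)
  if (!any(covered)) return(NA_real_)
  mean(ref[src[covered]] == as.character(pairs$target)[covered])
}

#' Translate an embedding through a learned mapping
#'
#' Replaces every word (and n-gram) vector `x` by `x %*% W`. Because `W` is
#' orthogonal, norms are preserved.
#'
#' @param source_emb A `subword_embedding`.
#' @param model A `kor2eng` object or a bare `d x d` matrix.
#' @return A `subword_embedding` in the target space.
#' @export
translate_embedding <- function(source_emb, model) {
  W <- if (inherits(model, "kor2eng")) model$transform else model
  stopifnot(inherits(source_emb, "subword_embedding"),
            ncol(source_emb$word_vec) == nrow(W))
  out <- source_emb
  wn <- rownames(out$word_vec)
  out$word_vec <- out$word_vec %*% W
  rownames(out$word_vec) <- wn
  if (nrow(out$ngram_vec)) {
    gn <- rownames(out$ngram_vec)
    out$ngram_vec <- out$ngram_vec %*% W
    rownames(out$ngram_vec) <- gn
  }
  out
}

#' @export
print.kor2eng <- function(x, ...) {
  d <- nrow(x$transform)
  orth <- max(abs(crossprod(x$transform) - diag(d)))
  cat("Kor2Eng mapping: dim", d, "|", x$iterations_run, "refinement iteration(s)\n")
  cat("  induced dictionary:", nrow(x$induced_dictionary), "pairs; CSLS k =",
      x$csls_k, "\n")
  cat("  orthogonality error:", format(orth, digits = 3), "\n")
  if (any(!is.na(x$history$precision))) {
    cat("  precision@1 by iteration:",
        paste(format(x$history$precision, digits = 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.kor2eng <- function(object, ...) object$transform

#' @export
predict.kor2eng <- function(object, newdata, ...) {
  if (inherits(newdata, "subword_embedding")) {
    translate_embedding(newdata, object)
  } else {
    as.matrix(newdata) %*% object$transform
  }
}

#' Save/load a mapping as TSV
#'
#' The transform is stored as a TSV matrix with a one-line header
#' `dim csls_k iterations`; the induced dictionary as 3-column TSV.
#'
#' @param model A `kor2eng` object.
#' @param path Output path for the transform (`<path>.dict` gets the
#'   dictionary).
#' @return `load_mapping()` returns a `kor2eng` object.
#' @export
save_mapping <- function(model, path) {
  stopifnot(inherits(model, "kor2eng"))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(paste(nrow(model$transform), model$csls_k, model$iterations_run), con)
  write.table(format(model$transform, digits = 12), con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  write.table(model$induced_dictionary, paste0(path, ".dict"), sep = "\t",
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname save_mapping
#' @export
load_mapping <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  W <- as.matrix(read.table(text = lines[-1], sep = "\t"))
  dimnames(W) <- NULL
  stopifnot(nrow(W) == hdr[1], ncol(W) == hdr[1])
  dict_path <- paste0(path, ".dict")
  dict <- if (file.exists(dict_path)) {
    read.csv(dict_path, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
  } else data.frame(source = character(), target = character(), score = numeric())
  structure(list(transform = W, induced_dictionary = dict, csls_k = hdr[2],
                 iterations_run = hdr[3],
                 history = data.frame(iteration = integer(),
                                      n_pairs = integer(), precision = numeric())),
            class = "kor2eng")
}
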
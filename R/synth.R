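#' Configuration for the synthetic bilingual corpus generator
#'
#' The generator emulates the study's setting: short chest CT / x-ray report
#' descriptions in which most function words are Korean (Hangul) while
#' disease nouns are English, every report contains at least one
#' pneumonia-related lexeme, and the three document labels are driven by
#' affirmation / negation / uncertainty cue phrases.
#'
#' @param n_reports Number of reports (also the number of sentences per
#'   monolingual corpus in [generate_monolingual_corpora()]).
#' @param class_priors Probabilities of (negative, positive, obscure); the
#'   default mirrors the study's 4005/895/550 class mix.
#' @param korean_fraction Probability that a function-word slot is rendered
#'   in Hangul rather than Latin script.
#' @param filler_vocab_size Number of generated filler word pairs per script,
#'   in addition to the fixed template pairs.
#' @param cue_noise Probability that the emitted cue phrase conflicts with
#'   the report's label (the cue is swapped for a cue of another class while
#'   the label is kept).
#' @param seed Integer seed; every generator operation uses its own stream
#'   derived from this seed, so corpora are reproducible piecewise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 2000,
                         class_priors = c(negative = 4005, positive = 895,
                                          obscure = 550) / 5450,
                         korean_fraction = 0.7,
                         filler_vocab_size = 40,
                         cue_noise = 0.05,
                         seed = 1L) {
  class_priors <- unname(as.numeric(class_priors))
  if (length(class_priors) != 3 || anyNA(class_priors) ||
      any(class_priors < 0) || any(class_priors > 1) ||
      abs(sum(class_priors) - 1) > 1e-12) {
    stop("class_priors must be 3 probabilities summing to 1")
  }
  stopifnot(
    is.numeric(n_reports), length(n_reports) == 1, n_reports >= 0,
    korean_fraction >= 0, korean_fraction <= 1,
    filler_vocab_size >= 1,
    cue_noise >= 0, cue_noise <= 1
  )
  structure(list(
    n_reports = as.integer(n_reports),
    class_priors = setNames(class_priors, .LABELS),
    korean_fraction = korean_fraction,
    filler_vocab_size = as.integer(filler_vocab_size),
    cue_noise = cue_noise,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# cue phrases per class; token sets are pairwise disjoint so that, at
# cue_noise = 0, a rule reading only cues recovers the label exactly
.cue_sets <- list(
  negative = c("no evidence of", "없음", "resolved"),
  positive = c("definite", "active", "악화"),
  obscure  = c("suspicious", "의심", "cannot exclude")
)

# English disease-noun surfaces; the guaranteed set passes default_lexicon()
.lexeme_surfaces <- c("pneumonia", "consolidation", "infiltration",
                      "bronchiole", "haziness", "hazziness", "opacity", "GGO")
.extra_nouns <- c("bronchopneumonia", "aspiration", "atelectasis", "effusion")

# fixed Hangul/Latin template pairs (function words and common findings)
.template_pairs <- function() {
  hangul <- c("소견", "관찰", "보임", "비교",
              "이전", "변화", "증가", "감소",
              "양측", "우측", "좌측", "흉부",
              "폐", "음영", "결절", "흉수",
              "심장", "정상", "상태", "검사")
  latin <- c("finding", "observed", "seen", "comparison",
             "previous", "change", "increase", "decrease",
             "bilateral", "right", "left", "chest",
             "lung", "shadow", "nodule", "pleural",
             "heart", "normal", "status", "exam")
  data.frame(hangul = hangul, latin = latin, stringsAsFactors = FALSE)
}

# random Hangul syllable strings (2-3 syllables) and CV-pattern Latin words
.make_filler_pairs <- function(n) {
  reserved <- c(unlist(.cue_sets), .lexeme_surfaces, .extra_nouns,
                .template_pairs()$latin)
  reserved <- unique(unlist(strsplit(tolower(reserved), " ", fixed = TRUE)))
  cons <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  hangul <- character(n); latin <- character(n)
  seen_h <- character(); seen_l <- character()
  i <- 1L
  while (i <= n) {
    ns <- sample(2:3, 1)
    h <- intToUtf8(0xAC00 + sample.int(11172, ns) - 1L)
    nl <- sample(2:4, 1)
    l <- paste0(vapply(seq_len(nl), function(j) {
      paste0(sample(cons, 1), sample(vow, 1))
    }, character(1)), collapse = "")
    if (h %in% seen_h || l %in% seen_l || l %in% reserved) next
    hangul[i] <- h; latin[i] <- l
    seen_h <- c(seen_h, h); seen_l <- c(seen_l, l)
    i <- i + 1L
  }
  data.frame(hangul = hangul, latin = latin, stringsAsFactors = FALSE)
}

#' Cue phrases and guaranteed lexeme surfaces of the generator
#'
#' Exposes the generator's internals that tests and attention analyses need:
#' the cue phrases for each label and the disease-noun surfaces guaranteed
#' to pass [default_lexicon()].
#'
#' @return A list with elements `cues` (named list of character vectors per
#'   label), `cue_tokens` (all normalized single tokens occurring in cues),
#'   and `lexemes` (guaranteed noun surfaces).
#' @export
synth_cue_lexicon <- function() {
  list(
    cues = .cue_sets,
    cue_tokens = unique(unlist(strsplit(tolower(unlist(.cue_sets)), " "))),
    lexemes = .lexeme_surfaces
  )
}

# the shared bilingual concept vocabulary: templates first, then fillers,
# with Zipf-like weights shared by both scripts, plus a shared concept-level
# Markov chain (each concept prefers a small fixed successor set) that gives
# every concept an individual co-occurrence signature — without it, words of
# similar frequency inside a topic are distributionally exchangeable and no
# algorithm could align them across languages
.concept_table <- function(config) {
  with_seed(config$seed + 101L, {
    fill <- .make_filler_pairs(config$filler_vocab_size)
    dict <- rbind(.template_pairs(), fill)
    n <- nrow(dict)
    dict$weight <- 1 / (seq_len(n) + 2)^1.3
    dict$topic <- rep_len(1:8, n)
    # preferential attachment: frequent concepts collect most in-links, so
    # the chain's stationary distribution keeps a well-separated Zipf shape
    # (rank-matched across languages) while each concept still has its own
    # successor signature
    succ <- lapply(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      sample(others, 4, prob = dict$weight[others])
    })
    attr(dict, "successors") <- succ
    dict
  })
}

#' Generate a labeled synthetic bilingual report corpus
#'
#' Each report is 8-60 tokens long, mixes Hangul function words with Latin
#' fillers and English disease nouns, contains at least one pneumonia lexeme
#' (so it passes [keyword_filter()] by construction), and carries exactly one
#' label-determining cue phrase. With probability `cue_noise` the emitted cue
#' conflicts with the label.
#'
#' @param config A [synth_config()].
#' @param order_coded If `TRUE`, positive and obscure reports are instead
#'   distinguished purely by the order of a two-token marker (`"interval
#'   aggravation"` vs `"aggravation interval"`), a regime in which any
#'   bag-of-words representation is blind to the positive/obscure contrast.
#' @return A list with `reports` (a report data frame with an extra `cue`
#'   column recording the emitted cue phrase) and `dictionary` (the
#'   ground-truth Hangul/Latin pairs, for evaluating — never training — the
#'   cross-lingual mapping).
#' @export
generate_corpus <- function(config, order_coded = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dict <- .concept_table(config)
  n <- config$n_reports
  with_seed(config$seed + 202L, {
    labels <- sample(.LABELS, n, replace = TRUE, prob = config$class_priors)
    rows <- lapply(seq_len(n), function(i) {
      lab <- labels[i]
      cue_class <- lab
      if (runif(1) < config$cue_noise) {
        cue_class <- sample(setdiff(.LABELS, lab), 1)
      }
      cue <- if (order_coded && cue_class != "negative") {
        if (cue_class == "positive") "interval aggravation" else "aggravation interval"
      } else if (order_coded) {
        sample(.cue_sets$negative, 1)
      } else {
        sample(.cue_sets[[cue_class]], 1)
      }
      len <- sample(8:60, 1)
      n_nouns <- sample(1:3, 1)
      nouns <- c(sample(.lexeme_surfaces, 1),
                 sample(c(.lexeme_surfaces, .extra_nouns), n_nouns - 1,
                        replace = TRUE))
      n_fill <- max(len - n_nouns - length(strsplit(cue, " ")[[1]]), 2L)
      ridx <- sample.int(nrow(dict), n_fill, replace = TRUE, prob = dict$weight)
      use_hangul <- runif(n_fill) < config$korean_fraction
      fillers <- ifelse(use_hangul, dict$hangul[ridx], dict$latin[ridx])
      units <- c(fillers, nouns)
      units <- sample(units)                      # shuffle content words
      pos <- sample.int(length(units) + 1L, 1)    # insert cue phrase
      units <- append(units, cue, after = pos - 1L)
      data.frame(
        id = sprintf("synth-%05d", i),
        modality = sample(c("CT", "XRAY"), 1, prob = c(0.4, 0.6)),
        text = paste(units, collapse = " "),
        label = lab,
        cue = cue,
        stringsAsFactors = FALSE
      )
    })
    reports <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(reports)) {
      reports <- data.frame(id = character(), modality = character(),
                            text = character(), label = character(),
                            cue = character(), stringsAsFactors = FALSE)
    }
    list(reports = reports, dictionary = dict[c("hangul", "latin")])
  })
}

#' Generate distributionally parallel monolingual corpora
#'
#' Produces one Hangul and one Latin corpus by running the same concept-level
#' Markov chain (shared successor preferences over the concept vocabulary),
#' sampled independently per language. Dictionary mates therefore have
#' matching expected frequencies and word-specific co-occurrence signatures —
#' the comparable-corpora setting in which an unsupervised embedding
#' alignment is learnable — without any sentence being a translation of
#' another. Language-specific extras (English disease nouns and the cue
#' tokens of each script) are mixed in so that downstream report tokens are
#' in-vocabulary.
#'
#' @param config A [synth_config()]; `n_reports` sets the number of
#'   sentences per corpus.
#' @return A list with `hangul` and `latin` (each a list of character token
#'   vectors) and `dictionary` (the ground-truth pairs).
#' @export
generate_monolingual_corpora <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dict <- .concept_table(config)
  # language-specific extras (cue tokens, disease nouns, Hangul particles)
  # each receive the same small per-word share in both corpora, so they sit
  # in the tail of the frequency ranking and do not disturb rank alignment
  extras <- list(
    hangul = unique(c(
      unlist(strsplit(unlist(lapply(.cue_sets, function(x) {
        x[grepl("[가-힣]", x)]
      })), " ")),
      c("있음", "되어", "관련", "다소", "경미", "심한", "흔적",
        "추적", "소량", "다량", "약간", "재검", "동반"))),
    latin = unique(c(tolower(.lexeme_surfaces), .extra_nouns,
                     "interval", "aggravation",  # order-coded regime markers
                     unlist(strsplit(tolower(unlist(lapply(.cue_sets, function(x) {
                       x[!grepl("[가-힣]", x)]
                     }))), " "))))
  )
  # Sentences are random walks of the SHARED concept-level Markov chain:
  # from concept i the walk moves to one of i's fixed preferred successors
  # (probability 0.75) or teleports to the Zipf marginal. Both corpora use
  # the identical chain over concept indices but are sampled independently,
  # so dictionary mates share expected frequencies (rank-matched up to
  # sampling noise) and word-specific co-occurrence signatures, while no
  # sentence is a translation of another. Language-specific extras are
  # interspersed at a small, per-word-constant rate.
  succ <- attr(dict, "successors")
  gen <- function(lang, seed_off) {
    forms <- dict[[lang]]
    ex <- extras[[lang]]
    n_sent <- config$n_reports
    if (n_sent == 0) return(list())
    p_extra <- 0.004 * length(ex)
    nc <- nrow(dict)
    with_seed(config$seed + seed_off, {
      lapply(seq_len(n_sent), function(s) {
        len <- sample(25:40, 1)
        toks <- character(len)
        cur <- sample.int(nc, 1, prob = dict$weight)
        for (j in seq_len(len)) {
          if (runif(1) < p_extra) {
            toks[j] <- ex[sample.int(length(ex), 1)]
            next
          }
          toks[j] <- forms[cur]
          cur <- if (runif(1) < 0.75) {
            succ[[cur]][sample.int(4, 1)]
          } else {
            sample.int(nc, 1, prob = dict$weight)
          }
        }
        toks
      })
    })
  }
  list(hangul = gen("hangul", 303L), latin = gen("latin", 404L),
       dictionary = dict[c("hangul", "latin")])
}

#' Planted-rotation fixture for the mapping oracle
#'
#' Draws a random `n_words x dim` Gaussian source matrix, a random orthogonal
#' `dim x dim` transform, and sets `target = source %*% transform + noise`.
#' Recovering the transform from the pairing is the ground-truth test for
#' [procrustes()].
#'
#' @param n_words Number of rows; must be at least `dim`.
#' @param dim Embedding dimension (at least 2).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return A list of class `planted_rotation` with elements `source`,
#'   `target`, `transform`, `noise_sd`.
#' @export
generate_planted_rotation <- function(n_words, dim, noise_sd = 0, seed = 1L) {
  stopifnot(dim >= 2, noise_sd >= 0)
  if (n_words < dim) stop("n_words must be >= dim (underdetermined otherwise)")
  with_seed(as.integer(seed) + 505L, {
    q <- qr(matrix(rnorm(dim * dim), dim, dim))
    Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))), dim)  # Haar-uniform rotation
    S <- matrix(rnorm(n_words * dim), n_words, dim)
    Tm <- S %*% Q
    if (noise_sd > 0) Tm <- Tm + matrix(rnorm(n_words * dim, sd = noise_sd),
                                        n_words, dim)
    structure(list(source = S, target = Tm, transform = Q,
                   noise_sd = noise_sd), class = "planted_rotation")
  })
}

#' Simulate an independent second annotator
#'
#' Relabels each report with a per-class disagreement probability: with
#' probability `disagreement_rate[class]` the second annotator assigns a
#' uniformly random *other* label. Used to exercise [cohens_kappa()].
#'
#' @param reports A labeled report data frame.
#' @param disagreement_rate Numeric 3-vector of per-class disagreement
#'   probabilities, in the (negative, positive, obscure) order.
#' @param seed Integer seed.
#' @return Character vector of second-annotator labels.
#' @export
simulate_second_annotator <- function(reports, disagreement_rate, seed = 1L) {
  stopifnot(is.data.frame(reports))
  if (length(disagreement_rate) != 3 || any(disagreement_rate < 0) ||
      any(disagreement_rate > 1)) {
    stop("disagreement_rate must be 3 probabilities")
  }
  labels <- .validate_label(reports$label, allow_na = FALSE)
  rates <- setNames(as.numeric(disagreement_rate), .LABELS)
  with_seed(as.integer(seed) + 606L, {
    vapply(labels, function(lab) {
      if (runif(1) < rates[[lab]]) sample(setdiff(.LABELS, lab), 1) else lab
    }, character(1), USE.NAMES = FALSE)
  })
}

#' A cue-reading rule classifier
#'
#' Labels a report by the class of the first cue phrase found in its text;
#' reports with no cue get `NA`. At `cue_noise = 0` this rule recovers the
#' generated labels exactly, which pins down the generator's cue-label
#' contract.
#'
#' @param text Character vector of report texts.
#' @return Character vector of labels (or `NA` where no cue is present).
#' @export
rule_cue_classifier <- function(text) {
  vapply(text, function(x) {
    toks <- tokenize(x)$norm
    joined <- paste0(" ", paste(toks, collapse = " "), " ")
    for (lab in .LABELS) {
      for (cue in .cue_sets[[lab]]) {
        cue_n <- paste(normalize_token(strsplit(cue, " ")[[1]]), collapse = " ")
        if (grepl(paste0(" ", cue_n, " "), joined, fixed = TRUE)) return(lab)
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
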
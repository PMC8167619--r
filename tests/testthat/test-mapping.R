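test_that("procrustes recovers identity and planted rotations", {
  set.seed(2)
  S <- matrix(rnorm(60), 20, 3)
  expect_lt(max(abs(procrustes(S, S) - diag(3))), 1e-10)

  fx <- generate_planted_rotation(100, 10, 0, seed = 3)
  W <- procrustes(fx$source, fx$target)
  expect_lt(norm(W - fx$transform, "F"), 1e-6)

  expect_error(procrustes(matrix(1, 1, 2), matrix(1, 1, 2)), "point pairs")
  expect_warning(procrustes(matrix(rep(1, 20), 10, 2),
                            matrix(rep(1, 20), 10, 2)), "rank")
})

test_that("procrustes matches a brute-force rotation search in 2-D", {
  set.seed(7)
  for (rep in 1:5) {
    fx <- generate_planted_rotation(40, 2, 0.05, seed = rep)
    W <- procrustes(fx$source, fx$target)
    obj <- function(M) norm(fx$source %*% M - fx$target, "F")
    # grid over rotations and reflections at 1e-3 rad resolution
    thetas <- seq(0, 2 * pi, by = 1e-3)
    best <- Inf
    for (th in thetas) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      best <- min(best, obj(R), obj(R %*% diag(c(1, -1))))
    }
    expect_lte(obj(W), best + 1e-6)
  }
})

test_that("noisy planted rotations are recovered within tolerance (5 seeds)", {
  for (sd in 1:5) {
    fx <- generate_planted_rotation(100, 10, 0.01, seed = sd)
    W <- procrustes(fx$source, fx$target)
    expect_lt(norm(W - fx$transform, "F"), 0.1)
  }
})

test_that("CSLS ranks an exact match first and demotes hubs", {
  targets <- rbind(c(1, 0), c(0, 1))
  out <- csls_neighbors(c(1, 0), targets, k = 1, sources = targets)
  expect_equal(out$index[1], 1)
  expect_error(csls_neighbors(c(1, 0), targets, k = 3, sources = targets), "k must")

  # 3-vector construction: target 2 sits between the spread-out sources (a
  # hub, moderately close to all of them) while target 1 is close to the
  # query source only. CSLS charges the hub its larger neighborhood term.
  # Hand-computed from the cosine table.
  s2 <- sqrt(2) / 2
  sources <- rbind(c(1, 0), c(0, 1), c(-s2, s2))
  targets <- rbind(c(0.998, sqrt(1 - 0.998^2)), c(s2, s2), c(0, 1))
  query <- sources[1, ]
  cs <- drop(targets %*% query)
  out <- csls_neighbors(query, targets, k = 2, sources = sources)
  r_t <- mean(sort(cs, decreasing = TRUE)[1:2])
  st <- sources %*% t(targets)
  r_s <- apply(st, 2, function(col) mean(sort(col, decreasing = TRUE)[1:2]))
  expect_gt(r_s[2], r_s[1])  # the hub carries the larger neighborhood penalty
  hand <- 2 * cs - r_t - r_s
  expect_equal(out$score, sort(hand, decreasing = TRUE))
  expect_equal(out$index, order(-hand))
  expect_equal(out$index[1], 1)  # exact match still wins under CSLS
})

test_that("dictionary induction on a planted fixture recovers the pairing", {
  fx <- generate_planted_rotation(60, 8, 0, seed = 5)
  src <- fx$source; tgt <- fx$target
  rownames(src) <- paste0("h", 1:60)
  rownames(tgt) <- paste0("e", 1:60)
  pairs <- induce_dictionary(src, tgt, fx$transform, k = 10)
  ref <- data.frame(source = paste0("h", 1:60), target = paste0("e", 1:60))
  expect_gte(mapping_precision(pairs, ref), 0.9)
  expect_lte(nrow(induce_dictionary(src, tgt, fx$transform, k = 10,
                                    max_pairs = 5)), 5)
  expect_warning(induce_dictionary(src, tgt, matrix(0, 8, 8), k = 10),
                 "zero transform")
})

test_that("seed dictionaries come from shared surfaces, ranks, or a TSV", {
  emb_a <- matrix_embedding(matrix(rnorm(40), 4, 10,
                                   dimnames = list(c("ggo", "ct", "소견", "흉부"),
                                                   NULL)))
  emb_b <- matrix_embedding(matrix(rnorm(40), 4, 10,
                                   dimnames = list(c("ggo", "ct", "lung", "chest"),
                                                   NULL)))
  ident <- seed_dictionary(emb_a, emb_b, "identical")
  expect_setequal(ident$source, c("ggo", "ct"))
  expect_identical(ident$source, ident$target)

  emb_c <- matrix_embedding(matrix(rnorm(30), 3, 10,
                                   dimnames = list(c("가", "나", "다"), NULL)))
  emb_d <- matrix_embedding(matrix(rnorm(30), 3, 10,
                                   dimnames = list(c("x", "y", "z"), NULL)))
  expect_error(seed_dictionary(emb_c, emb_d, "identical"), "FREQUENCY|frequency")

  freq <- seed_dictionary(emb_c, emb_d, "frequency", max_pairs = 2)
  expect_identical(freq$source, c("가", "나"))
  expect_identical(freq$target, c("x", "y"))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("가\tz", "나\tmissing"), tsv)
  sup <- seed_dictionary(emb_c, emb_d, "tsv", tsv_path = tsv)
  expect_equal(nrow(sup), 1)  # pairs outside both vocabularies are dropped
  expect_identical(sup$target, "z")
})

test_that("frequency seeding on the synthetic corpora beats chance comfortably", {
  cfg <- synth_config(seed = 1)  # generator defaults
  mono <- generate_monolingual_corpora(cfg)
  ec <- embedding_config(dim = 8, epochs = 1, min_count = 5,
                         ngram_min = 5, ngram_max = 6, seed = 1)
  emb_l <- train_subword_embeddings(mono$latin, ec)
  emb_h <- train_subword_embeddings(mono$hangul, ec)
  seeds <- seed_dictionary(emb_h, emb_l, "frequency")  # default top 30
  expect_gte(mapping_precision(seeds, mono$dictionary), 0.5)
})

test_that("mapping training refines a planted fixture to a perfect dictionary", {
  fx <- generate_planted_rotation(80, 10, 0, seed = 9)
  src <- fx$source; tgt <- fx$target
  rownames(src) <- paste0("h", 1:80)
  rownames(tgt) <- paste0("e", 1:80)
  ref <- data.frame(source = paste0("h", 1:80), target = paste0("e", 1:80))
  seed_pairs <- ref[1:20, ]
  model <- train_mapping(src, tgt, seed_pairs, iterations = 3, k = 10,
                         reference = ref)
  expect_s3_class(model, "kor2eng")
  expect_equal(tail(model$history$precision, 1), 1.0)
  # refinement never decreases precision on the planted fixture
  expect_true(all(diff(model$history$precision) >= -1e-12))
  # orthogonality after every step (final transform checked here)
  expect_lt(max(abs(crossprod(model$transform) - diag(10))), 1e-6)
})

test_that("iterations = 0 reduces to pure Procrustes on the seed pairs", {
  fx <- generate_planted_rotation(50, 6, 0.02, seed = 2)
  src <- fx$source; tgt <- fx$target
  rownames(src) <- paste0("h", 1:50)
  rownames(tgt) <- paste0("e", 1:50)
  seed_pairs <- data.frame(source = paste0("h", 1:30),
                           target = paste0("e", 1:30))
  model <- train_mapping(src, tgt, seed_pairs, iterations = 0, k = 5)
  unit <- function(m) m / sqrt(rowSums(m^2))
  prep <- function(m) {
    m <- unit(m)
    unit(scale(m, center = TRUE, scale = FALSE))
  }
  direct <- procrustes(prep(src)[1:30, ], prep(tgt)[1:30, ])
  expect_equal(model$transform, direct, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(model$iterations_run, 0)
})

test_that("a collapsing dictionary raises an error naming the iteration", {
  src <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("h", 1:6), NULL))
  tgt <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("e", 1:6), NULL))
  pairs <- data.frame(source = paste0("h", 1:6), target = paste0("e", 1:6))
  expect_error(train_mapping(src, tgt, pairs[1:4, ], iterations = 1),
               "iteration")
})

test_that("translation preserves vectors under identity and norms in general", {
  emb <- toy_embedding(c("소견", "흉부", "관찰"), dim = 6)
  ident <- translate_embedding(emb, diag(6))
  expect_equal(ident$word_vec, emb$word_vec)

  fx <- generate_planted_rotation(10, 6, 0, seed = 4)
  tr <- translate_embedding(emb, fx$transform)
  expect_equal(sqrt(rowSums(tr$word_vec^2)), sqrt(rowSums(emb$word_vec^2)),
               tolerance = 1e-6)
  expect_equal(sqrt(rowSums(tr$ngram_vec^2)), sqrt(rowSums(emb$ngram_vec^2)),
               tolerance = 1e-6)

  # planted fixture: mapped source matches the target up to the noise level
  fx2 <- generate_planted_rotation(40, 8, 0.01, seed = 6)
  mapped <- fx2$source %*% procrustes(fx2$source, fx2$target)
  expect_lt(max(abs(mapped - fx2$target)), 0.1)
})

test_that("mapping models save and load as TSV", {
  fx <- generate_planted_rotation(30, 5, 0, seed = 8)
  src <- fx$source; tgt <- fx$target
  rownames(src) <- paste0("h", 1:30)
  rownames(tgt) <- paste0("e", 1:30)
  model <- train_mapping(src, tgt,
                         data.frame(source = paste0("h", 1:10),
                                    target = paste0("e", 1:10)),
                         iterations = 1, k = 5)
  path <- tempfile(fileext = ".tsv")
  save_mapping(model, path)
  back <- load_mapping(path)
  expect_equal(back$transform, model$transform, tolerance = 1e-10)
  expect_equal(back$csls_k, model$csls_k)
  expect_equal(back$induced_dictionary$source, model$induced_dictionary$source)
})
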
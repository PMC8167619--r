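# fast settings shared by the training tests in this file
fast_config <- function(seed = 1, max_epochs = 40, ...) {
  classifier_config(hidden = 24, attention_dim = 24, dropout = 0.2,
                    learning_rate = 3e-3, max_epochs = max_epochs,
                    patience = 5, batch_size = 32, seed = seed, ...)
}

test_that("encode follows the script-routing and padding contract", {
  emb_l <- toy_embedding(c("ggo", "seen", "chest"), dim = 6)
  emb_h <- toy_embedding(c("의심", "소견"), dim = 6)

  # all-Latin report: the mapping must not matter
  e1 <- encode(c("ggo", "seen"), emb_l, emb_h, mapping = diag(6), max_len = 4)
  e2 <- encode(c("ggo", "seen"), emb_l, max_len = 4)
  expect_equal(e1$vectors, e2$vectors)
  expect_equal(e1$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(e1$n_tokens, 2)

  # truncation keeps the first max_len tokens
  e3 <- encode(c("ggo", "seen", "chest"), emb_l, max_len = 2)
  expect_equal(nrow(e3$vectors), 2)
  expect_equal(e3$vectors[1, ], unname(e1$vectors[1, ]))

  # Hangul token with the identity mapping: equals its raw source vector
  e4 <- encode("의심", emb_l, emb_h, mapping = diag(6), max_len = 2)
  expect_equal(e4$vectors[1, ], as.numeric(embedding_vector(emb_h, "의심")))

  # and with a real rotation: x %*% W
  fx <- generate_planted_rotation(8, 6, 0, seed = 1)
  e5 <- encode("의심", emb_l, emb_h, mapping = fx$transform, max_len = 2)
  expect_equal(e5$vectors[1, ],
               drop(as.numeric(embedding_vector(emb_h, "의심")) %*% fx$transform))
})

test_that("forward pass satisfies the attention and masking contracts", {
  model <- new_attn_bilstm(classifier_config(hidden = 8, seed = 3),
                           input_dim = 5)
  x1 <- matrix(rnorm(5), 1, 5)
  p1 <- forward_pass(model, x1)
  expect_equal(p1$attention_weights, 1.0)      # softmax over one position
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)

  # appending pad positions never changes probabilities
  set.seed(4)
  x <- matrix(rnorm(4 * 5), 4, 5)
  p <- forward_pass(model, x)
  xp <- rbind(x, matrix(0, 3, 5))
  pp <- forward_pass(model, xp, mask = c(rep(TRUE, 4), rep(FALSE, 3)))
  expect_equal(p$probabilities, pp$probabilities, tolerance = 1e-12)
  expect_equal(p$attention_weights, pp$attention_weights, tolerance = 1e-12)
  expect_equal(sum(p$attention_weights), 1, tolerance = 1e-9)
  expect_true(all(p$attention_weights >= 0))

  # zeroed output layer: exactly uniform probabilities
  model$par$Wo[] <- 0
  model$par$bo[] <- 0
  pz <- forward_pass(model, x)
  expect_equal(unname(pz$probabilities), rep(1 / 3, 3))
  # argmax tie broken by class order
  expect_equal(pz$predicted_label, "negative")

  expect_error(forward_pass(model, x, mask = rep(FALSE, 4)), "masked")
})

test_that("analytic gradients match finite differences", {
  par <- bilingrad:::.init_params(3, 4, 3, 3, seed = 9)
  set.seed(42)
  Tn <- 5
  X <- lapply(1:Tn, function(t) matrix(rnorm(2 * 3), 2, 3))
  mask <- matrix(1, 2, Tn); mask[2, 4:5] <- 0
  y <- c(2L, 3L)
  lossfn <- function(p) {
    fwd <- bilingrad:::.forward_batch(p, X, mask, dropout = 0, train = FALSE)
    bilingrad:::.ce_loss(fwd$probs, y)
  }
  fwd <- bilingrad:::.forward_batch(par, X, mask, dropout = 0, train = FALSE)
  g <- bilingrad:::.backward_batch(par, X, fwd, y, need_dx = TRUE)
  eps <- 1e-6
  for (nm in names(par)) {
    idx <- if (length(par[[nm]]) > 4) sample(length(par[[nm]]), 4) else
      seq_along(par[[nm]])
    for (i in idx) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- par; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
  # input gradients (used when fine-tuning embeddings)
  X2 <- X; X2[[2]][1, 3] <- X2[[2]][1, 3] + eps
  X3 <- X; X3[[2]][1, 3] <- X3[[2]][1, 3] - eps
  f2 <- bilingrad:::.forward_batch(par, X2, mask, 0, FALSE)
  f3 <- bilingrad:::.forward_batch(par, X3, mask, 0, FALSE)
  num <- (bilingrad:::.ce_loss(f2$probs, y) -
            bilingrad:::.ce_loss(f3$probs, y)) / (2 * eps)
  expect_equal(g$dX[[2]][1, 3], num, tolerance = 1e-4)
})

test_that("stratified splits hit the per-class arithmetic", {
  reports <- data.frame(
    id = as.character(1:100), modality = "CT", text = "GGO",
    label = rep(report_labels(), c(60, 30, 10)), stringsAsFactors = FALSE
  )
  sp <- stratified_split(reports, 0.2, seed = 1)
  expect_equal(unname(table(factor(sp$test$label, report_labels()))[1:3]),
               c(12, 6, 2), ignore_attr = TRUE)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  expect_length(intersect(sp$train$id, sp$test$id), 0)

  # the study's class sizes give the study's printed test-set sizes
  big <- data.frame(id = as.character(1:5450), modality = "CT", text = "x",
                    label = rep(report_labels(), c(4005, 895, 550)),
                    stringsAsFactors = FALSE)
  spb <- stratified_split(big, 0.2, seed = 3)
  expect_equal(unname(c(table(factor(spb$test$label, report_labels())))),
               c(801, 179, 110))

  expect_identical(stratified_split(reports, 0.2, seed = 9)$test$id,
                   stratified_split(reports, 0.2, seed = 9)$test$id)
  few <- reports[reports$label != "obscure", ]
  expect_warning(stratified_split(few, 0.2, seed = 1), "obscure")
})

fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    fx <- small_pipeline_fixture(n = 500, seed = 7, cue_noise = 0, dim = 16,
                                 epochs = 10)
    sp <- stratified_split(fx$corpus$reports, 0.2, seed = 7)
    model <- attn_bilstm(sp$train, fx$emb_l, fx$emb_h, fx$mapping,
                         config = fast_config(seed = 7))
    fixture_env$fx <- list(fx = fx, split = sp, model = model)
  }
  fixture_env$fx
}

test_that("the classifier learns a cue-deterministic corpus", {
  f <- get_fixture()
  preds <- predict(f$model, f$split$test)
  acc <- mean(vapply(preds, function(p) p$predicted_label, "") ==
                f$split$test$label)
  expect_gte(acc, 0.9)
  # structural invariants on every prediction
  for (p in preds) {
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-6)
    expect_equal(sum(p$attention_weights), 1, tolerance = 1e-6)
    expect_true(all(p$attention_weights >= 0))
    expect_equal(p$predicted_label,
                 report_labels()[which.max(p$probabilities)])
  }
  # early stopping bookkeeping: best epoch no worse than the first
  h <- f$model$history
  expect_lte(h$val_loss[f$model$best_epoch], h$val_loss[1])
})

test_that("predictions are batch-invariant and order-preserving", {
  f <- get_fixture()
  test20 <- head(f$split$test, 20)
  p_big <- predict(f$model, test20, batch_size = 32)
  p_one <- predict(f$model, test20, batch_size = 1)
  for (i in seq_len(20)) {
    expect_equal(p_big[[i]]$probabilities, p_one[[i]]$probabilities,
                 tolerance = 1e-6)
  }
  shuf <- c(5, 1, 3)
  p_shuf <- predict(f$model, test20[shuf, ])
  for (j in seq_along(shuf)) {
    expect_equal(p_shuf[[j]]$probabilities,
                 p_big[[shuf[j]]]$probabilities, tolerance = 1e-8)
  }
  expect_identical(predict(f$model, f$split$test[0, ]), list())
})

test_that("checkpoints reproduce in-memory predictions exactly", {
  f <- get_fixture()
  path <- tempfile(fileext = ".rds")
  save_classifier(f$model, path)
  back <- load_classifier(path)
  p1 <- predict(f$model, head(f$split$test, 5))
  p2 <- predict(back, head(f$split$test, 5))
  for (i in 1:5) {
    expect_identical(p1[[i]]$probabilities, p2[[i]]$probabilities)
  }
  expect_error(suppressWarnings(load_classifier(tempfile())),
               "cannot open|checkpoint")
})

test_that("attention concentrates on cue and lexeme tokens (explanation property)", {
  f <- get_fixture()
  preds <- predict(f$model, f$split$test)
  marker <- c(synth_cue_lexicon()$cue_tokens,
              tolower(synth_cue_lexicon()$lexemes))
  correct <- which(vapply(preds, function(p) p$predicted_label, "") ==
                     f$split$test$label)
  hit <- vapply(correct, function(i) {
    p <- preds[[i]]
    top3 <- p$tokens[order(-p$attention_weights)[1:min(3, p$token_count)]]
    any(top3 %in% marker)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("the untrained model refuses to predict and the trained one prints", {
  raw <- new_attn_bilstm(classifier_config(hidden = 4), input_dim = 3)
  expect_error(predict(raw, "GGO seen"), "not trained")
  f <- get_fixture()
  expect_output(print(f$model), "Attention Bi-LSTM")
  expect_s3_class(f$model$history, "data.frame")
  expect_identical(coef(f$model), f$model$par)
})

test_that("the bag-of-substrings baseline behaves and is deterministic", {
  f <- get_fixture()
  m1 <- baseline_logistic(f$split$train, f$split$test)
  m2 <- baseline_logistic(f$split$train, f$split$test)
  expect_identical(attr(m1, "probabilities"), attr(m2, "probabilities"))
  expect_gte(m1$accuracy, 0.9)  # cue tokens are visible to a bag model

  one_class <- f$split$train[f$split$train$label == "negative", ]
  mono <- baseline_logistic(one_class, f$split$test)
  probs <- attr(mono, "probabilities")
  expect_true(all(probs[, "negative"] == 1))
})

test_that("the recurrent model beats the bag baseline when obscure is order-coded", {
  # same generator seed as the shared fixture, so its embeddings cover the
  # concept vocabulary; only the report stream differs (order-coded cues)
  cfg <- synth_config(n_reports = 700, cue_noise = 0, seed = 7)
  corp <- generate_corpus(cfg, order_coded = TRUE)
  fx <- get_fixture()$fx
  sp <- stratified_split(corp$reports, 0.25, seed = 21)
  base <- baseline_logistic(sp$train, sp$test)
  model <- attn_bilstm(sp$train, fx$emb_l, fx$emb_h, fx$mapping,
                       config = fast_config(seed = 21))
  preds <- predict(model, sp$test)
  ours <- evaluate(preds, sp$test$label)
  expect_gt(ours$per_class$obscure$f1, base$per_class$obscure$f1)
})
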
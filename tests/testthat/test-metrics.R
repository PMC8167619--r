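test_that("confusion counts true-by-predicted in canonical order", {
  cm <- confusion(c("negative", "positive", "obscure", "negative"),
                  c("negative", "obscure", "obscure", "positive"))
  expect_equal(unclass(cm)[, ],
               matrix(c(1, 0, 0, 1, 0, 0, 0, 1, 1), 3, 3,
                      dimnames = dimnames(cm)),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4)

  ident <- confusion(rep(report_labels(), 2), rep(report_labels(), 2))
  expect_true(all(unclass(ident)[upper.tri(ident) | lower.tri(ident)] == 0))

  empty <- confusion(character(0), character(0))
  expect_true(all(unclass(empty) == 0))
  expect_error(confusion("negative", c("negative", "positive")), "length")
})

test_that("one-vs-rest precision/recall/F1 reproduce the printed study rows", {
  # proposed-model Negative row: 776/809 predicted, 776/801 actual
  neg <- f1_from_counts(776, 809, 801)
  expect_equal(neg$precision_pct, 95.9)
  expect_equal(neg$recall_pct, 96.9)
  expect_equal(neg$f1_pct, 96)
  # proposed-model Obscure row: 70/115 predicted, 70/110 actual
  obs <- f1_from_counts(70, 115, 110)
  expect_equal(obs$precision_pct, 60.9)
  expect_equal(obs$recall_pct, 63.6)
  expect_equal(obs$f1_pct, 62)
})

test_that("one_vs_rest_prf handles perfect and degenerate confusion matrices", {
  perfect <- confusion(rep(report_labels(), 5), rep(report_labels(), 5))
  for (cls in report_labels()) {
    expect_equal(as.numeric(one_vs_rest_prf(perfect, cls)), c(1, 1, 1))
  }
  # nothing predicted as obscure -> precision 0/0 -> 0 with flag
  cm <- confusion(c("negative", "obscure"), c("negative", "negative"))
  prf <- one_vs_rest_prf(cm, "obscure")
  expect_equal(as.numeric(prf), c(0, 0, 0))
  expect_true(attr(prf, "zero_division"))
})

test_that("f1 is the harmonic mean, between precision and recall", {
  set.seed(4)
  for (i in 1:50) {
    y <- sample(report_labels(), 60, replace = TRUE)
    p <- sample(report_labels(), 60, replace = TRUE)
    cm <- confusion(y, p)
    for (cls in report_labels()) {
      prf <- one_vs_rest_prf(cm, cls)
      expect_gte(prf["f1"] + 1e-12, min(prf["precision"], prf["recall"]))
      expect_lte(prf["f1"] - 1e-12, max(prf["precision"], prf["recall"]))
      if (prf["precision"] + prf["recall"] > 0) {
        expect_equal(unname(prf["f1"]),
                     2 * prf[["precision"]] * prf[["recall"]] /
                       (prf[["precision"]] + prf[["recall"]]))
      }
    }
  }
})

test_that("accuracy is trace over total and errors on empty input", {
  perfect <- confusion(rep(report_labels(), 4), rep(report_labels(), 4))
  expect_equal(accuracy(perfect), 1)
  wrong <- confusion(c("negative", "positive"), c("positive", "negative"))
  expect_equal(accuracy(wrong), 0)
  cm <- confusion(c("negative", "negative", "positive", "obscure"),
                  c("negative", "positive", "positive", "negative"))
  expect_equal(accuracy(cm), 2 / 4)
  expect_error(accuracy(confusion(character(0), character(0))), "empty")
})

test_that("auroc equals brute-force pair counting and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  pair_count_auc <- function(s, y) {  # O(n^2) oracle
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) y[1:2] <- c(TRUE, FALSE)
    expect_equal(auroc(s, y), pair_count_auc(s, y), tolerance = 1e-12)
  }
})

test_that("auprc is non-interpolated average precision", {
  expect_equal(auprc(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE)), 1)
  # hand example: ranked y = (1, 0, 1, 0, 1)
  # AP = (1/1 + 2/3 + 3/5) / 3
  s <- c(5, 4, 3, 2, 1)
  y <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(auprc(s, y), (1 + 2 / 3 + 3 / 5) / 3)
  expect_error(auprc(1:3, rep(FALSE, 3)), "positive")
})

test_that("auprc of random scores approaches prevalence", {
  set.seed(123)
  n <- 10000
  prev <- 0.3
  y <- runif(n) < prev
  s <- runif(n)
  expect_equal(auprc(s, y), mean(y), tolerance = 0.02)
})

test_that("Cohen's kappa matches hand computations and is symmetric", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1,
               ignore_attr = TRUE)
  # p_o = 0.5, p_e = 0.5 -> kappa 0
  a <- c("P", "P", "N", "N")
  b <- c("P", "N", "P", "N")
  expect_equal(cohens_kappa(a, b), 0)
  # complete disagreement, balanced binary -> -1
  expect_equal(cohens_kappa(c("P", "N"), c("N", "P")), -1)
  set.seed(5)
  x <- sample(report_labels(), 30, TRUE)
  y <- sample(report_labels(), 30, TRUE)
  expect_equal(cohens_kappa(x, y), cohens_kappa(y, x))
  # both raters constant and identical: degenerate, defined as 1
  k <- cohens_kappa(c("a", "a"), c("a", "a"))
  expect_equal(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
})

test_that("evaluate assembles per-class metrics; micro recall equals accuracy", {
  set.seed(8)
  n <- 200
  truth <- sample(report_labels(), n, TRUE, prob = c(0.6, 0.25, 0.15))
  probs <- matrix(runif(3 * n), n, 3)
  hit <- runif(n) < 0.7  # make scores informative
  probs[cbind(which(hit), match(truth[hit], report_labels()))] <- 2
  probs <- probs / rowSums(probs)
  rep_ <- evaluate(probs, truth)
  expect_s3_class(rep_, "metrics_report")
  cm <- rep_$confusion
  micro_recall <- sum(diag(cm)) / sum(cm)
  expect_equal(micro_recall, rep_$accuracy)
  for (cls in report_labels()) {
    m <- rep_$per_class[[cls]]
    expect_true(m$auroc >= 0 && m$auroc <= 1)
    expect_true(m$auprc >= 0 && m$auprc <= 1)
    expect_equal(m$support, sum(truth == cls))
  }
  expect_true(rep_$kappa >= -1 && rep_$kappa <= 1)

  js <- jsonlite::fromJSON(metrics_to_json(rep_))
  expect_equal(js$accuracy, rep_$accuracy)
  expect_equal(js$per_class$negative$f1, rep_$per_class$negative$f1)

  txt <- format(rep_)
  expect_true(any(grepl("Precision", txt)))
})

test_that("evaluate on a perfect prediction set gives accuracy 1", {
  truth <- rep(report_labels(), 10)
  probs <- matrix(0.05, 30, 3)
  probs[cbind(1:30, match(truth, report_labels()))] <- 0.9
  rep_ <- evaluate(probs / rowSums(probs), truth)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
})
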
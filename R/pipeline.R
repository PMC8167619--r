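#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations. Every stage seed is derived from
#' the global `seed` unless the nested config is supplied explicitly.
#'
#' @param seed Global integer seed.
#' @param synth A [synth_config()].
#' @param embedding An [embedding_config()] used for both scripts (the
#'   Hangul embedding uses `seed + 1`). The pipeline default is sized for
#'   the synthetic corpora: dim 24, 5-6-grams (short filler words share too
#'   many 3-4-grams, which blurs the space), 60 epochs, `min_count` 3.
#' @param classifier A [classifier_config()].
#' @param mapping_iterations,mapping_k,mapping_top_n,seed_mode Mapping-stage
#'   settings (refinement rounds, CSLS neighborhood, induction frequency
#'   cutoff, seed-dictionary mode).
#' @param test_fraction Held-out test share for the TRAIN/EVAL stages.
#' @param n_examples Reports rendered in the EXPLAIN gallery.
#' @param lexicon Inclusion lexicon for the FILTER stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = synth_config(seed = seed),
                            embedding = embedding_config(
                              dim = 24, ngram_min = 5, ngram_max = 6,
                              epochs = 20, min_count = 5, seed = seed),
                            classifier = classifier_config(seed = seed),
                            mapping_iterations = 5L, mapping_k = 10L,
                            mapping_top_n = 50L, seed_mode = "frequency",
                            test_fraction = 0.2, n_examples = 12L,
                            lexicon = default_lexicon()) {
  structure(list(seed = as.integer(seed), synth = synth,
                 embedding = embedding, classifier = classifier,
                 mapping_iterations = as.integer(mapping_iterations),
                 mapping_k = as.integer(mapping_k),
                 mapping_top_n = as.integer(mapping_top_n),
                 seed_mode = seed_mode,
                 test_fraction = test_fraction,
                 n_examples = as.integer(n_examples), lexicon = lexicon),
            class = "pipeline_config")
}

.STAGES <- c("synth", "filter", "embed", "align", "train", "eval", "explain")

.stage_error <- function(msg, stage) {
  stop(structure(class = c("bilingrad_missing_upstream", "error", "condition"),
                 list(message = paste0(msg, " — run stage '", stage,
                                       "' first"), call = NULL)))
}

.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, ascii = TRUE, compress = FALSE)
  unname(tools::md5sum(tf))
}

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.need <- function(out_dir, files, stage) {
  paths <- file.path(out_dir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    .stage_error(paste("missing artifact(s):",
                       paste(files[missing], collapse = ", ")), stage)
  }
  paths
}

.manifest_path <- function(out_dir, stage) {
  file.path(out_dir, paste0("stage_", stage, ".manifest.json"))
}

.write_manifest <- function(out_dir, stage, inputs, outputs, cfg_hash, seed) {
  man <- list(stage = stage, config_hash = cfg_hash, seed = seed,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  .atomic_write(function(p) {
    writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE), p)
  }, .manifest_path(out_dir, stage))
}

.up_to_date <- function(out_dir, stage, inputs, outputs, cfg_hash) {
  mp <- .manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  if (!all(file.exists(file.path(out_dir, outputs)))) return(FALSE)
  man <- tryCatch(jsonlite::fromJSON(mp), error = function(e) NULL)
  if (is.null(man) || !identical(man$config_hash, unname(cfg_hash))) return(FALSE)
  cur <- as.list(tools::md5sum(inputs))
  identical(lapply(man$inputs, unname), lapply(cur, unname))
}

#' Run one pipeline stage
#'
#' Stages: `synth` (generate the corpus, dictionary, monolingual corpora),
#' `filter` (lexeme inclusion filter), `embed` (subword embeddings per
#' script), `align` (Kor2Eng mapping), `train` (split + classifier),
#' `eval` (metrics on the held-out test set), `explain` (attention gallery).
#' Outputs are written atomically together with a manifest recording the
#' config hash and input checksums; re-running an up-to-date stage is a
#' no-op unless `force = TRUE`.
#'
#' @param stage One of the stage names above.
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory.
#' @param force Re-run even when the manifest says the stage is current.
#' @return Invisibly, a list describing the stage's artifacts (and for
#'   `eval` the `metrics_report`).
#' @export
run_stage <- function(stage, config, out_dir, force = FALSE) {
  stage <- match.arg(tolower(stage), .STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- switch(stage,
               synth = .stage_synth, filter = .stage_filter,
               embed = .stage_embed, align = .stage_align,
               train = .stage_train, eval = .stage_eval,
               explain = .stage_explain)
  t0 <- Sys.time()
  res <- fn(config, out_dir, force)
  message(sprintf("[%s] %s in %.1fs%s", stage,
                  if (isTRUE(res$skipped)) "up-to-date (skipped)" else "done",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  paste0(" -> ", paste(res$outputs, collapse = ", "))))
  invisible(res)
}

.stage_synth <- function(config, out_dir, force) {
  outs <- c("corpus.jsonl", "corpus_cues.csv", "dictionary.tsv",
            "mono_hangul.txt", "mono_latin.txt")
  h <- .hash_obj(config$synth)
  if (!force && .up_to_date(out_dir, "synth", character(0), outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  corp <- generate_corpus(config$synth)
  mono <- generate_monolingual_corpora(config$synth)
  .atomic_write(function(p) write_reports(corp$reports, p, "jsonl"),
                file.path(out_dir, "corpus.jsonl"))
  .atomic_write(function(p) {
    write.csv(corp$reports[c("id", "cue")], p, row.names = FALSE,
              fileEncoding = "UTF-8")
  }, file.path(out_dir, "corpus_cues.csv"))
  .atomic_write(function(p) {
    write.table(corp$dictionary, p, sep = "\t", row.names = FALSE,
                quote = FALSE, fileEncoding = "UTF-8")
  }, file.path(out_dir, "dictionary.tsv"))
  .atomic_write(function(p) {
    writeLines(vapply(mono$hangul, paste, character(1), collapse = " "), p,
               useBytes = TRUE)
  }, file.path(out_dir, "mono_hangul.txt"))
  .atomic_write(function(p) {
    writeLines(vapply(mono$latin, paste, character(1), collapse = " "), p,
               useBytes = TRUE)
  }, file.path(out_dir, "mono_latin.txt"))
  .write_manifest(out_dir, "synth", character(0), outs, h, config$synth$seed)
  list(skipped = FALSE, outputs = outs)
}

.stage_filter <- function(config, out_dir, force) {
  ins <- .need(out_dir, "corpus.jsonl", "synth")
  outs <- "filtered.jsonl"
  h <- .hash_obj(config$lexicon)
  if (!force && .up_to_date(out_dir, "filter", ins, outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  reports <- read_reports(ins, "jsonl")
  kept <- keyword_filter(reports, config$lexicon)
  .atomic_write(function(p) write_reports(kept, p, "jsonl"),
                file.path(out_dir, outs))
  .write_manifest(out_dir, "filter", ins, outs, h, config$seed)
  list(skipped = FALSE, outputs = outs, n_in = nrow(reports), n_out = nrow(kept))
}

.read_mono <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(x) {
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    toks[nzchar(toks)]
  })
}

.stage_embed <- function(config, out_dir, force) {
  ins <- .need(out_dir, c("mono_hangul.txt", "mono_latin.txt"), "synth")
  outs <- c("emb_latin.vec", "emb_latin.vec.ngrams",
            "emb_hangul.vec", "emb_hangul.vec.ngrams")
  h <- .hash_obj(config$embedding)
  if (!force && .up_to_date(out_dir, "embed", ins, outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  cfg_l <- config$embedding
  cfg_h <- config$embedding
  cfg_h$seed <- cfg_h$seed + 1L
  emb_l <- train_subword_embeddings(.read_mono(ins[2]), cfg_l)
  emb_h <- train_subword_embeddings(.read_mono(ins[1]), cfg_h)
  save_embeddings(emb_l, file.path(out_dir, "emb_latin.vec"))
  save_embeddings(emb_h, file.path(out_dir, "emb_hangul.vec"))
  .write_manifest(out_dir, "embed", ins, outs, h, config$embedding$seed)
  list(skipped = FALSE, outputs = outs)
}

.stage_align <- function(config, out_dir, force) {
  ins <- .need(out_dir, c("emb_hangul.vec", "emb_latin.vec"), "embed")
  outs <- c("mapping.tsv", "mapping.tsv.dict")
  h <- .hash_obj(config[c("mapping_iterations", "mapping_k", "mapping_top_n",
                          "seed_mode")])
  if (!force && .up_to_date(out_dir, "align", ins, outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  emb_h <- load_embeddings(ins[1])
  emb_l <- load_embeddings(ins[2])
  seeds <- seed_dictionary(emb_h, emb_l, config$seed_mode, max_pairs = 60)
  model <- train_mapping(emb_h, emb_l, seeds,
                         iterations = config$mapping_iterations,
                         k = config$mapping_k, top_n = config$mapping_top_n)
  save_mapping(model, file.path(out_dir, "mapping.tsv"))
  .write_manifest(out_dir, "align", ins, outs, h, config$seed)
  list(skipped = FALSE, outputs = outs)
}

.stage_train <- function(config, out_dir, force) {
  ins <- .need(out_dir, c("filtered.jsonl", "emb_latin.vec", "emb_hangul.vec",
                          "mapping.tsv"), "align")
  outs <- c("model.rds", "history.csv", "train.jsonl", "test.jsonl")
  h <- .hash_obj(list(config$classifier, config$test_fraction))
  if (!force && .up_to_date(out_dir, "train", ins, outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  reports <- read_reports(ins[1], "jsonl")
  sp <- stratified_split(reports, config$test_fraction, seed = config$seed)
  emb_l <- load_embeddings(ins[2])
  emb_h <- load_embeddings(ins[3])
  mapping <- load_mapping(ins[4])
  model <- attn_bilstm(sp$train, emb_l, emb_h, mapping,
                       config = config$classifier)
  .atomic_write(function(p) write_reports(sp$train, p, "jsonl"),
                file.path(out_dir, "train.jsonl"))
  .atomic_write(function(p) write_reports(sp$test, p, "jsonl"),
                file.path(out_dir, "test.jsonl"))
  .atomic_write(function(p) save_classifier(model, p),
                file.path(out_dir, "model.rds"))
  .atomic_write(function(p) {
    write.csv(model$history, p, row.names = FALSE)
  }, file.path(out_dir, "history.csv"))
  .write_manifest(out_dir, "train", ins, outs, h, config$classifier$seed)
  list(skipped = FALSE, outputs = outs)
}

.stage_eval <- function(config, out_dir, force) {
  ins <- .need(out_dir, c("model.rds", "test.jsonl"), "train")
  outs <- c("metrics.json", "metrics.md")
  h <- .hash_obj(config$test_fraction)
  if (!force && .up_to_date(out_dir, "eval", ins, outs, h)) {
    metrics <- jsonlite::fromJSON(file.path(out_dir, "metrics.json"))
    return(list(skipped = TRUE, outputs = outs, metrics_json = metrics))
  }
  model <- load_classifier(ins[1])
  test <- read_reports(ins[2], "jsonl")
  preds <- predict(model, test)
  metrics <- evaluate(preds, test$label)
  .atomic_write(function(p) metrics_to_json(metrics, p),
                file.path(out_dir, "metrics.json"))
  .atomic_write(function(p) writeLines(format(metrics), p),
                file.path(out_dir, "metrics.md"))
  .write_manifest(out_dir, "eval", ins, outs, h, config$seed)
  list(skipped = FALSE, outputs = outs, metrics = metrics)
}

.stage_explain <- function(config, out_dir, force) {
  ins <- .need(out_dir, c("model.rds", "test.jsonl"), "train")
  outs <- "gallery.html"
  h <- .hash_obj(config$n_examples)
  if (!force && .up_to_date(out_dir, "explain", ins, outs, h)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  model <- load_classifier(ins[1])
  test <- head(read_reports(ins[2], "jsonl"), config$n_examples)
  preds <- predict(model, test)
  ann <- lapply(seq_len(nrow(test)), function(i) {
    annotate(test[i, , drop = FALSE], preds[[i]])
  })
  .atomic_write(function(p) write_gallery(ann, p), file.path(out_dir, outs))
  .write_manifest(out_dir, "explain", ins, outs, h, config$seed)
  list(skipped = FALSE, outputs = outs)
}

#' Run the full pipeline
#'
#' Executes synth, filter, embed, align, train, eval and explain in order
#' and returns the final held-out metrics together with the gallery path.
#' A fixed global seed makes every artifact reproducible.
#'
#' @inheritParams run_stage
#' @return A list with `metrics` (a `metrics_report`) and `gallery` (path).
#' @export
run_all <- function(config, out_dir, force = FALSE) {
  ev <- NULL
  for (st in .STAGES) {
    res <- run_stage(st, config, out_dir, force)
    if (st == "eval") ev <- res
  }
  metrics <- if (!is.null(ev$metrics)) ev$metrics else {
    model <- load_classifier(file.path(out_dir, "model.rds"))
    test <- read_reports(file.path(out_dir, "test.jsonl"), "jsonl")
    evaluate(predict(model, test), test$label)
  }
  list(metrics = metrics, gallery = file.path(out_dir, "gallery.html"))
}
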
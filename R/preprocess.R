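#' Tokenize mixed Hangul/Latin text
#'
#' Splits a report into maximal runs of a single script class: Hangul
#' syllables/jamo, Latin letters, or digits. Punctuation and whitespace
#' separate tokens and are dropped; hyphens and slashes therefore split
#' tokens. An apostrophe flanked by two characters of the same class is
#' absorbed into the run (so `"radiologist's"` is one token) and removed
#' during normalization.
#'
#' @param text A length-1 UTF-8 character string.
#' @return A data frame with one row per token and columns
#'   `surface` (the exact slice of `text`), `norm` (the normalized form, see
#'   [normalize_token()]), `script` (`"HANGUL"`, `"LATIN"`, or `"DIGIT"`),
#'   and 0-based half-open character offsets `start`, `end` such that
#'   `substr(text, start + 1, end) == surface`.
#' @examples
#' tokenize("Peribronchial infiltration 의심")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(
    surface = character(), norm = character(), script = character(),
    start = integer(), end = integer(), stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- stringi::stri_trans_nfc(enc2utf8(text))
  chars <- stringi::stri_split_boundaries(text, type = "character")[[1]]
  cls <- vapply(chars, .char_class, character(1), USE.NAMES = FALSE)

  # absorb apostrophes between same-class letters into the surrounding run
  n <- length(cls)
  apo <- chars %in% c("'", "’")
  if (n >= 3) {
    mid <- which(apo[-c(1, n)]) + 1L
    keep <- mid[cls[mid - 1L] != "OTHER" & cls[mid - 1L] == cls[mid + 1L]]
    cls[keep] <- cls[keep - 1L]
  }

  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tok <- which(r$values != "OTHER")
  if (!length(tok)) return(empty)
  surface <- vapply(tok, function(i) {
    paste0(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
  out <- data.frame(
    surface = surface,
    norm = normalize_token(surface),
    script = r$values[tok],
    start = starts[tok] - 1L,
    end = ends[tok],
    stringsAsFactors = FALSE
  )
  out[nzchar(out$norm), , drop = FALSE]
}

.char_class <- function(ch) {
  cp <- utf8ToInt(ch)
  if (length(cp) != 1 || is.na(cp)) return("OTHER")
  if ((cp >= 0xAC00 && cp <= 0xD7A3) ||   # Hangul syllables
      (cp >= 0x1100 && cp <= 0x11FF) ||   # Hangul jamo
      (cp >= 0x3130 && cp <= 0x318F)) {   # Hangul compatibility jamo
    return("HANGUL")
  }
  if ((cp >= 0x41 && cp <= 0x5A) || (cp >= 0x61 && cp <= 0x7A)) return("LATIN")
  if (cp >= 0x30 && cp <= 0x39) return("DIGIT")
  "OTHER"
}

#' Normalize a token surface form
#'
#' Applies Unicode NFC, lowercases Latin letters, and strips apostrophes.
#' Hangul is left untouched (Korean has no case).
#'
#' @param surface Character vector of token surfaces.
#' @return Character vector of normalized forms.
#' @export
normalize_token <- function(surface) {
  x <- stringi::stri_trans_nfc(enc2utf8(surface))
  x <- gsub("['’]", "", x)
  stringi::stri_trans_tolower(x)
}

#' Pneumonia-lexeme inclusion lexicon
#'
#' The default inclusion lexicon: seven stems matched as token prefixes
#' (`pneumoni-`, `consolid-`, `infiltra-`, `bronchiole-`, `hazi-`, `hazzi-`,
#' `opacit-`) and `GGO` matched as a whole token, all case-insensitively.
#' Reports whose text matches none of the entries are considered irrelevant
#' to pneumonia and are excluded upstream of any modelling.
#'
#' @return A data frame with columns `pattern` and `mode`
#'   (`"prefix"` or `"exact"`).
#' @seealso [keyword_filter()], [read_lexicon()]
#' @export
default_lexicon <- function() {
  data.frame(
    pattern = c("pneumoni", "consolid", "infiltra", "bronchiole",
                "hazi", "hazzi", "opacit", "GGO"),
    mode = c(rep("prefix", 7), "exact"),
    stringsAsFactors = FALSE
  )
}

.validate_lexicon <- function(lexicon) {
  stopifnot(is.data.frame(lexicon), all(c("pattern", "mode") %in% names(lexicon)))
  if (nrow(lexicon) == 0) stop("lexicon must be non-empty")
  if (any(!nzchar(lexicon$pattern))) stop("lexicon patterns must be non-empty")
  if (any(!lexicon$mode %in% c("prefix", "exact"))) {
    stop("lexicon mode must be 'prefix' or 'exact'")
  }
  lexicon
}

#' Does a text match the pneumonia lexicon?
#'
#' @param text Character vector of report texts.
#' @param lexicon A lexicon data frame, by default [default_lexicon()].
#' @return Logical vector: `TRUE` where at least one lexicon entry matches a
#'   token (prefix entries match at token start, exact entries the whole
#'   token, case-insensitively on normalized tokens).
#' @export
matches_lexicon <- function(text, lexicon = default_lexicon()) {
  lexicon <- .validate_lexicon(lexicon)
  pat <- normalize_token(lexicon$pattern)
  vapply(text, function(x) {
    toks <- tokenize(x)$norm
    if (!length(toks)) return(FALSE)
    for (i in seq_along(pat)) {
      hit <- if (lexicon$mode[i] == "prefix") {
        any(startsWith(toks, pat[i]))
      } else {
        any(toks == pat[i])
      }
      if (hit) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter reports by the pneumonia lexicon
#'
#' Keeps exactly the reports whose text contains at least one lexicon entry,
#' preserving order. This mirrors the cohort-construction step in which only
#' radiology reports containing a pneumonia-related word enter the study.
#'
#' @param reports A report data frame (see [read_reports()]).
#' @param lexicon A lexicon data frame, by default [default_lexicon()].
#' @return The retained subset of `reports`.
#' @export
keyword_filter <- function(reports, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(reports), "text" %in% names(reports))
  keep <- matches_lexicon(reports$text, lexicon)
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.validate_reports <- function(reports) {
  stopifnot(is.data.frame(reports))
  need <- c("id", "modality", "text")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stop("report set missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(reports$id) | !nzchar(as.character(reports$id)))) {
    stop("report ids must be non-empty")
  }
  if (!"label" %in% names(reports)) reports$label <- NA_character_
  reports$label <- .validate_label(reports$label)
  bad <- !toupper(reports$modality) %in% c("CT", "XRAY", "OTHER")
  if (any(bad)) stop("unknown modality: ", paste(unique(reports$modality[bad]), collapse = ", "))
  reports$modality <- toupper(reports$modality)
  reports[c("id", "modality", "text", "label")]
}

#' Read and write report sets
#'
#' Reports travel as UTF-8 JSONL (one object per line with fields `id`,
#' `modality`, `text`, and optional `label`) or as CSV with the same columns.
#' `read_reports(write_reports(x))` is the identity, including Unicode text
#' and missing labels.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension when `NULL`.
#' @param reports A report data frame.
#' @return `read_reports()` returns a data frame with columns `id`,
#'   `modality`, `text`, `label` (`NA` when unlabeled).
#' @export
read_reports <- function(path, format = NULL) {
  format <- .guess_format(path, format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSONL at line ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
      for (f in c("id", "modality", "text")) {
        if (is.null(rec[[f]])) stop("JSONL line ", i, " missing field '", f, "'", call. = FALSE)
      }
      data.frame(id = as.character(rec$id), modality = as.character(rec$modality),
                 text = as.character(rec$text),
                 label = if (is.null(rec$label)) NA_character_ else as.character(rec$label),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    if (is.null(out)) {
      out <- data.frame(id = character(), modality = character(),
                        text = character(), label = character(),
                        stringsAsFactors = FALSE)
    }
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    colClasses = "character")
    if (!"label" %in% names(out)) out$label <- NA_character_
  }
  .validate_reports(out)
}

#' @rdname read_reports
#' @export
write_reports <- function(reports, path, format = NULL) {
  reports <- .validate_reports(reports)
  format <- .guess_format(path, format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(reports)), function(i) {
      rec <- list(id = reports$id[i], modality = reports$modality[i],
                  text = reports$text[i])
      if (!is.na(reports$label[i])) rec$label <- reports$label[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    write.csv(reports, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}

.guess_format <- function(path, format) {
  if (!is.null(format)) {
    format <- tolower(format)
    stopifnot(format %in% c("jsonl", "csv"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json", "ndjson")) "jsonl"
  else if (ext == "csv") "csv"
  else stop("cannot guess report format from extension '", ext, "'")
}

#' @rdname default_lexicon
#' @param path Path to a 2-column TSV (`pattern`, `mode`).
#' @param lexicon A lexicon data frame to write.
#' @export
read_lexicon <- function(path) {
  x <- read.csv(path, sep = "\t", stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  .validate_lexicon(x)
}

#' @rdname default_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  lexicon <- .validate_lexicon(lexicon)
  write.table(lexicon, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
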
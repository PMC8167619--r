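#' Annotate a report with display-scaled attention weights
#'
#' Pairs each (non-pad) token with its raw attention weight and a display
#' weight obtained by dividing by the maximum raw weight, so the most
#' important token always renders at full intensity and relative contrast
#' within the report is preserved.
#'
#' @param report A one-row report data frame or a single text string.
#' @param prediction The matching `attention_prediction`.
#' @return An object of class `annotated_report`: a `tokens` data frame
#'   (`surface`, `script`, `weight_raw`, `weight`), plus `id`,
#'   `predicted_label` and `probabilities`.
#' @export
annotate <- function(report, prediction) {
  stopifnot(inherits(prediction, "attention_prediction"))
  if (is.data.frame(report)) {
    stopifnot(nrow(report) == 1)
    text <- report$text
    id <- report$id
  } else {
    text <- as.character(report)
    id <- NA_character_
  }
  toks <- tokenize(text)
  if (!is.null(prediction$tokens)) {
    # predictions from the classifier carry their (possibly truncated)
    # token sequence; align the report tokens with it
    toks <- head(toks, prediction$token_count)
  }
  if (nrow(toks) != prediction$token_count) {
    stop("token count (", nrow(toks), ") does not match attention weights (",
         prediction$token_count, ")")
  }
  raw <- prediction$attention_weights
  mx <- max(raw)
  disp <- if (mx > 0) raw / mx else raw
  structure(list(
    id = id,
    tokens = data.frame(surface = toks$surface, script = toks$script,
                        weight_raw = raw, weight = disp,
                        stringsAsFactors = FALSE),
    predicted_label = prediction$predicted_label,
    probabilities = prediction$probabilities
  ), class = "annotated_report")
}

#' Top-weighted tokens of an annotated report
#'
#' @param annotated An [annotate()] result.
#' @param k Number of tokens; ties broken by earlier position, `k` beyond
#'   the report length returns all tokens.
#' @return Data frame `(surface, weight_raw)` in descending weight order.
#' @export
top_k <- function(annotated, k) {
  stopifnot(inherits(annotated, "annotated_report"), k >= 1)
  tk <- annotated$tokens
  ord <- order(-tk$weight_raw, seq_len(nrow(tk)))
  head(tk[ord, c("surface", "weight_raw")], k)
}

#' Render an annotated report as highlighted text
#'
#' HTML output is a standalone page with one `<span>` per token whose
#' background opacity is proportional to the display weight; ANSI output
#' shades each token into one of 8 background intensity buckets. Token
#' order and surfaces are never altered.
#'
#' @param annotated An [annotate()] result (or a list of them for an HTML
#'   gallery).
#' @param format `"html"` or `"ansi"`.
#' @return A single string.
#' @export
render_annotated <- function(annotated, format = c("html", "ansi")) {
  format <- match.arg(format)
  if (format == "html") return(.render_html(list(annotated)))
  tk <- annotated$tokens
  cols <- 254 - round(tk$weight * 7) * 3   # 8 grey buckets; weight 1 = darkest
  paste(sprintf("\033[48;5;%dm%s\033[0m", cols, tk$surface), collapse = " ")
}

.render_html <- function(annotated_list) {
  body <- vapply(annotated_list, function(a) {
    spans <- paste(sprintf(
      '<span style="background-color: rgba(220, 20, 60, %.3f)">%s</span>',
      a$tokens$weight, .html_escape(a$tokens$surface)), collapse = " ")
    sprintf('<div class="report"><p class="meta">%s &mdash; predicted: %s</p><p>%s</p></div>',
            .html_escape(ifelse(is.na(a$id), "", a$id)),
            a$predicted_label, spans)
  }, character(1))
  paste0('<!DOCTYPE html>\n<html><head><meta charset="utf-8">',
         "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}",
         ".meta{color:#666;font-size:smaller}</style></head>\n<body>\n",
         paste(body, collapse = "\n"), "\n</body></html>\n")
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an HTML gallery of annotated reports
#'
#' @param annotated_list List of [annotate()] results.
#' @param path Output HTML path.
#' @return The path, invisibly.
#' @export
write_gallery <- function(annotated_list, path) {
  writeLines(.render_html(annotated_list), path, useBytes = TRUE)
  invisible(path)
}

#' Export (token, weight) pairs as JSON
#'
#' @param annotated An [annotate()] result.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
annotated_to_json <- function(annotated, path = NULL) {
  stopifnot(inherits(annotated, "annotated_report"))
  js <- jsonlite::toJSON(list(
    id = annotated$id, predicted_label = annotated$predicted_label,
    probabilities = as.list(annotated$probabilities),
    tokens = annotated$tokens[c("surface", "weight_raw", "weight")]
  ), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' @export
print.annotated_report <- function(x, ...) {
  cat(render_annotated(x, "ansi"), "\n")
  cat("predicted:", x$predicted_label, "\n")
  invisible(x)
}
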
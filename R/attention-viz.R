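# Hierarchical attention normalization and the two-color HTML transcript
# heatmap: green background opacity per token (hierarchically normalized
# word weight), red left bar per sentence (sentence weight).

#' Default marker lexicons
#'
#' Three lexicons used to read attention maps: the content seed words a
#' complete Cookie Theft picture description is expected to mention, the
#' hesitation fillers characteristic of the disease class, and the personal
#' pronouns that stand in for content nouns under word-finding difficulty.
#' Shipped as JSON under `inst/extdata/lexicons.json`.
#'
#' @return Named list of character vectors `seed_words`, `fillers`,
#'   `pronouns`.
#' @export
han_lexicons <- function() {
  path <- system.file("extdata", "lexicons.json", package = "hanscribe")
  lapply(jsonlite::fromJSON(path), as.character)
}

#' Hierarchically normalize attention weights
#'
#' Multiplies each sentence's word weights by the sentence weight, so that
#' only important words in important sentences are emphasized; the products
#' sum to 1 over the whole document. Input invariants (each simplex sums to
#' 1) are checked and violations are an error.
#'
#' @param record An [attention_record()].
#' @return List with `sentence_weights` and `normalized_word_weights`
#'   (list of vectors, one per sentence).
#' @export
normalize_attention <- function(record) {
  tol <- 1e-6
  if (abs(sum(record$sentence_weights) - 1) > tol ||
      any(vapply(record$word_weights,
                 function(w) abs(sum(w) - 1) > tol, TRUE))) {
    stop("input error: attention record violates its simplex invariants",
         call. = FALSE)
  }
  normalized <- lapply(seq_along(record$word_weights), function(i) {
    record$sentence_weights[i] * record$word_weights[[i]]
  })
  list(sentence_weights = record$sentence_weights,
       normalized_word_weights = normalized)
}

#' Build a visualization document from a transcript and its attention
#'
#' Pairs every token (up to the encoder's truncation limits) with its
#' hierarchically normalized weight.
#'
#' @param transcript The [clean_transcript()] that was classified.
#' @param record The matching [attention_record()] from the forward pass.
#' @param predicted,truth Optional class labels shown in the report header.
#' @return Object of class `viz_document`.
#' @export
viz_document <- function(transcript, record, predicted = NA_character_,
                         truth = NA_character_) {
  norm <- normalize_attention(record)
  L <- length(norm$normalized_word_weights)
  sentences <- vector("list", L)
  for (i in seq_len(L)) {
    w <- norm$normalized_word_weights[[i]]
    toks <- transcript$sentences[[i]]
    n <- min(length(toks), length(w))
    sentences[[i]] <- list(tokens = toks[seq_len(n)],
                           weights = unname(w[seq_len(n)]))
  }
  structure(
    list(doc_id = transcript$doc_id, sentences = sentences,
         sentence_weights = unname(norm$sentence_weights),
         predicted = predicted, truth = truth),
    class = "viz_document")
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.lexicon_mass <- function(doc, lexicon) {
  s <- 0
  for (sen in doc$sentences) {
    s <- s + sum(sen$weights[sen$tokens %in% lexicon])
  }
  s
}

#' Render attention heatmaps as a self-contained HTML report
#'
#' One block per document, input order preserved. Each sentence sits on its
#' own line behind a red left bar whose opacity scales with the sentence
#' weight; each token's green background opacity scales with its
#' hierarchically normalized weight. Both scales are rescaled by the
#' per-document maximum (so short documents stay readable; stated in the
#' report header). Tokens belonging to any supplied lexicon are underlined,
#' and each document's total normalized attention mass per lexicon is
#' printed, making qualitative claims about where the model looks checkable
#' quantitatively. A JSON sidecar (`<out>.json`) carries all numeric
#' weights.
#'
#' @param docs List of [viz_document()].
#' @param out Output HTML path.
#' @param lexicons Named list of character vectors to underline and score;
#'   default [han_lexicons()]; `NULL` disables.
#' @return `out`, invisibly.
#' @export
render_html <- function(docs, out, lexicons = han_lexicons()) {
  fmt <- function(x) sprintf("%.6f", x)
  lex_all <- unique(unlist(lexicons))
  head_html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Attention heatmap report</title>",
    "<style>",
    "body{font-family:sans-serif;max-width:60em;margin:1em auto;}",
    ".doc{margin-bottom:2em;border-top:1px solid #ccc;padding-top:1em;}",
    ".sent{display:block;margin:0.15em 0;padding-left:0.6em;}",
    ".tok{padding:0.05em 0.15em;border-radius:0.15em;}",
    ".lex{text-decoration:underline;}",
    ".mass{color:#555;font-size:smaller;}",
    "</style></head><body>",
    "<h1>Attention heatmap report</h1>",
    paste0("<p>Green background: hierarchically normalized word weight; ",
           "red left bar: sentence weight. Opacities are rescaled by each ",
           "document's maximum weight so short documents stay readable. ",
           "Underlined tokens belong to a marker lexicon.</p>"))
  body <- character(0)
  for (doc in docs) {
    max_tok <- max(c(1e-300, unlist(lapply(doc$sentences, `[[`, "weights"))))
    max_sen <- max(c(1e-300, doc$sentence_weights))
    body <- c(body, "<div class=\"doc\">",
              sprintf("<h2>%s</h2>", .html_escape(doc$doc_id)),
              sprintf("<p class=\"mass\">predicted: %s; true: %s</p>",
                      .html_escape(as.character(doc$predicted)),
                      .html_escape(as.character(doc$truth))))
    for (i in seq_along(doc$sentences)) {
      sen <- doc$sentences[[i]]
      sw <- doc$sentence_weights[i] / max_sen
      toks <- vapply(seq_along(sen$tokens), function(j) {
        op <- sen$weights[j] / max_tok
        cls <- if (sen$tokens[j] %in% lex_all) "tok lex" else "tok"
        sprintf("<span class=\"%s\" style=\"background:rgba(0,160,0,%s)\">%s</span>",
                cls, fmt(op), .html_escape(sen$tokens[j]))
      }, "")
      body <- c(body,
                sprintf("<span class=\"sent\" style=\"border-left:0.5em solid rgba(200,0,0,%s)\">%s</span>",
                        fmt(sw), paste(toks, collapse = " ")))
    }
    if (length(lexicons)) {
      mass <- vapply(names(lexicons), function(nm) {
        sprintf("%s %s", nm, fmt(.lexicon_mass(doc, lexicons[[nm]])))
      }, "")
      body <- c(body, sprintf(
        "<p class=\"mass\">attention mass on lexicons: %s</p>",
        paste(mass, collapse = "; ")))
    }
    body <- c(body, "</div>")
  }
  html <- c(head_html, body, "</body></html>")
  con <- file(out, open = "wb")
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  close(con)
  sidecar <- lapply(docs, function(doc) {
    list(doc_id = doc$doc_id, predicted = doc$predicted, truth = doc$truth,
         sentence_weights = doc$sentence_weights,
         sentences = lapply(doc$sentences, function(s) {
           list(tokens = s$tokens, weights = s$weights)
         }),
         lexicon_mass = if (length(lexicons)) {
           lapply(lexicons, function(lx) .lexicon_mass(doc, lx))
         })
  })
  jsonlite::write_json(sidecar, paste0(out, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out)
}
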
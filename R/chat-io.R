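# Reading CHAT (.cha) transcripts and reducing them to pure participant text.

#' Characters that mark CHAT annotation and must never survive cleaning
#' @keywords internal
.chat_forbidden_chars <- "[][<>&@%*]"

#' Construct a clean transcript
#'
#' A `clean_transcript` is one document as an ordered list of sentences, each
#' an ordered vector of lowercase tokens, plus an optional class label and
#' provenance. It is the common currency of the whole pipeline: the CHAT
#' reader, the plain-text reader and the synthetic generator all emit it.
#'
#' @param doc_id Document identifier (string).
#' @param sentences List of character vectors, one per sentence; every
#'   sentence must hold at least one token and tokens must be free of CHAT
#'   annotation characters (`[ ] < > & @ \% *`).
#' @param label Optional class label, `"AD"` or `"CTRL"` (or `NA`).
#' @param patient_id Optional patient identifier used for grouped splits.
#' @param source_path Optional provenance path.
#' @return An object of class `clean_transcript` with fields `doc_id`,
#'   `sentences`, `label`, `n_words`, `patient_id`, `source_path`.
#' @export
clean_transcript <- function(doc_id, sentences, label = NA_character_,
                             patient_id = NA_character_,
                             source_path = NA_character_) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, is.list(sentences))
  if (length(sentences) == 0L) {
    stop("empty document: '", doc_id, "' has no sentences", call. = FALSE)
  }
  for (s in sentences) {
    if (!is.character(s) || length(s) == 0L) {
      stop("every sentence must hold at least one token (doc '", doc_id, "')",
           call. = FALSE)
    }
    bad <- grepl(.chat_forbidden_chars, s)
    if (any(bad)) {
      stop("annotation characters survive in token(s): ",
           paste(s[bad], collapse = " "), call. = FALSE)
    }
  }
  if (!is.na(label)) label <- match.arg(label, c("AD", "CTRL"))
  structure(
    list(doc_id = doc_id, sentences = sentences, label = label,
         n_words = sum(lengths(sentences)), patient_id = patient_id,
         source_path = source_path),
    class = "clean_transcript")
}

#' @export
print.clean_transcript <- function(x, ...) {
  cat(sprintf("<clean_transcript '%s'> %d sentence(s), %d token(s), label=%s\n",
              x$doc_id, length(x$sentences), x$n_words,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' Read one CHAT-format (.cha) file
#'
#' Parses a TalkBank/CLAN transcript into its tiers, in file order. Speaker
#' tiers (`*PAR:`, `*INV:`, ...) and dependent tiers (`%mor:`, `%gra:`, ...)
#' are kept; `@`-header lines are skipped; continuation lines (leading tab)
#' are joined to the tier that owns them. No cleaning happens here — see
#' [strip_annotations()].
#'
#' @param path Path to the `.cha` file (UTF-8).
#' @param speaker Speaker code whose presence is required, default `"PAR"`
#'   (the participant). All tiers are returned regardless; the filter is
#'   applied downstream.
#' @return An object of class `raw_chat_document` with fields `doc_id`,
#'   `tiers` (data.frame with columns `label`, `content`) and `source_path`.
#' @export
read_chat_file <- function(path, speaker = "PAR") {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  labels <- character(0)
  contents <- character(0)
  for (ln in lines) {
    if (!nzchar(ln)) next
    first <- substr(ln, 1L, 1L)
    if (first == "@") next
    if (first == "\t") {
      # continuation line: joined to its owning tier
      if (length(labels) > 0L) {
        contents[length(contents)] <-
          paste(contents[length(contents)], trimws(ln))
      }
      next
    }
    if (first %in% c("*", "%")) {
      colon <- regexpr(":", ln, fixed = TRUE)
      if (colon < 0L) next
      labels <- c(labels, substr(ln, 1L, colon - 1L))
      contents <- c(contents, trimws(substr(ln, colon + 1L, nchar(ln))))
    }
  }
  if (length(labels) == 0L) {
    stop("empty document: no tiers found in ", path, call. = FALSE)
  }
  if (!any(labels == paste0("*", speaker))) {
    stop("empty document: no tier for speaker '", speaker, "' in ", path,
         call. = FALSE)
  }
  structure(
    list(doc_id = sub("\\.[^.]*$", "", basename(path)),
         tiers = data.frame(label = labels, content = contents,
                            stringsAsFactors = FALSE),
         source_path = path),
    class = "raw_chat_document")
}

#' @export
print.raw_chat_document <- function(x, ...) {
  cat(sprintf("<raw_chat_document '%s'> %d tier(s) from %s\n",
              x$doc_id, nrow(x$tiers), x$source_path))
  invisible(x)
}

#' The CHAT code-removal rule table
#'
#' One editable table of regular-expression rewrites applied, in order, to
#' each utterance before tokenization. The default rules drop bracketed
#' retracing/error/replacement codes (`[//]`, `[/]`, `[: word]`, `[*]`, ...),
#' remove angle-bracket scope markers while keeping the scoped words, drop
#' `&`- and `&=`-prefixed non-word events, cut `@`-suffixed word-form markers
#' back to the stem, delete pause symbols `(.)`/`(..)`/`(...)`, and unwrap
#' other parenthesized material (so `(be)cause` becomes `because`). Users
#' matching another CHAT dialect can pass an edited table to
#' [strip_annotations()].
#'
#' @return data.frame with columns `pattern` (regex) and `replacement`.
#' @export
chat_cleaning_rules <- function() {
  data.frame(
    pattern = c(
      "\\[[^][]*\\]",        # bracketed codes: [//] [/] [: text] [* err] [+ exc]
      "[<>]",                # angle-bracket scope markers (words kept)
      "&=?\\S+",             # &-prefixed and &=-prefixed non-word events
      "@\\S*",               # @-suffixed word-form markers (stem kept)
      "\\(\\.{1,3}\\)",      # pause symbols (.) (..) (...)
      "\\(([^()]*)\\)",      # other parens: keep content, e.g. (be)cause
      "\\+\\S*"              # utterance-terminator codes such as +... +//.
    ),
    replacement = c("", "", "", "", "", "\\1", ""),
    stringsAsFactors = FALSE)
}

#' Strip CHAT annotation, keeping pure participant text
#'
#' Keeps only the chosen speaker's tiers, drops all dependent tiers
#' (`%mor`, `%gra`, ...), applies the [chat_cleaning_rules()] rewrites,
#' NFC-normalizes, lowercases, and splits each utterance into tokens on
#' whitespace. Utterances left without tokens are dropped. Sentence-final
#' punctuation is retained as a token.
#'
#' @param doc A `raw_chat_document` from [read_chat_file()].
#' @param speaker Speaker code to keep, default `"PAR"`.
#' @param label Optional class label attached to the result.
#' @param rules Rule table, see [chat_cleaning_rules()].
#' @return A [clean_transcript()].
#' @export
strip_annotations <- function(doc, speaker = "PAR", label = NA_character_,
                              rules = chat_cleaning_rules()) {
  stopifnot(inherits(doc, "raw_chat_document"))
  keep <- doc$tiers$label == paste0("*", speaker)
  utterances <- doc$tiers$content[keep]
  sentences <- list()
  for (u in utterances) {
    x <- stringi::stri_trans_nfc(u)
    for (k in seq_len(nrow(rules))) {
      # bracketed codes may nest one level; reapply until stable
      repeat {
        y <- gsub(rules$pattern[k], rules$replacement[k], x, perl = TRUE)
        if (identical(y, x)) break
        x <- y
      }
    }
    x <- gsub(.chat_forbidden_chars, " ", x)   # final scrub, belt and braces
    toks <- strsplit(tolower(trimws(x)), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) > 0L) sentences[[length(sentences) + 1L]] <- toks
  }
  if (length(sentences) == 0L) {
    stop("empty document: no utterances left for speaker '", speaker,
         "' in '", doc$doc_id, "'", call. = FALSE)
  }
  clean_transcript(doc$doc_id, sentences, label = label,
                   source_path = doc$source_path)
}

.normalize_label <- function(x) {
  lx <- tolower(trimws(x))
  if (lx == "ad") return("AD")
  if (lx %in% c("ctrl", "control", "nc", "hc")) return("CTRL")
  stop("input error: unknown label string '", x,
       "' (expected AD or CTRL/control/NC/HC, any case)", call. = FALSE)
}

#' Read a plain-text corpus via a label manifest
#'
#' @param dir Directory holding one plain-text file per document.
#' @param manifest CSV file with header `doc_id,filename,label` and an
#'   optional `patient_id` column. Labels are case-insensitive; `AD` maps to
#'   the positive class.
#' @param tokenizer Function string -> token vector, default
#'   [default_tokenizer()].
#' @param splitter Function string -> sentence vector, default
#'   [split_sentences()].
#' @return List of [clean_transcript()] in manifest order.
#' @export
read_plaintext_corpus <- function(dir, manifest,
                                  tokenizer = default_tokenizer,
                                  splitter = split_sentences) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("doc_id", "filename", "label")
  if (!all(need %in% names(man))) {
    stop("input error: manifest must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$filename[i])
    if (!file.exists(path)) {
      stop("input error: manifest row ", i, " references missing file '",
           man$filename[i], "'", call. = FALSE)
    }
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = " ")
    sentences <- lapply(splitter(text), tokenizer)
    sentences <- sentences[lengths(sentences) > 0L]
    out[[i]] <- clean_transcript(
      as.character(man$doc_id[i]), sentences,
      label = .normalize_label(man$label[i]),
      patient_id = if ("patient_id" %in% names(man))
        as.character(man$patient_id[i]) else NA_character_,
      source_path = path)
  }
  out
}

#' Write a clean transcript back out as a minimal .cha file
#'
#' One speaker tier per sentence, with a standard header. Used for round-trip
#' testing and for exporting synthetic corpora in CHAT form.
#'
#' @param transcript A [clean_transcript()].
#' @param path Output path.
#' @param speaker Speaker code, default `"PAR"`.
#' @return `path`, invisibly.
#' @export
write_chat_file <- function(transcript, path, speaker = "PAR") {
  stopifnot(inherits(transcript, "clean_transcript"))
  lines <- c("@Begin", "@Languages:\teng",
             sprintf("@Participants:\t%s Participant", speaker),
             sprintf("*%s:\t%s", speaker,
                     vapply(transcript$sentences, paste, "", collapse = " ")),
             "@End")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a corpus as JSON Lines
#'
#' One JSON object per line with fields `doc_id`, `sentences`, `label`,
#' `patient_id`. This is the interchange format between the readers, the
#' synthetic generator and the command-line interface.
#'
#' @param corpus List of [clean_transcript()].
#' @param path File path.
#' @return `path` invisibly for the writer; a list of transcripts for the
#'   reader.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(tr) {
    jsonlite::toJSON(list(doc_id = tr$doc_id, sentences = tr$sentences,
                          label = tr$label, patient_id = tr$patient_id),
                     auto_unbox = TRUE, null = "null", na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyMatrix = FALSE)
    sentences <- x$sentences
    if (!is.list(sentences)) sentences <- list(sentences)
    sentences <- lapply(sentences, as.character)
    clean_transcript(x$doc_id, sentences,
                     label = if (is.null(x$label)) NA_character_ else x$label,
                     patient_id = if (is.null(x$patient_id)) NA_character_
                                  else x$patient_id)
  })
}
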
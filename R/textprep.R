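# Sentence splitting, tokenization, vocabulary, embeddings, batch encoding.

#' Split running text into sentences
#'
#' Rule-based default splitter: a sentence ends at a run of `.`, `?` or `!`
#' followed by whitespace or end of text. The splitter (like the tokenizer)
#' is pluggable everywhere it is consumed, so an external NLP tokenizer can
#' be substituted without touching the rest of the pipeline.
#'
#' @param text A single string.
#' @return Character vector of sentences (terminal punctuation kept).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[[:alnum:]]", text)) {
    stop("empty document: text has no word characters", call. = FALSE)
  }
  m <- regmatches(text, gregexpr("[^.?!]+[.?!]*", text))[[1]]
  m <- trimws(m)
  m[nzchar(m) & grepl("[[:alnum:]]", m)]
}

#' Default whitespace-and-punctuation tokenizer
#'
#' NFC-normalizes, lowercases, splits off `. , ! ? ; :` as their own tokens
#' (apostrophes and hyphens stay inside words), removes CHAT annotation
#' characters, and splits on whitespace.
#'
#' @param sentence A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
default_tokenizer <- function(sentence) {
  x <- tolower(stringi::stri_trans_nfc(sentence))
  x <- gsub(.chat_forbidden_chars, " ", x)
  x <- gsub("([.,!?;:])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Build a vocabulary from a corpus
#'
#' Tokens are indexed by descending corpus frequency, ties broken
#' lexicographically, so the mapping is deterministic. Index 0 is the padding
#' symbol, index 1 the unknown-word symbol; real tokens start at 2. Tokens
#' occurring fewer than `min_count` times are left out and map to UNK at
#' encode time.
#'
#' @param corpus List of [clean_transcript()].
#' @param min_count Minimum corpus frequency for a token to get its own
#'   index; default 1 (no pruning — these corpora are small).
#' @return An object of class `han_vocab`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(min_count >= 1L)
  if (length(corpus) == 0L) {
    stop("input error: empty corpus", call. = FALSE)
  }
  toks <- unlist(lapply(corpus, function(tr) unlist(tr$sentences)),
                 use.names = FALSE)
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  index_to_token <- c("<pad>", "<unk>", names(tab)[ord])
  structure(
    list(token_to_index = stats::setNames(seq_along(index_to_token) - 1L,
                                          index_to_token),
         index_to_token = index_to_token,
         pad_index = 0L, unk_index = 1L,
         min_count = as.integer(min_count),
         size = length(index_to_token)),
    class = "han_vocab")
}

#' @export
print.han_vocab <- function(x, ...) {
  cat(sprintf("<han_vocab> %d symbols (incl. <pad>, <unk>), min_count=%d\n",
              x$size, x$min_count))
  invisible(x)
}

#' Map tokens to integer indices (0-based; unseen tokens map to UNK)
#' @param vocab A `han_vocab`.
#' @param tokens Character vector.
#' @return Integer vector of 0-based indices.
#' @export
vocab_lookup <- function(vocab, tokens) {
  idx <- vocab$token_to_index[tokens]
  idx[is.na(idx)] <- vocab$unk_index
  unname(idx)
}

#' Fraction of corpus tokens that map to the unknown symbol
#' @param corpus List of [clean_transcript()].
#' @param vocab A `han_vocab`.
#' @return Proportion in \[0, 1\].
#' @export
unk_rate <- function(corpus, vocab) {
  toks <- unlist(lapply(corpus, function(tr) unlist(tr$sentences)),
                 use.names = FALSE)
  mean(vocab_lookup(vocab, toks) == vocab$unk_index)
}

.new_embedding <- function(weights, trainable = TRUE) {
  structure(list(weights = weights, dim = ncol(weights),
                 trainable = trainable),
            class = "embedding_matrix")
}

#' Load pretrained word vectors in GloVe text format
#'
#' Each line of the file is `token v1 ... v_dim` (whitespace-delimited).
#' Vocabulary tokens found in the file get the pretrained row; missing
#' tokens (including UNK) are drawn from N(0, 0.1); the padding row is all
#' zeros and stays zero. The same seed always yields the same matrix.
#'
#' @param path Embedding file path.
#' @param vocab A `han_vocab`.
#' @param dim Vector dimension; the default 100 matches the 100-dimensional
#'   GloVe vectors used for model initialization.
#' @param seed Integer seed for the rows that must be drawn.
#' @return An `embedding_matrix` with a `coverage` attribute (fraction of
#'   vocabulary tokens found in the file).
#' @export
load_embeddings <- function(path, vocab, dim = 100L, seed = 1L) {
  if (!file.exists(path)) {
    stop("input error: embedding file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  V <- vocab$size
  W <- withr::with_seed(seed, matrix(stats::rnorm(V * dim, 0, 0.1), V, dim))
  found <- 0L
  wanted <- vocab$token_to_index
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(parts) != dim + 1L) {
      stop("format error: line ", i, " has ", length(parts) - 1L,
           " values, expected ", dim, call. = FALSE)
    }
    j <- wanted[parts[1]]
    if (!is.na(j)) {
      W[j + 1L, ] <- as.numeric(parts[-1])
      found <- found + 1L
    }
  }
  W[vocab$pad_index + 1L, ] <- 0
  rownames(W) <- vocab$index_to_token
  emb <- .new_embedding(W)
  attr(emb, "coverage") <- found / max(1L, V - 2L)
  emb
}

#' Randomly initialized embeddings (no pretrained file)
#'
#' All rows except padding are drawn from N(0, `sd`); used when no GloVe
#' file is supplied, e.g. for synthetic corpora.
#'
#' @param vocab A `han_vocab`.
#' @param dim Vector dimension.
#' @param seed Integer seed.
#' @param sd Standard deviation of the draws, default 0.1.
#' @return An `embedding_matrix`.
#' @export
random_embeddings <- function(vocab, dim = 100L, seed = 1L, sd = 0.1) {
  V <- vocab$size
  W <- withr::with_seed(seed, matrix(stats::rnorm(V * dim, 0, sd), V, dim))
  W[vocab$pad_index + 1L, ] <- 0
  rownames(W) <- vocab$index_to_token
  .new_embedding(W)
}

#' Encode documents into a padded, masked index block
#'
#' Documents are truncated to their first `l_max` sentences and sentences to
#' their first `t_max` tokens; padding positions carry the pad index and a 0
#' mask. Valid positions always form a contiguous prefix at both levels,
#' which the encoders rely on.
#'
#' @param docs List of [clean_transcript()].
#' @param vocab A `han_vocab`.
#' @param l_max Maximum sentences per document.
#' @param t_max Maximum tokens per sentence.
#' @return An object of class `encoded_batch` with fields `token_ids`
#'   (integer array `B x l_max x t_max`, 0-based indices), `word_mask`,
#'   `sentence_mask`, `labels` (0 = CTRL, 1 = AD, NA if unlabeled) and
#'   `doc_ids`.
#' @export
encode_batch <- function(docs, vocab, l_max, t_max) {
  stopifnot(l_max >= 1L, t_max >= 1L, length(docs) >= 1L)
  B <- length(docs)
  ids <- array(vocab$pad_index, dim = c(B, l_max, t_max))
  wmask <- array(0, dim = c(B, l_max, t_max))
  smask <- matrix(0, B, l_max)
  labels <- rep(NA_integer_, B)
  doc_ids <- character(B)
  for (b in seq_len(B)) {
    tr <- docs[[b]]
    doc_ids[b] <- tr$doc_id
    if (!is.na(tr$label)) labels[b] <- if (tr$label == "AD") 1L else 0L
    sents <- tr$sentences[seq_len(min(length(tr$sentences), l_max))]
    if (length(sents) == 0L || all(lengths(sents) == 0L)) {
      stop("input error: document '", tr$doc_id,
           "' is empty after truncation", call. = FALSE)
    }
    for (i in seq_along(sents)) {
      toks <- sents[[i]][seq_len(min(length(sents[[i]]), t_max))]
      n <- length(toks)
      ids[b, i, seq_len(n)] <- vocab_lookup(vocab, toks)
      wmask[b, i, seq_len(n)] <- 1
      smask[b, i] <- 1
    }
  }
  structure(
    list(token_ids = ids, word_mask = wmask, sentence_mask = smask,
         labels = labels, doc_ids = doc_ids,
         l_max = as.integer(l_max), t_max = as.integer(t_max),
         vocab_size = vocab$size),
    class = "encoded_batch")
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat(sprintf("<encoded_batch> %d document(s), l_max=%d, t_max=%d\n",
              length(x$doc_ids), x$l_max, x$t_max))
  invisible(x)
}

# 95th-percentile sizing rule for l_max / t_max, computed on a training split
.size_limits <- function(corpus, prob = 0.95) {
  n_sent <- vapply(corpus, function(tr) length(tr$sentences), 0L)
  n_word <- unlist(lapply(corpus, function(tr) lengths(tr$sentences)),
                   use.names = FALSE)
  list(l_max = max(1L, as.integer(ceiling(stats::quantile(n_sent, prob)))),
       t_max = max(1L, as.integer(ceiling(stats::quantile(n_word, prob)))))
}
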
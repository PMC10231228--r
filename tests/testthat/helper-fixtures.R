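# Shared fixtures: tiny corpora, small-dimension configurations, CHAT file
# builders, and random-document generators for property-style tests.

# A handful of hand-written labeled transcripts with a clear lexical split
tiny_corpus <- function() {
  ad <- list(
    list(c("the", "boy", "uh", "falls", "."), c("uh", "he", "um", ".")),
    list(c("um", "the", "uh", "water", "."), c("she", "uh", "falls", ".")),
    list(c("uh", "um", "he", "."), c("the", "uh", "boy", ".")),
    list(c("he", "um", "uh", "."), c("um", "she", "falls", ".")))
  ctrl <- list(
    list(c("the", "boy", "takes", "cookies", "."),
         c("the", "water", "overflows", ".")),
    list(c("the", "girl", "sees", "the", "stool", "."),
         c("the", "window", "is", "open", ".")),
    list(c("the", "woman", "washes", "dishes", "."),
         c("the", "curtain", "moves", ".")),
    list(c("the", "jar", "falls", "."),
         c("the", "girl", "takes", "the", "plate", ".")))
  c(lapply(seq_along(ad), function(i)
      clean_transcript(sprintf("ad%d", i), ad[[i]], label = "AD")),
    lapply(seq_along(ctrl), function(i)
      clean_transcript(sprintf("ct%d", i), ctrl[[i]], label = "CTRL")))
}

# Small dimensions so unit tests stay fast; protocol-scale defaults are
# exercised by the acceptance tests
tiny_config <- function(seed = 1L, batch_size = 4L, ...) {
  train_config(gru_units = 4L, attn_dim = 3L, embed_dim = 6L,
               batch_size = batch_size, seed = seed, ...)
}

# Random transcript with reproducible content
random_transcript <- function(seed, label = "AD", max_sent = 4L,
                              max_words = 6L) {
  withr::with_seed(seed, {
    pool <- c("boy", "girl", "water", "uh", "um", "he", "the", "falls",
              "window", "cookie", "stool", "sees", "takes")
    n_sent <- sample(max_sent, 1L)
    sentences <- lapply(seq_len(n_sent), function(i) {
      sample(pool, sample(max_words, 1L), replace = TRUE)
    })
    clean_transcript(sprintf("rnd%d", seed), sentences, label = label)
  })
}

random_corpus <- function(n, seed = 1L) {
  lapply(seq_len(n), function(i) {
    random_transcript(seed * 1000L + i,
                      label = if (i %% 2 == 0) "AD" else "CTRL")
  })
}

# Random parameters at small dimensions for forward-pass property tests
random_params <- function(vocab, seed = 1L, u = 4L, a = 3L, d = 6L,
                          sd = 0.4) {
  cfg <- train_config(gru_units = u, attn_dim = a, embed_dim = d,
                      init_std = sd, seed = seed)
  init_params(cfg, vocab, seed = seed)
}

# Probabilities from the reference R forward pass as a B x 2 matrix
forward_probs <- function(enc, params, ...) {
  t(vapply(forward_document(enc, params, ...),
           function(x) x$probabilities, numeric(2)))
}

# Probabilities/loss/gradients from the compiled core
cpp_pass <- function(params, enc, labels = enc$labels, dropout = 0,
                     training = FALSE, seed = 0, uniform_word = FALSE,
                     uniform_sent = FALSE, compute_grad = FALSE,
                     mean_loss = FALSE) {
  lens <- hanscribe:::.enc_lens(enc)
  labels[is.na(labels)] <- -1L
  hanscribe:::cpp_han_pass(
    hanscribe:::.flatten_params(params),
    hanscribe:::.as_int_array(enc$token_ids), lens$wlen, lens$slen,
    as.integer(labels), dropout, training, seed, uniform_word,
    uniform_sent, compute_grad, mean_loss)
}

# Write a small CHAT file with annotation codes; returns the path
write_cha_fixture <- function(path) {
  writeLines(c(
    "@Begin",
    "@Languages:\teng",
    "@Participants:\tPAR Participant, INV Investigator",
    "*INV:\tok tell me what you see .",
    "%mor:\tco|ok pro|me .",
    "*PAR:\tthe boy [//] uh the boy is falling &=laughs .",
    "*PAR:\tthe water",
    "\tis running .",
    "%gra:\t1|2|DET 2|3|SUBJ",
    "*PAR:\t<the window> [/] the window is open@x (.) .",
    "@End"), path, useBytes = TRUE)
  path
}

# CHAT utterance built from random tokens and random annotation codes, with
# the plain tokens it must reduce to
random_chat_utterance <- function(seed) {
  withr::with_seed(seed, {
    words <- sample(c("boy", "girl", "water", "window", "falls", "the"),
                    sample(4:7, 1L), replace = TRUE)
    codes <- c("[//]", "[/]", "[: boy]", "[*]", "&=laughs", "&uh", "(.)",
               "(..)")
    out <- character(0)
    for (w in words) {
      out <- c(out, w)
      if (stats::runif(1) < 0.4) out <- c(out, sample(codes, 1L))
    }
    if (stats::runif(1) < 0.5) {
      k <- sample(length(out), 1L)
      out[k] <- paste0(out[k], "@x")
    }
    list(utterance = paste(c(out, "."), collapse = " "),
         tokens = c(words, "."))
  })
}
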
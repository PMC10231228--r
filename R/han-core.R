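# Reference implementation of the model mathematics: GRU recurrence,
# bidirectional encoding, attention pooling, softmax classification, and the
# negative log-likelihood loss. This pure-R path is the ground truth the
# compiled training core is verified against; it also serves inference and
# attention extraction.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct one GRU parameter set
#'
#' Holds input weights, recurrent weights and bias for each of the three
#' gates: update `z`, reset `r`, and candidate state. Matrices follow the
#' row-vector convention `x %*% W + h %*% U + b`.
#'
#' @param input_dim Input dimension d.
#' @param units Hidden dimension u.
#' @param init Function `(n)` returning n draws for weight entries; defaults
#'   to zeros. Biases are always zero at construction.
#' @return Object of class `gru_params`.
#' @export
gru_params <- function(input_dim, units, init = function(n) numeric(n)) {
  mk <- function(nr, nc) matrix(init(nr * nc), nr, nc)
  structure(
    list(W_z = mk(input_dim, units), U_z = mk(units, units),
         b_z = numeric(units),
         W_r = mk(input_dim, units), U_r = mk(units, units),
         b_r = numeric(units),
         W_c = mk(input_dim, units), U_c = mk(units, units),
         b_c = numeric(units),
         input_dim = as.integer(input_dim), units = as.integer(units)),
    class = "gru_params")
}

#' One GRU recurrence step
#'
#' Gates: update `z = sigma(x W_z + h U_z + b_z)`, reset
#' `r = sigma(x W_r + h U_r + b_r)`, candidate
#' `c = tanh(x W_c + (r * h) U_c + b_c)`, new state
#' `h' = (1 - z) * h + z * c` (elementwise products). The update gate
#' interpolates between the carried state and the candidate; the reset gate
#' damps the recurrent contribution to the candidate.
#'
#' @param x Input vector (length `input_dim`).
#' @param h_prev Previous hidden state (length `units`).
#' @param params A [gru_params()].
#' @return New hidden state, length `units`.
#' @export
gru_step <- function(x, h_prev, params) {
  if (length(x) != params$input_dim || length(h_prev) != params$units) {
    stop("dimension error: x has length ", length(x), " (expected ",
         params$input_dim, "), h_prev has length ", length(h_prev),
         " (expected ", params$units, ")", call. = FALSE)
  }
  z <- .sigmoid(drop(x %*% params$W_z) + drop(h_prev %*% params$U_z) +
                  params$b_z)
  r <- .sigmoid(drop(x %*% params$W_r) + drop(h_prev %*% params$U_r) +
                  params$b_r)
  cand <- tanh(drop(x %*% params$W_c) + drop((r * h_prev) %*% params$U_c) +
                 params$b_c)
  (1 - z) * h_prev + z * cand
}

#' Bidirectional GRU encoding of one sequence
#'
#' Runs a forward GRU left-to-right and a backward GRU right-to-left over the
#' valid prefix of the sequence and concatenates the two hidden states at
#' each position. Masked (padding) positions output zeros and never influence
#' valid positions.
#'
#' @param X Numeric matrix, one row per position (`T x input_dim`).
#' @param fwd,bwd Forward / backward [gru_params()].
#' @param mask Binary vector of length `T`; the 1s must form a contiguous
#'   prefix.
#' @return `T x 2u` matrix `[h_fwd, h_bwd]`.
#' @export
bigru_encode <- function(X, fwd, bwd, mask = rep(1, nrow(X))) {
  X <- rbind(X)
  Tn <- nrow(X)
  stopifnot(length(mask) == Tn)
  n_valid <- sum(mask > 0)
  if (n_valid == 0L) {
    stop("empty-sequence error: no valid positions", call. = FALSE)
  }
  if (any(mask[seq_len(n_valid)] == 0)) {
    stop("mask must mark a contiguous prefix of valid positions",
         call. = FALSE)
  }
  u <- fwd$units
  H <- matrix(0, Tn, 2L * u)
  h <- numeric(u)
  for (t in seq_len(n_valid)) {
    h <- gru_step(X[t, ], h, fwd)
    H[t, seq_len(u)] <- h
  }
  h <- numeric(u)
  for (t in rev(seq_len(n_valid))) {
    h <- gru_step(X[t, ], h, bwd)
    H[t, u + seq_len(u)] <- h
  }
  H
}

#' Construct one attention parameter set
#'
#' Projection `W` (`2u x a`) and bias `b` (`a`) feeding a tanh one-layer
#' perceptron, plus the learned context vector `u_ctx` (`a`) against which
#' projected hidden states are scored.
#'
#' @param hidden_dim Input dimension (2u for bidirectional hidden pairs).
#' @param attn_dim Projection dimension a.
#' @param init Function `(n)` returning draws; defaults to zeros.
#' @return Object of class `attention_params`.
#' @export
attention_params <- function(hidden_dim, attn_dim,
                             init = function(n) numeric(n)) {
  structure(
    list(W = matrix(init(hidden_dim * attn_dim), hidden_dim, attn_dim),
         b = numeric(attn_dim),
         u_ctx = init(attn_dim),
         hidden_dim = as.integer(hidden_dim),
         attn_dim = as.integer(attn_dim)),
    class = "attention_params")
}

#' Attention pooling over a sequence of hidden vectors
#'
#' Scores each valid position by the similarity of its tanh projection to a
#' learned context vector, normalizes the scores with a softmax over valid
#' positions, and returns the weighted sum of hidden vectors. The same
#' operation serves the word level (building sentence vectors) and the
#' sentence level (building the document vector), with independent
#' parameters.
#'
#' @param H Numeric matrix, one hidden vector per row.
#' @param params An [attention_params()].
#' @param mask Binary validity vector (length `nrow(H)`).
#' @param uniform If `TRUE` the learned scores are ignored and weights are
#'   forced to `1/valid-count` — the ablated variant of the layer.
#' @return List with `pooled` (vector) and `weights` (simplex over valid
#'   positions, zeros at masked ones).
#' @export
attention_pool <- function(H, params, mask = rep(1, nrow(H)),
                           uniform = FALSE) {
  H <- rbind(H)
  n <- nrow(H)
  stopifnot(length(mask) == n)
  valid <- which(mask > 0)
  if (length(valid) == 0L) {
    stop("empty-sequence error: all positions masked", call. = FALSE)
  }
  w <- numeric(n)
  if (uniform) {
    w[valid] <- 1 / length(valid)
  } else {
    S <- tanh(sweep(H[valid, , drop = FALSE] %*% params$W, 2L, params$b, "+"))
    e <- drop(S %*% params$u_ctx)
    e <- e - max(e)                       # stable softmax
    w[valid] <- exp(e) / sum(exp(e))
  }
  list(pooled = drop(crossprod(H, w)), weights = w)
}

#' Softmax classification of a document vector
#'
#' `t = softmax(p %*% w + b)`, computed with max-subtraction for numerical
#' stability. Class order: index 1 = CTRL, index 2 = AD (the positive class).
#'
#' @param p Document vector (length 2u).
#' @param w Classifier matrix (`2u x 2`).
#' @param b Classifier bias (length 2).
#' @return Named probability vector `c(CTRL = , AD = )` summing to 1.
#' @export
classify_softmax <- function(p, w, b) {
  if (length(p) != nrow(w) || ncol(w) != length(b)) {
    stop("dimension error in classifier shapes", call. = FALSE)
  }
  logits <- drop(p %*% w) + b
  if (any(!is.finite(logits))) {
    stop("numeric error: non-finite logits", call. = FALSE)
  }
  z <- exp(logits - max(logits))
  stats::setNames(z / sum(z), c("CTRL", "AD"))
}

#' Negative log-likelihood of the correct labels
#'
#' Sum over documents of `-log p(true class)`. Probabilities below 1e-12 are
#' clamped (with a warning) so a confidently wrong prediction cannot produce
#' an infinite loss.
#'
#' @param probabilities Matrix with one row per document and columns
#'   `(CTRL, AD)`, or a single probability vector.
#' @param labels Integer vector, 0 = CTRL, 1 = AD.
#' @return Scalar loss, non-negative.
#' @export
nll_loss <- function(probabilities, labels) {
  P <- rbind(probabilities)
  stopifnot(nrow(P) == length(labels), all(labels %in% c(0L, 1L)))
  p_true <- P[cbind(seq_len(nrow(P)), labels + 1L)]
  if (any(p_true < 1e-12)) {
    warning("probability at true class clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -sum(log(p_true))
}

#' Assemble an attention record
#'
#' Word weights per sentence, sentence weights, and the hierarchically
#' normalized products `m_i * m_it` used for visualization. The record
#' carries three conservation invariants: each valid sentence's word weights
#' sum to 1, the sentence weights sum to 1, and the normalized products sum
#' to 1 over the whole document.
#'
#' @param word_weights List of simplex vectors, one per valid sentence.
#' @param sentence_weights Simplex vector over valid sentences.
#' @return Object of class `attention_record`.
#' @export
attention_record <- function(word_weights, sentence_weights) {
  tol <- 1e-6
  if (abs(sum(sentence_weights) - 1) > tol) {
    stop("input error: sentence weights do not sum to 1", call. = FALSE)
  }
  for (w in word_weights) {
    if (abs(sum(w) - 1) > tol) {
      stop("input error: word weights of a sentence do not sum to 1",
           call. = FALSE)
    }
  }
  normalized <- lapply(seq_along(word_weights), function(i) {
    sentence_weights[i] * word_weights[[i]]
  })
  structure(list(word_weights = word_weights,
                 sentence_weights = sentence_weights,
                 normalized_word_weights = normalized),
            class = "attention_record")
}

#' @export
print.attention_record <- function(x, ...) {
  cat(sprintf("<attention_record> %d sentence(s); weight mass %.6f\n",
              length(x$word_weights),
              sum(unlist(x$normalized_word_weights))))
  invisible(x)
}

.dropout_mask <- function(dim, rate) {
  # inverted dropout: scale kept units by 1/keep so inference needs nothing
  keep <- 1 - rate
  array(stats::rbinom(prod(dim), 1L, keep) / keep, dim = dim)
}

#' Full forward pass of the hierarchical attention network
#'
#' Per document: embed tokens, encode each sentence with the bidirectional
#' word GRU, pool words with word attention into sentence vectors, encode
#' the sentence sequence with the bidirectional sentence GRU, pool sentences
#' with sentence attention into the document vector, classify with softmax.
#' Dropout is applied (only when `training = TRUE`) to embedding output,
#' word-level hidden pairs, sentence vectors, and the document vector.
#'
#' @param batch An [encode_batch()] result.
#' @param params A `han_params` object (see [init_params()]).
#' @param dropout Dropout rate in \[0, 1).
#' @param training If `FALSE` (default) dropout is disabled and the pass is
#'   deterministic.
#' @param seed Seed for dropout draws when `training = TRUE`.
#' @param uniform_word_attn,uniform_sent_attn Replace the named attention
#'   layer by a uniform average (the ablation variants).
#' @return List (one element per document) of class-`han_forward` lists with
#'   fields `probabilities`, `attention` (an [attention_record()]), and
#'   `document_vector`.
#' @export
forward_document <- function(batch, params, dropout = 0, training = FALSE,
                             seed = NULL,
                             uniform_word_attn = FALSE,
                             uniform_sent_attn = FALSE) {
  stopifnot(inherits(batch, "encoded_batch"))
  run <- function() {
    E <- params$embedding$weights
    u <- params$word_gru_fwd$units
    B <- length(batch$doc_ids)
    out <- vector("list", B)
    drop_it <- function(x) {
      if (!training || dropout <= 0) return(x)
      d <- if (is.matrix(x)) dim(x) else length(x)
      x * .dropout_mask(d, dropout)
    }
    for (b in seq_len(B)) {
      L <- sum(batch$sentence_mask[b, ] > 0)
      if (L == 0L) stop("empty-sequence error: document ", b, call. = FALSE)
      P <- matrix(0, L, 2L * u)
      word_weights <- vector("list", L)
      for (i in seq_len(L)) {
        m <- batch$word_mask[b, i, ]
        n <- sum(m > 0)
        ids <- batch$token_ids[b, i, seq_len(n)]
        X <- E[ids + 1L, , drop = FALSE]
        X <- drop_it(X)
        H <- bigru_encode(X, params$word_gru_fwd, params$word_gru_bwd,
                          mask = rep(1, n))
        H <- drop_it(H)
        pool <- attention_pool(H, params$word_attn,
                               uniform = uniform_word_attn)
        P[i, ] <- pool$pooled
        word_weights[[i]] <- pool$weights
      }
      P <- drop_it(P)
      Hs <- bigru_encode(P, params$sent_gru_fwd, params$sent_gru_bwd,
                         mask = rep(1, L))
      pool_s <- attention_pool(Hs, params$sent_attn,
                               uniform = uniform_sent_attn)
      p_doc <- drop_it(pool_s$pooled)
      probs <- classify_softmax(p_doc, params$classifier_w,
                                params$classifier_b)
      out[[b]] <- structure(
        list(probabilities = probs,
             attention = attention_record(word_weights, pool_s$weights),
             document_vector = p_doc),
        class = "han_forward")
    }
    out
  }
  if (training && !is.null(seed)) withr::with_seed(seed, run()) else run()
}
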
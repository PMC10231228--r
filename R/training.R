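# Training protocol: configuration, stratified splits, the Adam loop with
# per-epoch validation and best-epoch selection, five-fold cross-validation,
# and the attention-ablation variants.

#' Training configuration
#'
#' Defaults follow the reference protocol for this model family: 100 GRU
#' units, 50-dimensional attention projections, 100-dimensional embeddings,
#' a fixed 10 epochs with per-epoch validation, Adam at learning rate 0.01,
#' dropout 0.35 on all functional-layer outputs, and N(0, 0.1) weight
#' initialization. Batch size (16) and gradient clipping (global norm 5) are
#' this package's own choices, documented in the methods vignette.
#'
#' @param gru_units Hidden units u per GRU direction.
#' @param attn_dim Attention projection dimension a (both levels).
#' @param embed_dim Word-embedding dimension d.
#' @param epochs Number of training epochs (fixed; no early stopping).
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param dropout Dropout rate in \[0, 1).
#' @param init_std Standard deviation of weight initialization.
#' @param batch_size Documents per gradient step.
#' @param clip_norm Global gradient-norm clip; `Inf` disables.
#' @param min_count Vocabulary pruning threshold (1 = keep everything).
#' @param seed Integer seed; every stochastic draw of a run flows from it.
#' @param ablation One of `"none"`, `"no_word_attn"`, `"no_sentence_attn"`:
#'   the named attention layer is replaced by a uniform average.
#' @return Object of class `train_config`.
#' @export
train_config <- function(gru_units = 100L, attn_dim = 50L, embed_dim = 100L,
                         epochs = 10L, learning_rate = 0.01,
                         optimizer = "adam", dropout = 0.35,
                         init_std = 0.1, batch_size = 16L, clip_norm = 5,
                         min_count = 1L, seed = 1L,
                         ablation = c("none", "no_word_attn",
                                      "no_sentence_attn")) {
  ablation <- match.arg(ablation)
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(gru_units >= 1L, attn_dim >= 1L, embed_dim >= 1L, epochs >= 1L,
            learning_rate > 0, learning_rate <= 1,
            dropout >= 0, dropout < 1, init_std > 0, batch_size >= 1L,
            clip_norm > 0, min_count >= 1L)
  structure(
    list(gru_units = as.integer(gru_units), attn_dim = as.integer(attn_dim),
         embed_dim = as.integer(embed_dim), epochs = as.integer(epochs),
         learning_rate = learning_rate, optimizer = optimizer,
         dropout = dropout, init_std = init_std,
         batch_size = as.integer(batch_size), clip_norm = clip_norm,
         min_count = as.integer(min_count), seed = as.integer(seed),
         ablation = ablation),
    class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(paste0("<train_config> u=%d a=%d d=%d epochs=%d lr=%g ",
                     "dropout=%g batch=%d seed=%d ablation=%s\n"),
              x$gru_units, x$attn_dim, x$embed_dim, x$epochs,
              x$learning_rate, x$dropout, x$batch_size, x$seed, x$ablation))
  invisible(x)
}

#' Derive an ablated configuration
#'
#' Returns `config` with the named attention layer replaced by a uniform
#' average over valid positions; everything else is untouched.
#'
#' @param config A [train_config()].
#' @param which `"no_word_attn"` or `"no_sentence_attn"`.
#' @return A [train_config()].
#' @export
ablate_variant <- function(config,
                           which = c("no_word_attn", "no_sentence_attn")) {
  config$ablation <- match.arg(which)
  config
}

.corpus_labels <- function(corpus) {
  vapply(corpus, function(tr) tr$label, "")
}

# Largest-remainder allocation of n items to ratios
.largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(ratios))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Per-class largest-remainder allocation, so each set's class proportions
#' are within one document of the corpus proportions. With
#' `group_by_patient = TRUE`, allocation happens at the patient level and no
#' patient ever spans two sets (documents without a patient id count as
#' their own singleton group).
#'
#' @param corpus List of labeled [clean_transcript()].
#' @param ratios Positive ratios `(train, val, test)` summing to 1.
#' @param seed Integer seed for the shuffles.
#' @param group_by_patient Keep all of a patient's documents in one set.
#' @return List of integer index vectors `train`, `val`, `test`; disjoint
#'   and exhaustive.
#' @export
make_split <- function(corpus, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                       group_by_patient = FALSE) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  labels <- .corpus_labels(corpus)
  if (any(is.na(labels))) {
    stop("split error: all documents must be labeled", call. = FALSE)
  }
  pid <- vapply(corpus, function(tr) tr$patient_id, "")
  units <- if (group_by_patient) {
    key <- ifelse(is.na(pid) | pid == "",
                  paste0(".doc", seq_along(corpus)), pid)
    split(seq_along(corpus), key)
  } else {
    as.list(seq_along(corpus))
  }
  unit_label <- vapply(units, function(ix) labels[ix[1]], "")
  classes <- sort(unique(unit_label))
  # set sizes come from largest-remainder rounding of the totals; classes
  # then fill them with floor allocations plus remainders by descending
  # fractional part, keeping every set within one unit of exact
  # stratification
  totals <- .largest_remainder(length(units), ratios)
  counts <- matrix(0L, length(classes), 3L,
                   dimnames = list(classes, c("train", "val", "test")))
  fracs <- matrix(0, length(classes), 3L)
  for (ci in seq_along(classes)) {
    raw <- sum(unit_label == classes[ci]) * ratios
    counts[ci, ] <- as.integer(floor(raw))
    fracs[ci, ] <- raw - floor(raw)
  }
  capacity <- totals - colSums(counts)
  for (ci in seq_along(classes)) {
    left <- sum(unit_label == classes[ci]) - sum(counts[ci, ])
    for (s in order(-fracs[ci, ], 1:3)) {
      if (left == 0L) break
      add <- min(left, capacity[s])
      counts[ci, s] <- counts[ci, s] + add
      capacity[s] <- capacity[s] - add
      left <- left - add
    }
  }
  sets <- list(train = integer(0), val = integer(0), test = integer(0))
  withr::with_seed(seed, {
    for (ci in seq_along(classes)) {
      ix <- sample(which(unit_label == classes[ci]))
      cuts <- cumsum(counts[ci, ])
      sets$train <- c(sets$train, unlist(units[ix[seq_len(cuts[1])]]))
      sets$val <- c(sets$val,
                    unlist(units[ix[seq2(cuts[1] + 1L, cuts[2])]]))
      sets$test <- c(sets$test,
                     unlist(units[ix[seq2(cuts[2] + 1L, cuts[3])]]))
    }
  })
  sets <- lapply(sets, function(ix) sort(unname(as.integer(ix))))
  for (nm in names(sets)) {
    got <- unique(labels[sets[[nm]]])
    if (length(got) < length(unique(labels))) {
      stop("split error: set '", nm,
           "' received zero documents of a class", call. = FALSE)
    }
  }
  sets
}

# seq() that returns integer(0) when from > to (base seq would count down)
seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

# Balanced stratified k folds: per class, floor(n/k) everywhere and the
# remainders dealt to the currently smallest folds, so fold sizes differ by
# at most one overall.
.stratified_folds <- function(labels, k, seed = 1L) {
  folds <- vector("list", k)
  totals <- integer(k)
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      ix <- sample(which(labels == cl))
      n <- length(ix)
      counts <- rep(n %/% k, k)
      extras <- n %% k
      if (extras > 0) {
        ord <- order(totals, seq_len(k))
        counts[ord[seq_len(extras)]] <- counts[ord[seq_len(extras)]] + 1L
      }
      at <- 0L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ix[seq2(at + 1L, at + counts[f])])
        at <- at + counts[f]
        totals[f] <- totals[f] + counts[f]
      }
    }
  })
  lapply(folds, function(ix) sort(as.integer(ix)))
}

# ---- optimizer -------------------------------------------------------------

.flatten_grads <- function(grads) {
  out <- list(embedding = grads$embedding)
  for (g in c("wgf", "wgb", "sgf", "sgb")) {
    for (k in .gru_leaf_names) out[[paste0(g, "_", k)]] <- grads[[g]][[k]]
  }
  for (k in c("wa_W", "wa_b", "wa_ctx", "sa_W", "sa_b", "sa_ctx",
              "cls_W", "cls_b")) {
    out[[k]] <- grads[[k]]
  }
  out
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(flat = flat, state = state)
}

.clip_global_norm <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (total > clip) grads <- lapply(grads, function(g) g * (clip / total))
  grads
}

# ---- batch plumbing --------------------------------------------------------

.enc_lens <- function(enc) {
  list(wlen = matrix(as.integer(apply(enc$word_mask, c(1, 2), sum)),
                     nrow = dim(enc$word_mask)[1]),
       slen = as.integer(rowSums(enc$sentence_mask)))
}

.enc_subset <- function(enc, idx) {
  structure(
    list(token_ids = enc$token_ids[idx, , , drop = FALSE],
         word_mask = enc$word_mask[idx, , , drop = FALSE],
         sentence_mask = enc$sentence_mask[idx, , drop = FALSE],
         labels = enc$labels[idx], doc_ids = enc$doc_ids[idx],
         l_max = enc$l_max, t_max = enc$t_max, vocab_size = enc$vocab_size),
    class = "encoded_batch")
}

.ablation_flags <- function(config) {
  list(word = config$ablation == "no_word_attn",
       sent = config$ablation == "no_sentence_attn")
}

# Forward pass through the compiled core; returns B x 2 probability matrix
.han_probs <- function(flat, enc, config) {
  lens <- .enc_lens(enc)
  fl <- .ablation_flags(config)
  labs <- enc$labels
  labs[is.na(labs)] <- -1L
  cpp_han_pass(flat, .as_int_array(enc$token_ids), lens$wlen, lens$slen,
               as.integer(labs), 0, FALSE, 0, fl$word, fl$sent, FALSE,
               TRUE)$probs
}

.as_int_array <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# ---- training --------------------------------------------------------------

#' Train the hierarchical attention network
#'
#' Runs exactly `config$epochs` epochs of Adam over shuffled mini-batches,
#' evaluates validation accuracy after every epoch, and returns the
#' parameters of the epoch with the highest validation accuracy (earliest
#' epoch wins ties). The vocabulary is built on the training and validation
#' documents; padded sizes `l_max`/`t_max` are the 95th percentiles of the
#' training split's sentence and word counts.
#'
#' @param corpus List of labeled [clean_transcript()].
#' @param config A [train_config()].
#' @param embeddings Optional pretrained `embedding_matrix`; when `NULL` the
#'   embedding is initialized from N(0, `init_std`).
#' @param split Optional list of index vectors `train`, `val` (and
#'   optionally `test`, unused here); defaults to a stratified 8:1:1 split
#'   under `config$seed`.
#' @param verbose Print per-epoch loss and validation accuracy.
#' @return Object of class `han_model`: fields `params`, `vocab`, `config`,
#'   `l_max`, `t_max`, and `fold_result` (best epoch, per-epoch validation
#'   accuracy trace, per-epoch mean training loss).
#' @export
train_han <- function(corpus, config = train_config(), embeddings = NULL,
                      split = NULL, verbose = FALSE) {
  if (is.null(split)) {
    split <- make_split(corpus, c(0.8, 0.1, 0.1), seed = config$seed)
  }
  stopifnot(length(split$train) > 0, length(split$val) > 0)
  fit_docs <- corpus[c(split$train, split$val)]
  vocab <- build_vocab(fit_docs, min_count = config$min_count)
  lims <- .size_limits(corpus[split$train])
  enc_train <- encode_batch(corpus[split$train], vocab,
                            lims$l_max, lims$t_max)
  enc_val <- encode_batch(corpus[split$val], vocab, lims$l_max, lims$t_max)
  if (any(is.na(enc_train$labels)) || any(is.na(enc_val$labels))) {
    stop("input error: unlabeled documents in train/validation sets",
         call. = FALSE)
  }
  params <- init_params(config, vocab, embeddings = embeddings,
                        seed = config$seed)
  flat <- .flatten_params(params)
  state <- .adam_init(flat)
  fl <- .ablation_flags(config)
  n_train <- length(split$train)
  val_trace <- numeric(config$epochs)
  loss_trace <- numeric(config$epochs)
  best <- list(acc = -Inf, epoch = NA_integer_, flat = flat)
  lens_train <- .enc_lens(enc_train)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n_train)
      starts <- seq(1L, n_train, by = config$batch_size)
      epoch_loss <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[seq2(starts[bi], min(starts[bi] + config$batch_size - 1L,
                                        n_train))]
        drop_seed <- sample.int(.Machine$integer.max, 1L)
        res <- cpp_han_pass(
          flat, .as_int_array(enc_train$token_ids[idx, , , drop = FALSE]),
          lens_train$wlen[idx, , drop = FALSE], lens_train$slen[idx],
          enc_train$labels[idx], config$dropout, TRUE, drop_seed,
          fl$word, fl$sent, TRUE, TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf("divergence error: non-finite loss at epoch %d batch %d",
                       epoch, bi), call. = FALSE)
        }
        epoch_loss <- epoch_loss + res$loss * length(idx)
        grads <- .clip_global_norm(.flatten_grads(res$grads),
                                   config$clip_norm)
        upd <- .adam_step(flat, grads, state, config$learning_rate)
        flat <- upd$flat
        state <- upd$state
      }
      loss_trace[epoch] <- epoch_loss / n_train
      probs <- .han_probs(flat, enc_val, config)
      acc <- mean((probs[, 2] > 0.5) == (enc_val$labels == 1L))
      val_trace[epoch] <- acc
      if (acc > best$acc) {            # strict: earliest best epoch wins ties
        best <- list(acc = acc, epoch = epoch, flat = flat)
      }
      if (verbose) {
        message(sprintf("epoch %2d  train loss %.4f  val acc %.3f",
                        epoch, loss_trace[epoch], acc))
      }
    }
  })
  structure(
    list(params = .unflatten_params(best$flat, params), vocab = vocab,
         config = config, l_max = lims$l_max, t_max = lims$t_max,
         fold_result = list(best_epoch = best$epoch,
                            validation_accuracy = val_trace,
                            train_loss = loss_trace)),
    class = "han_model")
}

#' @export
print.han_model <- function(x, ...) {
  cat(sprintf(paste0("<han_model> vocab %d, l_max=%d, t_max=%d, ",
                     "best epoch %d (val acc %.3f)\n"),
              x$vocab$size, x$l_max, x$t_max, x$fold_result$best_epoch,
              max(x$fold_result$validation_accuracy)))
  invisible(x)
}

#' Predict classes, probabilities, or full forward outputs
#'
#' @param object A `han_model`.
#' @param corpus List of [clean_transcript()].
#' @param type `"class"` for labels, `"prob"` for the B x 2 probability
#'   matrix, `"forward"` for per-document [forward_document()] outputs
#'   including attention records (computed by the reference R path).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.han_model <- function(object, corpus,
                              type = c("class", "prob", "forward"), ...) {
  type <- match.arg(type)
  enc <- encode_batch(corpus, object$vocab, object$l_max, object$t_max)
  if (type == "forward") {
    fl <- .ablation_flags(object$config)
    return(forward_document(enc, object$params,
                            uniform_word_attn = fl$word,
                            uniform_sent_attn = fl$sent))
  }
  probs <- .han_probs(.flatten_params(object$params), enc, object$config)
  colnames(probs) <- c("CTRL", "AD")
  if (type == "prob") return(probs)
  ifelse(probs[, "AD"] > 0.5, "AD", "CTRL")
}

#' Stratified k-fold cross-validation
#'
#' Per fold: the held-out fold is the test set; one ninth of the remaining
#' documents (stratified) is carved out as the validation set for best-epoch
#' selection; the rest trains the model. Fold metrics are aggregated as
#' their unweighted mean; the pooled confusion matrix is also reported.
#'
#' @param corpus List of labeled [clean_transcript()].
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param embeddings Optional pretrained `embedding_matrix`.
#' @param attention Also compute per-test-document attention records via the
#'   reference forward pass (slower; needed for marker scoring and
#'   visualization).
#' @param verbose Print per-fold progress.
#' @return Object of class `han_cv`: `folds` (list of per-fold results with
#'   `fold_index`, `best_epoch`, `validation_accuracy`, `metrics`,
#'   `test_idx`, `predictions`, and optionally `attention`) and `aggregate`
#'   (mean metrics plus pooled confusion).
#' @export
cross_validate <- function(corpus, config = train_config(), k = 5L,
                           embeddings = NULL, attention = FALSE,
                           verbose = FALSE) {
  stopifnot(k >= 2L)
  labels <- .corpus_labels(corpus)
  folds <- .stratified_folds(labels, k, seed = config$seed)
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    rest <- setdiff(seq_along(corpus), test_idx)
    cfg_f <- config
    cfg_f$seed <- config$seed + 1000L * f
    val_pick <- .stratified_folds(labels[rest], 9L, seed = cfg_f$seed)[[1]]
    split <- list(train = setdiff(seq_along(rest), val_pick),
                  val = val_pick)
    model <- train_han(corpus[rest], cfg_f, embeddings = embeddings,
                       split = split)
    pred <- predict(model, corpus[test_idx], type = "class")
    cm <- confusion_counts(pred, labels[test_idx])
    fr <- list(fold_index = f, best_epoch = model$fold_result$best_epoch,
               validation_accuracy = model$fold_result$validation_accuracy,
               metrics = compute_metrics(cm), test_idx = test_idx,
               predictions = pred, truths = labels[test_idx])
    if (attention) {
      fr$attention <- predict(model, corpus[test_idx], type = "forward")
    }
    fold_results[[f]] <- fr
    if (verbose) {
      message(sprintf("fold %d/%d  acc %.3f", f, k,
                      fr$metrics$accuracy))
    }
  }
  structure(
    list(folds = fold_results,
         aggregate = aggregate_metric_reports(
           lapply(fold_results, `[[`, "metrics"))),
    class = "han_cv")
}

#' @export
print.han_cv <- function(x, ...) {
  agg <- x$aggregate$mean
  cat(sprintf(paste0("<han_cv> %d folds; mean accuracy %.3f, precision ",
                     "%.3f, recall %.3f, F1 %.3f\n"),
              length(x$folds), agg$accuracy, agg$precision, agg$recall,
              agg$f1))
  invisible(x)
}
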
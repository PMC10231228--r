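# The full learnable state of the network, its initialization, and the
# checkpoint format.

.han_params <- function(embedding, word_gru_fwd, word_gru_bwd,
                        sent_gru_fwd, sent_gru_bwd, word_attn, sent_attn,
                        classifier_w, classifier_b) {
  structure(
    list(embedding = embedding,
         word_gru_fwd = word_gru_fwd, word_gru_bwd = word_gru_bwd,
         sent_gru_fwd = sent_gru_fwd, sent_gru_bwd = sent_gru_bwd,
         word_attn = word_attn, sent_attn = sent_attn,
         classifier_w = classifier_w, classifier_b = classifier_b),
    class = "han_params")
}

#' @export
print.han_params <- function(x, ...) {
  d <- ncol(x$embedding$weights)
  u <- x$word_gru_fwd$units
  cat(sprintf(paste0("<han_params> vocab %d, embed %d, GRU units %d, ",
                     "word/sentence attention dims %d/%d\n"),
              nrow(x$embedding$weights), d, u,
              x$word_attn$attn_dim, x$sent_attn$attn_dim))
  invisible(x)
}

#' Initialize all learnable arrays of the network
#'
#' Attention projections and context vectors, GRU weights and classifier
#' weights are drawn from N(0, `init_std`); all biases start at zero; the
#' embedding matrix is copied from `embeddings` when given and drawn
#' otherwise (padding row zero). The same seed always yields identical
#' arrays.
#'
#' @param config A [train_config()].
#' @param vocab A `han_vocab`.
#' @param embeddings Optional `embedding_matrix` (e.g. from
#'   [load_embeddings()]); must match `config$embed_dim` and the vocabulary
#'   size.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `han_params` object.
#' @export
init_params <- function(config, vocab, embeddings = NULL,
                        seed = config$seed) {
  d <- config$embed_dim
  u <- config$gru_units
  a <- config$attn_dim
  sdv <- config$init_std
  if (!is.null(embeddings)) {
    if (ncol(embeddings$weights) != d ||
        nrow(embeddings$weights) != vocab$size) {
      stop("config error: embedding dims (", nrow(embeddings$weights), " x ",
           ncol(embeddings$weights), ") do not match vocabulary/config (",
           vocab$size, " x ", d, ")", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    init <- function(n) stats::rnorm(n, 0, sdv)
    emb <- if (is.null(embeddings)) {
      W <- matrix(init(vocab$size * d), vocab$size, d)
      W[vocab$pad_index + 1L, ] <- 0
      rownames(W) <- vocab$index_to_token
      .new_embedding(W)
    } else embeddings
    .han_params(
      embedding = emb,
      word_gru_fwd = gru_params(d, u, init),
      word_gru_bwd = gru_params(d, u, init),
      sent_gru_fwd = gru_params(2L * u, u, init),
      sent_gru_bwd = gru_params(2L * u, u, init),
      word_attn = attention_params(2L * u, a, init),
      sent_attn = attention_params(2L * u, a, init),
      classifier_w = matrix(init(2L * u * 2L), 2L * u, 2L),
      classifier_b = numeric(2L))
  })
}

# ---- flat-leaf view shared with the compiled core and the optimizer -------

.gru_leaf_names <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wc", "Uc", "bc")
.gru_field_names <- c("W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
                      "W_c", "U_c", "b_c")
.gru_prefixes <- c(word_gru_fwd = "wgf", word_gru_bwd = "wgb",
                   sent_gru_fwd = "sgf", sent_gru_bwd = "sgb")
.attn_prefixes <- c(word_attn = "wa", sent_attn = "sa")

.flatten_params <- function(params) {
  out <- list(embedding = params$embedding$weights)
  for (g in names(.gru_prefixes)) {
    for (k in seq_along(.gru_leaf_names)) {
      out[[paste0(.gru_prefixes[[g]], "_", .gru_leaf_names[k])]] <-
        params[[g]][[.gru_field_names[k]]]
    }
  }
  for (a in names(.attn_prefixes)) {
    p <- .attn_prefixes[[a]]
    out[[paste0(p, "_W")]] <- params[[a]]$W
    out[[paste0(p, "_b")]] <- params[[a]]$b
    out[[paste0(p, "_ctx")]] <- params[[a]]$u_ctx
  }
  out$cls_W <- params$classifier_w
  out$cls_b <- params$classifier_b
  out
}

.unflatten_params <- function(flat, template) {
  params <- template
  W <- flat$embedding
  rownames(W) <- rownames(template$embedding$weights)
  params$embedding$weights <- W
  for (g in names(.gru_prefixes)) {
    for (k in seq_along(.gru_leaf_names)) {
      params[[g]][[.gru_field_names[k]]] <-
        flat[[paste0(.gru_prefixes[[g]], "_", .gru_leaf_names[k])]]
    }
  }
  for (a in names(.attn_prefixes)) {
    p <- .attn_prefixes[[a]]
    params[[a]]$W <- flat[[paste0(p, "_W")]]
    params[[a]]$b <- drop(flat[[paste0(p, "_b")]])
    params[[a]]$u_ctx <- drop(flat[[paste0(p, "_ctx")]])
  }
  params$classifier_w <- flat$cls_W
  params$classifier_b <- drop(flat$cls_b)
  params
}

# ---- checkpoint ------------------------------------------------------------

#' Save / load a trained model
#'
#' The checkpoint is a single JSON file (format version 1) holding a header
#' — dimensions, training configuration, seed, the full vocabulary, and the
#' padded-size limits used at encode time — plus every parameter array. JSON
#' keeps the checkpoint portable and diffable; arrays are written at full
#' double precision.
#'
#' @param model A `han_model` from [train_han()].
#' @param path Output path (by convention `.json`).
#' @return `path` invisibly for the writer; a `han_model` for the reader.
#' @export
save_han_model <- function(model, path) {
  stopifnot(inherits(model, "han_model"))
  flat <- .flatten_params(model$params)
  payload <- list(
    format = "hanscribe-checkpoint", version = 1L,
    config = model$config[setdiff(names(model$config), "class")],
    seed = model$config$seed,
    l_max = model$l_max, t_max = model$t_max,
    vocab = list(index_to_token = model$vocab$index_to_token,
                 min_count = model$vocab$min_count),
    arrays = lapply(flat, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = length(x), data = as.numeric(x))
    }))
  # I(17) = 17 significant digits: doubles survive the decimal round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_han_model
#' @export
load_han_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(x$format, "hanscribe-checkpoint")) {
    stop("input error: not a hanscribe checkpoint: ", path, call. = FALSE)
  }
  vocab <- structure(
    list(token_to_index = stats::setNames(
           seq_along(x$vocab$index_to_token) - 1L, x$vocab$index_to_token),
         index_to_token = x$vocab$index_to_token,
         pad_index = 0L, unk_index = 1L,
         min_count = as.integer(x$vocab$min_count),
         size = length(x$vocab$index_to_token)),
    class = "han_vocab")
  cfg <- do.call(train_config, x$config)
  flat <- lapply(x$arrays, function(a) {
    if (length(a$dim) == 2L) matrix(a$data, a$dim[1], a$dim[2])
    else as.numeric(a$data)
  })
  template <- init_params(cfg, vocab, seed = 0L)
  params <- .unflatten_params(flat, template)
  structure(list(params = params, vocab = vocab, config = cfg,
                 l_max = as.integer(x$l_max), t_max = as.integer(x$t_max)),
            class = "han_model")
}
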
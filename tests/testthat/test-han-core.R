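test_that("gru_step follows the gate equations", {
  p <- gru_params(3L, 3L)                     # all zeros
  v <- c(0.4, -0.2, 0.8)
  # zero parameters: z = 0.5, candidate = 0 -> h' = 0.5 v
  expect_equal(gru_step(c(1, 1, 1), v, p), 0.5 * v)
  # zero state is a fixed point of the zero-parameter cell
  expect_equal(gru_step(c(1, 2, 3), numeric(3), p), numeric(3))
  # saturated update gate hands the state to the candidate: tanh(x W_c)
  p2 <- gru_params(1L, 1L)
  p2$b_z <- 30
  p2$W_c <- matrix(0.7)
  expect_equal(gru_step(0.5, 0.9, p2), tanh(0.35), tolerance = 1e-10)
  expect_error(gru_step(c(1, 2), v, p), "dimension error")
})

test_that("bidirectional encoding runs both directions over the valid prefix", {
  set.seed(2)
  fwd <- gru_params(3L, 2L, stats::rnorm)
  bwd <- gru_params(3L, 2L, stats::rnorm)
  x <- matrix(rnorm(3), 1, 3)
  H1 <- bigru_encode(x, fwd, bwd)
  expect_equal(H1[1, ], c(gru_step(x[1, ], c(0, 0), fwd),
                          gru_step(x[1, ], c(0, 0), bwd)))
  # the backward direction is the forward recurrence on the reversed input
  X <- matrix(rnorm(6), 2, 3)
  H <- bigru_encode(X, fwd, bwd, mask = c(1, 1))
  Hrev <- bigru_encode(X[2:1, , drop = FALSE], bwd, fwd, mask = c(1, 1))
  expect_equal(H[, 3:4], Hrev[2:1, 1:2])
  # appending a masked position changes nothing at valid positions
  Hpad <- bigru_encode(rbind(X, 0), fwd, bwd, mask = c(1, 1, 0))
  expect_equal(Hpad[1:2, ], H)
  expect_equal(Hpad[3, ], rep(0, 4))
  expect_error(bigru_encode(X, fwd, bwd, mask = c(0, 0)), "empty-sequence")
  expect_error(bigru_encode(X, fwd, bwd, mask = c(0, 1)), "contiguous")
})

test_that("attention_pool normalizes over valid positions", {
  set.seed(3)
  ap <- attention_params(4L, 2L, stats::rnorm)
  # identical rows: softmax symmetry forces uniform weights
  H <- matrix(rep(rnorm(4), 3), 3, 4, byrow = TRUE)
  out <- attention_pool(H, ap)
  expect_equal(out$weights, rep(1 / 3, 3))
  expect_equal(out$pooled, H[1, ])
  # single valid position takes all the weight
  out1 <- attention_pool(H, ap, mask = c(1, 0, 0))
  expect_equal(out1$weights, c(1, 0, 0))
  expect_equal(out1$pooled, H[1, ])
  expect_error(attention_pool(H, ap, mask = c(0, 0, 0)), "empty-sequence")
})

test_that("attention weights follow the softmax of projected scores", {
  # a 1-d projection engineered to score (ln 2, 0) -> weights (2/3, 1/3)
  ap <- attention_params(2L, 1L)
  ap$W <- matrix(c(1, 0), 2, 1)
  ap$u_ctx <- 1
  H <- rbind(c(atanh(log(2)), 5), c(0, -1))
  out <- attention_pool(H, ap)
  expect_equal(out$weights, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(out$pooled, (2 * H[1, ] + H[2, ]) / 3, tolerance = 1e-10)
})

test_that("classify_softmax is a stable shift-invariant softmax", {
  expect_equal(unname(classify_softmax(numeric(4), matrix(0, 4, 2),
                                       c(0, 0))),
               c(0.5, 0.5))
  out <- classify_softmax(numeric(4), matrix(0, 4, 2), c(log(3), 0))
  expect_equal(unname(out), c(0.75, 0.25))
  shifted <- classify_softmax(numeric(4), matrix(0, 4, 2),
                              c(log(3), 0) + 123)
  expect_equal(out, shifted)
  # huge logits do not overflow
  big <- classify_softmax(numeric(2), matrix(0, 2, 2), c(1e4, 0))
  expect_equal(sum(big), 1)
  expect_error(classify_softmax(c(Inf, 0), diag(2), c(0, 0)),
               "non-finite")
})

test_that("nll_loss sums -log p(true) with clamping", {
  expect_equal(nll_loss(rbind(c(0, 1), c(1, 0)), c(1L, 0L)), 0)
  expect_equal(nll_loss(rbind(c(0.5, 0.5)), 1L), log(2))
  expect_equal(nll_loss(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(1L, 0L)),
               2 * log(2))
  expect_warning(l <- nll_loss(rbind(c(1, 0)), 1L), "clamped")
  expect_equal(l, -log(1e-12))
})

test_that("forward pass handles the degenerate one-word document", {
  doc <- clean_transcript("d", list("boy"))
  vocab <- build_vocab(list(doc))
  params <- random_params(vocab, seed = 6L)
  enc <- encode_batch(list(doc), vocab, 1L, 1L)
  out <- forward_document(enc, params)[[1]]
  expect_equal(out$attention$word_weights[[1]], 1)
  expect_equal(out$attention$sentence_weights, 1)
  # probability equals classifying the trivially pooled hidden pair
  x <- params$embedding$weights[vocab_lookup(vocab, "boy") + 1L, ]
  h <- c(gru_step(x, numeric(4), params$word_gru_fwd),
         gru_step(x, numeric(4), params$word_gru_bwd))
  hs <- bigru_encode(rbind(h), params$sent_gru_fwd, params$sent_gru_bwd)
  expect_equal(out$probabilities,
               classify_softmax(hs[1, ], params$classifier_w,
                                params$classifier_b))
})

test_that("inference is deterministic; training dropout is seeded", {
  corp <- tiny_corpus()
  vocab <- build_vocab(corp)
  params <- random_params(vocab, seed = 7L)
  enc <- encode_batch(corp, vocab, 2L, 5L)
  expect_identical(forward_probs(enc, params), forward_probs(enc, params))
  r1 <- cpp_pass(params, enc, dropout = 0.35, training = TRUE, seed = 9,
                 compute_grad = TRUE, mean_loss = TRUE)
  r2 <- cpp_pass(params, enc, dropout = 0.35, training = TRUE, seed = 9,
                 compute_grad = TRUE, mean_loss = TRUE)
  expect_identical(r1, r2)
  r3 <- cpp_pass(params, enc, dropout = 0.35, training = TRUE, seed = 10)
  expect_false(identical(r1$probs, r3$probs))
})

test_that("compiled forward agrees with the R reference to double precision", {
  for (seed in 1:5) {
    corp <- random_corpus(6, seed = seed)
    vocab <- build_vocab(corp)
    params <- random_params(vocab, seed = seed)
    enc <- encode_batch(corp, vocab, 4L, 6L)
    pr <- forward_probs(enc, params)
    pc <- cpp_pass(params, enc)$probs
    expect_lt(max(abs(pr - pc)), 1e-12)
    # and under both ablations
    for (abl in list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
      pr <- forward_probs(enc, params, uniform_word_attn = abl[1],
                          uniform_sent_attn = abl[2])
      pc <- cpp_pass(params, enc, uniform_word = abl[1],
                     uniform_sent = abl[2])$probs
      expect_lt(max(abs(pr - pc)), 1e-12)
    }
  }
})

test_that("hidden states stay inside the tanh range", {
  corp <- random_corpus(6, seed = 11L)
  vocab <- build_vocab(corp)
  set.seed(11)
  fwd <- gru_params(6L, 4L, function(n) rnorm(n, 0, 0.8))
  bwd <- gru_params(6L, 4L, function(n) rnorm(n, 0, 0.8))
  for (i in 1:20) {
    X <- matrix(rnorm(5 * 6), 5, 6)
    H <- bigru_encode(X, fwd, bwd)
    expect_true(all(abs(H) < 1))
  }
})

test_that("pooled vectors are convex combinations of their inputs", {
  set.seed(12)
  ap <- attention_params(4L, 3L, stats::rnorm)
  for (i in 1:20) {
    H <- matrix(rnorm(5 * 4, 0, 2), 5, 4)
    out <- attention_pool(H, ap)
    expect_true(all(out$weights >= 0))
    expect_equal(sum(out$weights), 1)
    expect_equal(out$pooled, drop(crossprod(H, out$weights)))
  }
})

test_that("attention_record validates its simplex invariants", {
  rec <- attention_record(list(c(0.5, 0.5), c(1)), c(0.6, 0.4))
  expect_equal(rec$normalized_word_weights[[1]], c(0.3, 0.3))
  expect_error(attention_record(list(c(0.5, 0.4)), 1), "sum to 1")
  expect_error(attention_record(list(1), c(0.7, 0.7)), "sum to 1")
})
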
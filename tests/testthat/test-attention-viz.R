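test_that("hierarchical normalization multiplies through the levels", {
  # single-sentence document: normalized weights equal raw word weights
  rec1 <- attention_record(list(c(0.7, 0.3)), 1)
  norm1 <- normalize_attention(rec1)
  expect_equal(norm1$normalized_word_weights[[1]], c(0.7, 0.3))
  # worked product: (0.6, 0.4) over uniform pairs -> 0.3 0.3 0.2 0.2
  rec2 <- attention_record(list(c(0.5, 0.5), c(0.5, 0.5)), c(0.6, 0.4))
  norm2 <- normalize_attention(rec2)
  expect_equal(unlist(norm2$normalized_word_weights), c(0.3, 0.3, 0.2, 0.2))
  # conservation holds for any valid record
  for (seed in 1:10) {
    rec <- withr::with_seed(seed, {
      L <- sample(1:4, 1)
      ww <- lapply(seq_len(L), function(i) {
        w <- runif(sample(1:5, 1))
        w / sum(w)
      })
      sw <- runif(L)
      attention_record(ww, sw / sum(sw))
    })
    expect_equal(sum(unlist(normalize_attention(rec)$normalized_word_weights)),
                 1, tolerance = 1e-12)
  }
  bad <- rec2
  bad$sentence_weights <- c(0.9, 0.4)
  expect_error(normalize_attention(bad), "simplex")
})

test_that("marker attention scores sum normalized weights at positions", {
  rec <- attention_record(list(c(0.5, 0.3, 0.2)), 1)
  expect_equal(marker_attention_score(rec, cbind(1, c(1, 3))), 0.7)
  # uniform attention over markers covering fraction f scores f
  recu <- attention_record(list(rep(0.25, 4), rep(0.25, 4)), c(0.5, 0.5))
  expect_equal(marker_attention_score(recu, cbind(c(1, 2), c(2, 4))),
               2 / 8)
  # all mass on a single marker token scores 1
  rec1 <- attention_record(list(c(1, 0, 0)), 1)
  expect_equal(marker_attention_score(rec1, cbind(1, 1)), 1)
  expect_equal(marker_attention_score(rec1, matrix(0, 0, 2)), 0)
  expect_error(marker_attention_score(rec1, cbind(2, 1)), "out of range")
  expect_equal(marker_attention_score(rec1, cbind(2, 1), clip = TRUE), 0)
})

test_that("viz documents pair tokens with their normalized weights", {
  tr <- clean_transcript("d", list(c("the", "boy", "."), c("uh", ".")),
                         label = "AD")
  rec <- attention_record(list(c(0.2, 0.7, 0.1), c(0.9, 0.1)),
                          c(0.8, 0.2))
  doc <- viz_document(tr, rec, predicted = "AD", truth = "AD")
  expect_equal(doc$sentences[[1]]$weights, 0.8 * c(0.2, 0.7, 0.1))
  expect_equal(doc$sentences[[2]]$tokens, c("uh", "."))
  expect_equal(sum(unlist(lapply(doc$sentences, `[[`, "weights"))), 1)
})

test_that("rendering is a pure function of its inputs", {
  tr <- clean_transcript("d", list(c("the", "boy", "."), c("uh", ".")),
                         label = "AD")
  rec <- attention_record(list(c(0.2, 0.7, 0.1), c(0.9, 0.1)),
                          c(0.8, 0.2))
  doc <- viz_document(tr, rec, predicted = "AD", truth = "AD")
  f1 <- withr::local_tempfile(fileext = ".html")
  f2 <- withr::local_tempfile(fileext = ".html")
  render_html(list(doc), f1)
  render_html(list(doc), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # stored golden rendering of this fixed document
  golden <- test_path("golden-viz.txt")
  expect_identical(readLines(f1), readLines(golden))
})

test_that("rendered report encodes weights and lexicons as specified", {
  tr <- clean_transcript("d", list(c("the", "boy", "."), c("uh", ".")),
                         label = "AD")
  rec <- attention_record(list(c(0.2, 0.7, 0.1), c(0.9, 0.1)),
                          c(0.8, 0.2))
  doc <- viz_document(tr, rec, predicted = "AD", truth = "AD")
  tr2 <- tr; tr2$doc_id <- "second"
  out <- withr::local_tempfile(fileext = ".html")
  render_html(list(doc, viz_document(tr2, rec)), out)
  html <- paste(readLines(out), collapse = "\n")
  # two blocks, input order preserved
  expect_equal(length(gregexpr("<div class=\"doc\">", html)[[1]]), 2L)
  expect_lt(regexpr("<h2>d</h2>", html), regexpr("<h2>second</h2>", html))
  # the document-maximum token is fully opaque; the max sentence bar too
  expect_match(html, "rgba\\(0,160,0,1\\.000000\\)")
  expect_match(html, "rgba\\(200,0,0,1\\.000000\\)")
  # lexicon tokens are underlined and their mass is reported
  expect_match(html, "class=\"tok lex\"[^>]*>uh</span>")
  expect_match(html, "fillers 0\\.180000")
  # JSON sidecar carries the numeric weights
  side <- jsonlite::fromJSON(paste0(out, ".json"), simplifyVector = FALSE)
  expect_length(side, 2L)
  expect_equal(side[[1]]$lexicon_mass$fillers, 0.2 * 0.9)
})

test_that("a zero-weight token renders transparent", {
  tr <- clean_transcript("d", list(c("a", "b")))
  rec <- attention_record(list(c(1, 0)), 1)
  out <- withr::local_tempfile(fileext = ".html")
  render_html(list(viz_document(tr, rec)), out, lexicons = NULL)
  html <- paste(readLines(out), collapse = "\n")
  expect_match(html, "rgba\\(0,160,0,0\\.000000\\)\">b</span>")
})

test_that("shipped lexicons cover the expected marker families", {
  lex <- han_lexicons()
  expect_setequal(names(lex), c("seed_words", "fillers", "pronouns"))
  expect_length(lex$seed_words, 23L)
  expect_true(all(c("boy", "cookie", "overflow", "kitchen") %in%
                    lex$seed_words))
  expect_setequal(lex$fillers, c("uh", "um"))
  expect_setequal(lex$pronouns, c("he", "she"))
})
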
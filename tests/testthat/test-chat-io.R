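test_that("read_chat_file parses tiers, joins continuations, keeps order", {
  path <- write_cha_fixture(withr::local_tempfile(fileext = ".cha"))
  doc <- read_chat_file(path)
  expect_s3_class(doc, "raw_chat_document")
  expect_equal(doc$tiers$label,
               c("*INV", "%mor", "*PAR", "*PAR", "%gra", "*PAR"))
  # continuation line joined to its owning tier
  expect_equal(doc$tiers$content[4], "the water is running .")
})

test_that("read_chat_file degenerate inputs error informatively", {
  expect_error(read_chat_file(file.path(tempdir(), "nope.cha")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".cha")
  writeLines(character(0), empty)
  expect_error(read_chat_file(empty), "empty document")
  noinv <- withr::local_tempfile(fileext = ".cha")
  writeLines(c("*INV:\thello ."), noinv)
  expect_error(read_chat_file(noinv), "no tier for speaker 'PAR'")
})

test_that("strip_annotations removes codes, keeps pure participant text", {
  path <- write_cha_fixture(withr::local_tempfile(fileext = ".cha"))
  tr <- strip_annotations(read_chat_file(path), label = "AD")
  expect_s3_class(tr, "clean_transcript")
  # retracing marker dropped, both repetitions kept; non-word event dropped
  expect_equal(tr$sentences[[1]],
               c("the", "boy", "uh", "the", "boy", "is", "falling", "."))
  expect_equal(tr$sentences[[2]],
               c("the", "water", "is", "running", "."))
  # angle-bracket scope markers removed (words kept), @-suffix cut to stem,
  # pause symbol removed
  expect_equal(tr$sentences[[3]],
               c("the", "window", "the", "window", "is", "open", "."))
  expect_equal(tr$n_words, sum(lengths(tr$sentences)))
  # dependent tiers and investigator speech never appear
  expect_false(any(grepl("mor|DET|tell", unlist(tr$sentences))))
})

test_that("strip_annotations is the identity on code-free lowercase text", {
  path <- withr::local_tempfile(fileext = ".cha")
  writeLines(c("*PAR:\tThe window is open ."), path)
  tr <- strip_annotations(read_chat_file(path))
  expect_equal(tr$sentences[[1]], c("the", "window", "is", "open", "."))
  # idempotence: re-cleaning already-clean text is token-identical
  path2 <- withr::local_tempfile(fileext = ".cha")
  write_chat_file(tr, path2)
  tr2 <- strip_annotations(read_chat_file(path2))
  expect_identical(tr$sentences, tr2$sentences)
})

test_that("no annotation character survives randomized CHAT input", {
  forbidden <- c("[", "]", "<", ">", "&", "@", "%", "*")
  for (seed in 1:25) {
    u <- random_chat_utterance(seed)
    path <- withr::local_tempfile(fileext = ".cha")
    writeLines(c(sprintf("*PAR:\t%s", u$utterance)), path)
    tr <- strip_annotations(read_chat_file(path))
    toks <- unlist(tr$sentences)
    for (ch in forbidden) {
      expect_false(any(grepl(ch, toks, fixed = TRUE)),
                   label = sprintf("seed %d char %s", seed, ch))
    }
    expect_identical(toks, u$tokens,
                     label = sprintf("seed %d full reduction", seed))
  }
})

test_that("chat round trip preserves token sequences", {
  corp <- generate_corpus(synth_config(n_docs = c(AD = 3, CTRL = 3),
                                       seed = 5L))
  for (tr in corp$transcripts) {
    path <- withr::local_tempfile(fileext = ".cha")
    write_chat_file(tr, path)
    back <- strip_annotations(read_chat_file(path), label = tr$label)
    expect_identical(back$sentences, tr$sentences)
  }
})

test_that("read_plaintext_corpus follows the manifest and folds labels", {
  dir <- withr::local_tempdir()
  writeLines("The boy falls. The water is running.",
             file.path(dir, "d1.txt"))
  writeLines("A girl sees the window!", file.path(dir, "d2.txt"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("doc_id,filename,label,patient_id",
               "d1,d1.txt,ad,p1", "d2,d2.txt,Control,p2"), manifest)
  corp <- read_plaintext_corpus(dir, manifest)
  expect_length(corp, 2L)
  expect_equal(vapply(corp, `[[`, "", "doc_id"), c("d1", "d2"))
  expect_equal(vapply(corp, `[[`, "", "label"), c("AD", "CTRL"))
  expect_equal(vapply(corp, `[[`, "", "patient_id"), c("p1", "p2"))
  expect_equal(corp[[1]]$sentences[[1]], c("the", "boy", "falls", "."))
  expect_length(corp[[1]]$sentences, 2L)
})

test_that("read_plaintext_corpus errors name the offending row", {
  dir <- withr::local_tempdir()
  writeLines("text.", file.path(dir, "ok.txt"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("doc_id,filename,label", "d1,missing.txt,AD"), manifest)
  expect_error(read_plaintext_corpus(dir, manifest), "missing.txt")
  writeLines(c("doc_id,filename,label", "d1,ok.txt,weird"), manifest)
  expect_error(read_plaintext_corpus(dir, manifest), "unknown label")
})

test_that("corpus JSON Lines round trip", {
  corp <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, path)
  back <- read_corpus_jsonl(path)
  expect_length(back, length(corp))
  for (i in seq_along(corp)) {
    expect_identical(back[[i]]$sentences, corp[[i]]$sentences)
    expect_identical(back[[i]]$label, corp[[i]]$label)
  }
})

test_that("clean_transcript enforces its invariants", {
  expect_error(clean_transcript("x", list()), "no sentences")
  expect_error(clean_transcript("x", list(character(0))),
               "at least one token")
  expect_error(clean_transcript("x", list(c("ok", "b[a]d"))),
               "annotation characters")
})
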
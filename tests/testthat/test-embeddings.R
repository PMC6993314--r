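test_that("plain-text embedding files load, validate and round-trip", {
  path <- tempfile()
  writeLines(c("alpha 1 2 3", "beta 4 5 6"), path)
  tab <- load_text_embeddings(path)
  expect_equal(tab$dim, 3L)
  expect_equal(length(tab$vocab), 2L)
  expect_equal(as.numeric(embedding_lookup(tab, "beta")), c(4, 5, 6))
  expect_equal(load_text_embeddings(path, expected_dim = 3)$dim, 3L)
  expect_error(load_text_embeddings(path, expected_dim = 50), "expected 50")
  bad <- tempfile()
  writeLines(c("alpha 1 2 3", "beta 4 5"), bad)
  expect_error(load_text_embeddings(bad), "line 2")
  dup <- tempfile()
  writeLines(c("tok 1 2", "tok 9 9"), dup)
  expect_warning(tdup <- load_text_embeddings(dup), "first occurrence wins")
  expect_equal(as.numeric(embedding_lookup(tdup, "tok")), c(1, 2))
  out <- tempfile()
  write_text_embeddings(tab, out)
  back <- load_text_embeddings(out)
  expect_equal(back$vocab, tab$vocab)
  expect_equal(unname(back$vectors), unname(tab$vectors), tolerance = 1e-6)
})

test_that("lookups are total: unknown tokens fall back to the OOV vector", {
  tab <- embedding_table(matrix(1:6, 3), c("a", "b"))
  expect_equal(as.numeric(embedding_lookup(tab, "zzz")), c(0, 0, 0))
  expect_equal(dim(embedding_lookup(tab, c("a", "zzz", "b", ""))), c(3L, 4L))
  # keys are normalized forms: "A" and digit strings hit normalized entries
  tab2 <- embedding_table(matrix(1:3, 3), "00")
  expect_equal(as.numeric(embedding_lookup(tab2, "42")), 1:3)
})

test_that("skip-gram vocabulary is exactly the min-count frequency filter", {
  set.seed(4)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon")
  for (rep in 1:3) {
    freqs <- sample(1:20, length(words), replace = TRUE)
    sents <- list(rep(words, freqs))
    for (mc in c(2L, 10L)) {
      expected <- sort(words[freqs >= mc])
      if (length(expected) == 0) {
        expect_error(train_skipgram(sents, dim = 8, min_count = mc,
                                    epochs = 1),
                     "too small")
      } else {
        tab <- train_skipgram(sents, dim = 8, min_count = mc, epochs = 1,
                              seed = rep)
        expect_equal(sort(tab$vocab), expected)
        expect_true(all(is.finite(tab$vectors)))
      }
    }
  }
  # a token occurring 9 times misses the default threshold of 10
  sents <- list(c(rep("common", 30), rep("rare", 9)))
  tab <- train_skipgram(sents, dim = 8, min_count = 10, epochs = 1)
  expect_false("rare" %in% tab$vocab)
  expect_true("common" %in% tab$vocab)
})

test_that("skip-gram places tokens with shared contexts close together", {
  # X and Y are interchangeable in their contexts; Z lives elsewhere
  set.seed(2)
  sents <- lapply(1:200, function(i) {
    xy <- sample(c("xx", "yy"), 1)
    c("left", "cue", xy, "right", "tail",
      sample(c("noise1", "noise2", "noise3"), 1),
      "zz", sample(c("other1", "other2"), 1))
  })
  tab <- train_skipgram(sents, dim = 16, min_count = 5, window = 2,
                        epochs = 10, seed = 3)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  v <- function(t) as.numeric(embedding_lookup(tab, t))
  expect_gt(cosine(v("xx"), v("yy")), cosine(v("xx"), v("zz")))
  # determinism under a fixed seed
  tab2 <- train_skipgram(sents, dim = 16, min_count = 5, window = 2,
                         epochs = 10, seed = 3)
  expect_identical(tab$vectors, tab2$vectors)
})

test_that("coverage report counts OOV occurrences and types", {
  corp <- deid_corpus(list(annotated_note("n", "alpha beta alpha gamma",
                                          patient_id = "p")))
  full <- embedding_table(matrix(0, 2, 3), c("alpha", "beta", "gamma"))
  expect_equal(coverage_report(full, corp)$oov_rate, 0)
  none <- embedding_table(matrix(0, 2, 1), "unrelated")
  expect_equal(coverage_report(none, corp)$oov_rate, 1)
  half <- embedding_table(matrix(0, 2, 1), "alpha")
  r <- coverage_report(half, corp)
  expect_equal(r$oov_rate, 0.5)           # 2 of 4 occurrences
  expect_equal(r$type_oov_rate, 2 / 3)    # 2 of 3 types
  expect_equal(coverage_report(full, deid_corpus(list()))$oov_rate, 0)
})
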
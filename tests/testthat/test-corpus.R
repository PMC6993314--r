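test_that("span and note validation enforce the offset contract", {
  expect_error(annotated_note("n1", "short", phi_span(0, 99, "NAME")),
               "invalid span offsets")
  expect_error(annotated_note("n1", "abcdef",
                              rbind(phi_span(0, 4, "NAME"),
                                    phi_span(2, 6, "DATE"))),
               "overlapping")
  expect_error(annotated_note("n1", "abcdef", phi_span(0, 3, "WRONG")),
               "unknown PHI type")
  expect_error(annotated_note("n1", "John London",
                              phi_span(0, 4, "NAME", text = "Jane")),
               "mismatch")
  n <- annotated_note("n1", "John London complains of chest pain",
                      phi_span(0, 11, "NAME"))
  expect_equal(n$spans$text, "John London")
})

test_that("standoff JSONL round-trips corpora field for field", {
  corp <- tiny_corpus(12, seed = 5)
  # add a unicode note to exercise encoding
  corp$notes[[length(corp$notes) + 1L]] <-
    annotated_note("uni-1", "Señor Müller was seen on Janúary 1st.",
                   phi_span(0, 12, "NAME"), patient_id = "PX",
                   note_type = "discharge")
  path <- tempfile(fileext = ".jsonl")
  write_standoff(corp, path)
  back <- read_standoff(path, name = corp$name)
  expect_equal(length(back), length(corp))
  for (i in seq_along(corp$notes)) {
    expect_identical(back$notes[[i]]$text, corp$notes[[i]]$text)
    expect_identical(back$notes[[i]]$note_id, corp$notes[[i]]$note_id)
    expect_identical(back$notes[[i]]$patient_id, corp$notes[[i]]$patient_id)
    expect_equal(back$notes[[i]]$spans, corp$notes[[i]]$spans)
  }
  # writing again gives byte-identical files
  path2 <- tempfile(fileext = ".jsonl")
  write_standoff(back, path2)
  expect_identical(readLines(path, warn = FALSE), readLines(path2, warn = FALSE))
})

test_that("standoff reader handles empty files, bad records and label maps", {
  empty <- tempfile(); file.create(empty)
  expect_equal(length(read_standoff(empty)), 0L)
  bad <- tempfile()
  writeLines(c('{"note_id":"a","text":"ok","spans":[]}', "{not json"), bad)
  expect_error(read_standoff(bad), "line 2")
  over <- tempfile()
  writeLines(paste0('{"note_id":"a","text":"abcdef","spans":',
                    '[{"start":0,"end":20,"type":"NAME"}]}'), over)
  expect_error(read_standoff(over), "invalid span offsets")
  mapped <- tempfile()
  writeLines(paste0('{"note_id":"a","text":"John ok","spans":',
                    '[{"start":0,"end":4,"type":"PATIENT"}]}'), mapped)
  corp <- read_standoff(mapped, label_map = c(PATIENT = "NAME"))
  expect_equal(corp$notes[[1]]$spans$type, "NAME")
})

test_that("BIO materialization follows BIO-2 with the straddle rule", {
  note <- annotated_note("n1", "John London complains",
                         phi_span(0, 11, "NAME"))
  rows <- to_conll(note)
  expect_equal(rows$token, c("John", "London", "complains"))
  expect_equal(rows$tag, c("B-NAME", "I-NAME", "O"))
  # note without spans is all O
  expect_true(all(to_conll(annotated_note("n2", "all clear here"))$tag == "O"))
  # adjacent distinct spans restart with B-
  note3 <- annotated_note("n3", "Smith Jones here",
                          rbind(phi_span(0, 5, "NAME"), phi_span(6, 11, "NAME")))
  expect_equal(to_conll(note3)$tag, c("B-NAME", "B-NAME", "O"))
  # a span cutting through a token labels the whole token, with a warning
  tk <- tokenize("ABCDEF rest")
  expect_warning(tags <- deidtag:::token_bio_tags(tk, phi_span(0, 3, "ID")),
                 "straddles")
  expect_equal(tags[1], "B-ID")
})

test_that("BIO tag sequences from annotations are always well formed", {
  corp <- tiny_corpus(25, seed = 9)
  for (n in corp$notes) {
    tags <- deidtag:::token_bio_tags(tokenize(n$text), n$spans,
                                     warn_straddle = FALSE)
    prev <- "O"
    for (t in tags) {
      if (startsWith(t, "I-"))
        expect_equal(sub("^[BI]-", "", prev), sub("^I-", "", t))
      prev <- t
    }
    # cross-check against the quadratic covering-span oracle
    expect_equal(deidtag:::bio_type(tags),
                 oracle_token_types(tokenize(n$text), n$spans))
  }
})

test_that("patient-level splits are disjoint, sized and deterministic", {
  corp <- tiny_corpus(40, seed = 2)
  for (seed in c(1, 7, 42)) {
    sp <- split_by_patient(corp, 0.75, seed = seed)
    tr <- unique(deidtag:::corpus_patients(sp$train))
    te <- unique(deidtag:::corpus_patients(sp$test))
    expect_length(intersect(tr, te), 0)
    expect_equal(length(sp$train) + length(sp$test), length(corp))
  }
  s1 <- split_by_patient(corp, 0.6, seed = 3)
  s2 <- split_by_patient(corp, 0.6, seed = 3)
  expect_identical(s1, s2)
  # 10 patients x 1 note at f = 0.5 forces a 5/5 split
  notes <- lapply(1:10, function(i)
    annotated_note(paste0("n", i), "text here", patient_id = paste0("p", i)))
  even <- split_by_patient(deid_corpus(notes), 0.5, seed = 1)
  expect_equal(length(even$train), 5L)
  expect_equal(length(even$test), 5L)
  single <- deid_corpus(list(annotated_note("a", "x y", patient_id = "p1"),
                             annotated_note("b", "x y", patient_id = "p1")))
  expect_error(split_by_patient(single, 0.5), "single patient")
})
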
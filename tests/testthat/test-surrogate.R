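intro_text <- "John London complains of chest pain that started on January 1st 2012"
intro_spans <- rbind(phi_span(0, 11, "NAME"), phi_span(52, 68, "DATE"))

test_that("tag redaction reproduces the worked de-identification", {
  expect_equal(
    redact_tags(intro_text, intro_spans),
    "[PersonNameTag] complains of chest pain that started on [DateTag]")
  expect_equal(redact_tags("untouched text", empty_spans()), "untouched text")
  # adjacent spans redact to adjacent tags, order preserved
  expect_equal(redact_tags("Smith Jones x",
                           rbind(phi_span(0, 5, "NAME"),
                                 phi_span(6, 11, "NAME"))),
               "[PersonNameTag] [PersonNameTag] x")
  expect_error(redact_tags("abcdef", rbind(phi_span(0, 4, "NAME"),
                                           phi_span(2, 6, "DATE"))),
               "overlapping")
})

test_that("realistic surrogation is seeded, consistent and non-leaking", {
  lex <- surrogate_lexicon()
  r1 <- surrogate_realistic(intro_text, intro_spans, lex, seed = 41)
  r2 <- surrogate_realistic(intro_text, intro_spans, lex, seed = 41)
  expect_identical(r1, r2)
  r3 <- surrogate_realistic(intro_text, intro_spans, lex, seed = 42)
  expect_false(identical(r1$text, r3$text))
  # originals are gone from the replaced positions
  expect_false(grepl("John London", r1$text, fixed = TRUE))
  expect_false(grepl("January 1st 2012", r1$text, fixed = TRUE))
  expect_equal(r1$map$original, c("John London", "January 1st 2012"))
  # date surrogates preserve the format class
  expect_true(grepl(paste(deidtag:::lex_months, collapse = "|"),
                    r1$map$surrogate[r1$map$type == "DATE"]))
  num <- surrogate_realistic("seen on 01/02/2010 ok",
                             phi_span(8, 18, "DATE"), lex, seed = 1)
  expect_true(grepl("^\\d{2}/\\d{2}/\\d{4}$",
                    num$map$surrogate))
  # consistent mode maps identical surfaces to one surrogate
  text2 <- "Smith seen. Smith left. Jones here."
  spans2 <- rbind(phi_span(0, 5, "NAME"), phi_span(12, 17, "NAME"),
                  phi_span(24, 29, "NAME"))
  rc <- surrogate_realistic(text2, spans2, lex, seed = 7, consistent = TRUE)
  expect_equal(rc$map$surrogate[1], rc$map$surrogate[2])
  # ID and phone shapes are preserved
  idrep <- surrogate_realistic("MRN 1234567 x", phi_span(4, 11, "ID"),
                               lex, seed = 3)
  expect_true(grepl("^\\d{7}$", idrep$map$surrogate))
  ph <- surrogate_realistic("call 555-123-4567 now",
                            phi_span(5, 17, "CONTACT"), lex, seed = 3)
  expect_true(grepl("^\\d{3}-\\d{3}-\\d{4}$", ph$map$surrogate))
})

test_that("redaction audits flag exactly the skipped spans", {
  note_spans <- rbind(phi_span(0, 11, "NAME", "John London"),
                      phi_span(52, 68, "DATE", "January 1st 2012"))
  clean <- redact_tags(intro_text, note_spans)
  expect_equal(nrow(verify_redaction(note_spans, clean)), 0L)
  # skip the date span: exactly one leak of that type
  partial <- redact_tags(intro_text, note_spans[1, , drop = FALSE])
  leaks <- verify_redaction(note_spans, partial)
  expect_equal(nrow(leaks), 1L)
  expect_equal(leaks$type, "DATE")
  # the audit is per note: another note's coincidental match is not its
  # concern
  other_note_output <- "Jack London was here"
  expect_equal(nrow(verify_redaction(
    data.frame(start = 0, end = 3, type = "NAME", text = "disjoint"),
    other_note_output)), 0L)
  # short or dictionary-common surfaces are skipped as unattributable
  expect_equal(nrow(verify_redaction(
    data.frame(start = 0, end = 2, type = "OTHER", text = "JL"),
    "JL still here")), 0L)
})

test_that("surrogation shifts untouched text consistently", {
  res <- surrogate_realistic(intro_text, intro_spans, seed = 12)
  # sentinel substrings between spans relocate intact
  expect_true(grepl(" complains of chest pain that started on ", res$text,
                    fixed = TRUE))
  first_len <- nchar(res$map$surrogate[1])
  expect_equal(substr(res$text, first_len + 2, first_len + 10), "complains")
})
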
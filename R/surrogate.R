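# type -> bracketed tag token used for tag-style redaction
phi_tag_map <- c(NAME = "[PersonNameTag]", DATE = "[DateTag]",
                 LOCATION = "[LocationTag]", ID = "[IdTag]",
                 AGE = "[AgeTag]", CONTACT = "[ContactTag]",
                 PROFESSION = "[ProfessionTag]", OTHER = "[OtherTag]")

check_nonoverlap <- function(spans) {
  if (nrow(spans) > 1L) {
    o <- order(spans$start)
    if (any(spans$start[o][-1L] < spans$end[o][-nrow(spans)]))
      stop("overlapping spans")
  }
  invisible(TRUE)
}

# replace spans right-to-left so earlier offsets stay valid
replace_spans <- function(text, spans, replacements) {
  o <- order(spans$start, decreasing = TRUE)
  for (i in o) {
    text <- paste0(substring(text, 1L, spans$start[i]),
                   replacements[i],
                   substring(text, spans$end[i] + 1L))
  }
  text
}

#' Redact PHI spans with type tags
#'
#' Replaces each span (right to left, so offsets stay valid) with its
#' bracketed type tag: `[PersonNameTag]`, `[DateTag]`, `[LocationTag]`,
#' `[IdTag]`, `[AgeTag]`, `[ContactTag]`, `[ProfessionTag]`, `[OtherTag]`.
#' Text outside the spans is untouched.
#'
#' @param text note text.
#' @param spans span data.frame (`start`, `end`, `type`), non-overlapping.
#' @return the redacted text.
#' @export
#' @examples
#' redact_tags("John London complains of chest pain",
#'             phi_span(0, 11, "NAME"))
redact_tags <- function(text, spans) {
  if (nrow(spans) == 0L) return(text)
  check_nonoverlap(spans)
  unknown <- setdiff(spans$type, names(phi_tag_map))
  if (length(unknown)) stop("no tag for PHI type '", unknown[1], "'")
  replace_spans(text, spans, phi_tag_map[spans$type])
}

#' Surrogate samplers per PHI type
#'
#' One sampler per PHI category, drawing plausible fictitious replacements:
#' names from bundled public name lists, dates preserving the original's
#' format class (month-name, slash or ISO), locations matching the original's
#' shape (unit-style abbreviation vs facility name), IDs and phone numbers
#' regenerated digit for digit, ages in 21-89, professions from a fixed
#' list. Samplers consume the ambient RNG, so they are seeded by the caller
#' ([surrogate_realistic()] does this).
#'
#' @return a `surrogate_lexicon`: named list of functions
#'   `function(original_surface) -> replacement`.
#' @export
surrogate_lexicon <- function() {
  structure(list(
    NAME = function(orig) {
      full <- paste(sample(lex_first_names, 1), sample(lex_last_names, 1))
      if (length(strsplit(orig, "\\s+")[[1]]) < 2L)
        sample(lex_last_names, 1) else full
    },
    DATE = function(orig) {
      y <- sample(2005:2015, 1); m <- sample.int(12, 1); d <- sample.int(28, 1)
      if (grepl(paste(lex_months, collapse = "|"), orig)) {
        sfx <- if (d %in% c(1, 21)) "st" else if (d %in% c(2, 22)) "nd"
               else if (d %in% c(3, 23)) "rd" else "th"
        paste0(lex_months[m], " ", d, sfx, " ", y)
      } else if (grepl("^\\d{4}-", orig)) {
        sprintf("%d-%02d-%02d", y, m, d)
      } else {
        sprintf("%02d/%02d/%d", m, d, y)
      }
    },
    LOCATION = function(orig) {
      if (grepl("^[A-Z]{2,7}$", orig))
        sample(c(lex_jargon_a, lex_jargon_b), 1)
      else paste(sample(lex_cities, 1), sample(lex_hospital_suffixes, 1))
    },
    ID = function(orig) {
      n <- max(nchar(gsub("\\D", "", orig)), 1L)
      paste(sample(0:9, n, replace = TRUE), collapse = "")
    },
    AGE = function(orig) as.character(sample(21:89, 1)),
    CONTACT = function(orig) {
      digits <- as.character(sample(0:9, nchar(orig), replace = TRUE))
      chars <- strsplit(orig, "")[[1]]
      isd <- grepl("[0-9]", chars)
      chars[isd] <- digits[seq_len(sum(isd))]
      paste(chars, collapse = "")
    },
    PROFESSION = function(orig) sample(lex_professions, 1),
    OTHER = function(orig)
      paste0(sample(LETTERS, 1), sample(LETTERS, 1))
  ), class = "surrogate_lexicon")
}

#' Replace PHI spans with realistic surrogates
#'
#' Each span is replaced by a draw from the lexicon's sampler for its type.
#' With `consistent = TRUE`, identical surfaces of the same type within the
#' note map to the same surrogate (one draw, reused). Deterministic given
#' `seed`; the replacement map is returned for audit.
#'
#' @param text note text.
#' @param spans span data.frame, non-overlapping.
#' @param lexicon a [surrogate_lexicon()].
#' @param seed integer seed.
#' @param consistent reuse one surrogate per (type, surface) pair.
#' @return list with `text` (surrogated note) and `map` (data.frame
#'   `type`, `original`, `surrogate`).
#' @export
surrogate_realistic <- function(text, spans, lexicon = surrogate_lexicon(),
                                seed = 1L, consistent = TRUE) {
  if (nrow(spans) == 0L)
    return(list(text = text, map = data.frame(type = character(),
                                              original = character(),
                                              surrogate = character(),
                                              stringsAsFactors = FALSE)))
  check_nonoverlap(spans)
  missing_s <- setdiff(spans$type, names(lexicon))
  if (length(missing_s))
    stop("no surrogate sampler for PHI type '", missing_s[1], "'")
  originals <- substring(text, spans$start + 1L, spans$end)
  reps <- character(nrow(spans))
  with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    for (i in order(spans$start)) {
      key <- paste0(spans$type[i], "\r", originals[i])
      if (consistent && !is.null(seen[[key]])) {
        reps[i] <- seen[[key]]
      } else {
        reps[i] <- lexicon[[spans$type[i]]](originals[i])
        if (consistent) seen[[key]] <- reps[i]
      }
    }
  })
  list(text = replace_spans(text, spans, reps),
       map = data.frame(type = spans$type, original = originals,
                        surrogate = reps, stringsAsFactors = FALSE))
}

#' Audit a redacted note for leaked PHI
#'
#' Lists any gold PHI surface still present verbatim in the output text.
#' Surfaces shorter than 3 characters or equal to common dictionary words
#' are skipped (they cannot be attributed reliably); the check is per note,
#' so a surrogate that coincidentally equals another note's PHI is not
#' flagged. An empty report is a pass.
#'
#' @param original_spans gold span data.frame carrying a `text` column (or
#'   `original_text` from which surfaces are extracted).
#' @param output_text the redacted/surrogated note.
#' @param original_text optional source text to extract surfaces from when
#'   `original_spans$text` is absent.
#' @return data.frame of leaks (`type`, `surface`).
#' @export
verify_redaction <- function(original_spans, output_text,
                             original_text = NULL) {
  if (nrow(original_spans) == 0L)
    return(data.frame(type = character(), surface = character(),
                      stringsAsFactors = FALSE))
  surfaces <- original_spans$text
  if (is.null(surfaces) || all(is.na(surfaces))) {
    if (is.null(original_text))
      stop("spans carry no text; supply original_text")
    surfaces <- substring(original_text, original_spans$start + 1L,
                          original_spans$end)
  }
  common <- c(lex_general_words, tolower(lex_filler_shared))
  keep <- nchar(surfaces) >= 3L & !(tolower(surfaces) %in% common)
  leaked <- keep & vapply(surfaces, function(s)
    grepl(s, output_text, fixed = TRUE), logical(1), USE.NAMES = FALSE)
  data.frame(type = original_spans$type[leaked],
             surface = surfaces[leaked], stringsAsFactors = FALSE)
}
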
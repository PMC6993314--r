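#' Construct a PHI span
#'
#' Character offsets are 0-based and half-open: `start` is the index of the
#' first character, `end` one past the last. `text`, when supplied, must equal
#' the note substring `[start, end)` and is checked at note construction.
#'
#' @param start,end integer offsets, `0 <= start < end`.
#' @param type a PHI category from [phi_types()].
#' @param text optional surface string.
#' @return one-row data.frame with columns `start`, `end`, `type`, `text`.
#' @export
phi_span <- function(start, end, type, text = NA_character_) {
  data.frame(start = as.integer(start), end = as.integer(end),
             type = as.character(type), text = as.character(text),
             stringsAsFactors = FALSE)
}

empty_spans <- function() {
  data.frame(start = integer(), end = integer(), type = character(),
             text = character(), stringsAsFactors = FALSE)
}

#' Construct an annotated note
#'
#' @param note_id unique note identifier.
#' @param text note text.
#' @param spans data.frame of PHI spans (`start`, `end`, `type`, optionally
#'   `text`); validated and sorted by `start`.
#' @param patient_id patient identifier (required for patient-level splits).
#' @param note_type free-text note category (e.g. "discharge", "radiology").
#' @return an `annotated_note` object.
#' @export
annotated_note <- function(note_id, text, spans = empty_spans(),
                           patient_id = NA_character_,
                           note_type = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(spans) || nrow(spans) == 0L) {
    spans <- empty_spans()
  } else {
    spans <- spans[order(spans$start), , drop = FALSE]
    rownames(spans) <- NULL
    if (is.null(spans$text)) spans$text <- NA_character_
    spans$start <- as.integer(spans$start)
    spans$end <- as.integer(spans$end)
    validate_spans(spans, text, note_id)
    spans$text <- substring(text, spans$start + 1L, spans$end)
  }
  structure(list(note_id = as.character(note_id),
                 patient_id = as.character(patient_id),
                 note_type = as.character(note_type),
                 text = text, spans = spans),
            class = "annotated_note")
}

validate_spans <- function(spans, text, note_id) {
  n <- nchar(text)
  bad <- spans$start < 0L | spans$end <= spans$start | spans$end > n
  if (any(bad))
    stop("invalid span offsets in note '", note_id, "': span ",
         which(bad)[1], " [", spans$start[which(bad)[1]], ",",
         spans$end[which(bad)[1]], ") with note length ", n)
  unknown <- !(spans$type %in% phi_types())
  if (any(unknown))
    stop("unknown PHI type '", spans$type[which(unknown)[1]],
         "' in note '", note_id, "'")
  if (nrow(spans) > 1L) {
    prev_end <- spans$end[-nrow(spans)]
    nxt_start <- spans$start[-1L]
    if (any(nxt_start < prev_end))
      stop("overlapping spans in note '", note_id, "'")
  }
  got <- substring(text, spans$start + 1L, spans$end)
  stated <- spans$text
  mism <- !is.na(stated) & stated != got
  if (any(mism))
    stop("span text mismatch in note '", note_id, "': stated '",
         stated[which(mism)[1]], "' but substring is '", got[which(mism)[1]], "'")
  invisible(TRUE)
}

#' Construct a corpus of annotated notes
#'
#' @param notes list of [annotated_note()] objects.
#' @param name corpus name (e.g. the "A"/"B" role in a transfer experiment).
#' @return a `deid_corpus` object.
#' @export
deid_corpus <- function(notes = list(), name = "corpus") {
  ids <- vapply(notes, function(n) n$note_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate note_id: '", ids[duplicated(ids)][1], "'")
  structure(list(notes = notes, name = name), class = "deid_corpus")
}

#' @export
length.deid_corpus <- function(x) length(x$notes)

#' @export
`[.deid_corpus` <- function(x, i) deid_corpus(x$notes[i], name = x$name)

#' @export
print.deid_corpus <- function(x, ...) {
  np <- length(unique(corpus_patients(x)))
  nspan <- sum(vapply(x$notes, function(n) nrow(n$spans), integer(1)))
  cat(sprintf("<deid_corpus '%s': %d notes, %d patients, %d PHI spans>\n",
              x$name, length(x), np, nspan))
  invisible(x)
}

corpus_patients <- function(corpus)
  vapply(corpus$notes, function(n) n$patient_id, character(1))

corpus_texts <- function(corpus)
  vapply(corpus$notes, function(n) n$text, character(1))

#' Read a corpus from JSONL standoff format
#'
#' One JSON object per line with fields `note_id`, `patient_id`, `note_type`,
#' `text` and `spans` (array of `{start, end, type}` with 0-based half-open
#' character offsets). Span invariants are validated on load.
#'
#' @param path file to read.
#' @param name corpus name; defaults to the file name.
#' @param label_map optional named character vector mapping on-disk span
#'   types to the package label set, applied before validation (guideline
#'   reconciliation across corpora); identity by default.
#' @return a `deid_corpus`.
#' @export
read_standoff <- function(path, name = NULL, label_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  notes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e)
                      stop("malformed standoff record at line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(rec$text) || is.null(rec$note_id))
      stop("malformed standoff record at line ", i,
           ": missing 'text' or 'note_id'")
    spans <- rec$spans
    if (is.null(spans) || length(spans) == 0L || NROW(spans) == 0L) {
      spans <- empty_spans()
    } else {
      spans <- as.data.frame(spans, stringsAsFactors = FALSE)
      if (!is.null(label_map)) {
        hit <- spans$type %in% names(label_map)
        spans$type[hit] <- unname(label_map[spans$type[hit]])
      }
    }
    notes[[i]] <- annotated_note(
      note_id = rec$note_id, text = rec$text, spans = spans,
      patient_id = if (is.null(rec$patient_id)) NA_character_ else rec$patient_id,
      note_type = if (is.null(rec$note_type)) NA_character_ else rec$note_type)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  deid_corpus(notes, name = name)
}

#' Write a corpus to JSONL standoff format
#'
#' Inverse of [read_standoff()]: reading a written file reproduces the corpus
#' field for field, in order.
#'
#' @param corpus a `deid_corpus`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(corpus, path) {
  lines <- vapply(corpus$notes, function(n) {
    spans <- lapply(seq_len(nrow(n$spans)), function(i)
      list(start = n$spans$start[i], end = n$spans$end[i],
           type = n$spans$type[i]))
    jsonlite::toJSON(list(note_id = n$note_id, patient_id = n$patient_id,
                          note_type = n$note_type, text = n$text,
                          spans = spans),
                     auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# Assign a BIO-2 tag to every token given gold spans. A token fully inside a
# span gets B-/I- of the span's type (B- on the span's first token); a token
# straddling a span boundary is labeled with the span's type (recall favoring)
# and a warning is raised. All other tokens get "O".
token_bio_tags <- function(tokens, spans, warn_straddle = TRUE) {
  tags <- rep("O", nrow(tokens))
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    hit <- which(tokens$start < e & tokens$end > s & tags == "O")
    if (length(hit) == 0L) next
    straddle <- tokens$start[hit] < s | tokens$end[hit] > e
    if (warn_straddle && any(straddle))
      warning("token straddles span boundary (", spans$type[i], " [", s, ",",
              e, ")); labeled with the span's type", call. = FALSE)
    tags[hit] <- paste0("I-", spans$type[i])
    tags[hit[1]] <- paste0("B-", spans$type[i])
  }
  tags
}

#' Convert a note to CoNLL-style token/tag rows
#'
#' Materializes the note's PHI spans as BIO-2 tags over its tokens: the first
#' token of each span gets `B-<type>`, later tokens `I-<type>`, everything
#' else `O`. A token straddling a span boundary is labeled with the span's
#' type (the recall-favoring choice) and a warning is logged.
#'
#' @param note an [annotated_note()].
#' @param tokens a `token_seq` produced from `note$text` (tokenized on demand
#'   if omitted).
#' @return data.frame with columns `token` and `tag`.
#' @export
to_conll <- function(note, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize(note$text, note$note_id)
  data.frame(token = tokens$text,
             tag = token_bio_tags(tokens, note$spans),
             stringsAsFactors = FALSE)
}

#' Write a corpus as a CoNLL-style file
#'
#' One `token<TAB>tag` per line, with a blank line between notes.
#'
#' @param corpus a `deid_corpus`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (n in corpus$notes) {
    rows <- to_conll(n)
    writeLines(paste(rows$token, rows$tag, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Split a corpus by patient
#'
#' Partitions notes into train and test sets such that no patient appears on
#' both sides. Patients are shuffled with the given seed and the cut point is
#' chosen so that the train side's note-count fraction is as close to
#' `train_fraction` as patient granularity allows.
#'
#' @param corpus a `deid_corpus`; every note must carry a `patient_id`.
#' @param train_fraction target fraction of notes on the train side, in (0,1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train` and `test`, both `deid_corpus`.
#' @export
split_by_patient <- function(corpus, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  pats <- corpus_patients(corpus)
  if (anyNA(pats) || any(pats == "NA"))
    stop("every note needs a patient_id for patient-level splitting")
  upats <- unique(pats)
  if (length(upats) < 2L)
    stop("cannot split a corpus with a single patient")
  ord <- with_seed(seed, sample(upats))
  counts <- table(pats)[ord]
  cum <- cumsum(as.integer(counts))
  k <- which.min(abs(cum / length(corpus) - train_fraction))
  k <- max(1L, min(k, length(upats) - 1L))  # both sides non-empty
  train_p <- ord[seq_len(k)]
  list(train = structure(deid_corpus(corpus$notes[pats %in% train_p],
                                     name = paste0(corpus$name, "-train")),
                         class = "deid_corpus"),
       test = deid_corpus(corpus$notes[!(pats %in% train_p)],
                          name = paste0(corpus$name, "-test")))
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
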
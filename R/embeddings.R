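#' Construct an embedding table
#'
#' A token-to-vector map with a total lookup: any string not in the
#' vocabulary falls back to the out-of-vocabulary vector, which is all zeros
#' by default so that OOV tokens contribute no signal and discrimination is
#' pushed onto the character encoder. Keys are normalized token forms
#' (lowercased, digits mapped to 0); see [normalize_token()].
#'
#' @param vectors numeric matrix, one column per vocabulary token.
#' @param vocab character vector of (normalized) tokens, one per column.
#' @param oov_vector fallback vector; defaults to zeros.
#' @return an `embedding_table` with fields `dim`, `vocab`, `vectors`,
#'   `oov_vector`.
#' @export
embedding_table <- function(vectors, vocab, oov_vector = NULL) {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == length(vocab), all(is.finite(vectors)))
  if (is.null(oov_vector)) oov_vector <- numeric(nrow(vectors))
  stopifnot(length(oov_vector) == nrow(vectors))
  colnames(vectors) <- vocab
  structure(list(dim = nrow(vectors), vocab = vocab, vectors = vectors,
                 oov_vector = as.numeric(oov_vector)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d tokens, dim %d>\n", length(x$vocab), x$dim))
  invisible(x)
}

#' Look up embedding vectors
#'
#' Total on any input: unknown tokens map to the table's OOV vector. Lookups
#' key on the normalized form of the query.
#'
#' @param table an [embedding_table()].
#' @param tokens character vector of token surfaces or normalized forms.
#' @return matrix with `table$dim` rows and one column per query token.
#' @export
embedding_lookup <- function(table, tokens) {
  keys <- normalize_token(tokens)
  idx <- match(keys, table$vocab)
  out <- matrix(table$oov_vector, nrow = table$dim, ncol = length(tokens))
  hit <- !is.na(idx)
  if (any(hit)) out[, hit] <- table$vectors[, idx[hit], drop = FALSE]
  out
}

#' Load embeddings from a plain-text file
#'
#' Standard word-vector text format: one record per line, the token followed
#' by whitespace-separated vector components. The dimensionality is inferred
#' from the first record (and checked against `expected_dim` if given); a
#' record with a different component count is a format error reported with
#' its line number. On duplicate tokens the first record wins.
#'
#' @param path file to read.
#' @param expected_dim optional dimensionality check.
#' @return an [embedding_table()].
#' @export
load_text_embeddings <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  parts <- strsplit(lines, "[ \t]+")
  dim <- length(parts[[1]]) - 1L
  if (!is.null(expected_dim) && dim != expected_dim)
    stop("embedding file has dim ", dim, ", expected ", expected_dim)
  if (dim < 1L) stop("embedding format error at line 1: no vector components")
  toks <- character(length(parts))
  vecs <- matrix(NA_real_, dim, length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != dim + 1L)
      stop("embedding format error at line ", i, ": expected ", dim,
           " components, got ", length(p) - 1L)
    toks[i] <- p[1]
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v))
      stop("embedding format error at line ", i, ": non-numeric component")
    vecs[, i] <- v
  }
  if (anyDuplicated(toks)) {
    warning("duplicate tokens in embedding file; first occurrence wins")
    keep <- !duplicated(toks)
    toks <- toks[keep]
    vecs <- vecs[, keep, drop = FALSE]
  }
  embedding_table(vecs, toks)
}

#' Write embeddings to a plain-text file
#'
#' @param table an [embedding_table()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_text_embeddings <- function(table, path) {
  lines <- paste(table$vocab,
                 apply(table$vectors, 2, function(v)
                   paste(formatC(v, format = "g", digits = 8), collapse = " ")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Train skip-gram embeddings on unlabeled text
#'
#' Word2vec-style skip-gram with negative sampling, trained on tokenized and
#' normalized sentences. Only tokens appearing at least `min_count` times
#' enter the vocabulary (default 10); everything rarer is dropped before
#' context windows are formed. Training is single-threaded and fully
#' deterministic given `seed`.
#'
#' @param sentences list of character vectors (tokens; normalized internally),
#'   or a `deid_corpus` whose note texts are tokenized per line.
#' @param dim embedding dimensionality (default 200, matching the tagger's
#'   default token-embedding size).
#' @param min_count minimum token frequency for vocabulary inclusion.
#' @param window maximum context window (sampled uniformly per position).
#' @param negative number of negative samples per context pair.
#' @param epochs passes over the corpus.
#' @param lr initial learning rate, linearly decayed.
#' @param seed integer seed.
#' @return an [embedding_table()] over the retained vocabulary.
#' @export
train_skipgram <- function(sentences, dim = 200L, min_count = 10L,
                           window = 5L, negative = 5L, epochs = 5L,
                           lr = 0.025, seed = 1L) {
  if (inherits(sentences, "deid_corpus"))
    sentences <- corpus_sentences(sentences)
  sents <- lapply(sentences, normalize_token)
  counts <- table(unlist(sents))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) == 0L)
    stop("no token reaches min_count = ", min_count,
         "; the corpus is too small to build an embedding")
  vocab <- sort(vocab)
  freq <- as.numeric(counts[vocab])
  idx_sents <- lapply(sents, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  idx_sents <- idx_sents[vapply(idx_sents, length, integer(1)) >= 2L]
  if (length(idx_sents) == 0L)
    stop("no usable sentences after frequency filtering")
  vecs <- with_seed(seed,
    cpp_skipgram(idx_sents, freq, as.integer(dim), as.integer(window),
                 as.integer(negative), as.integer(epochs), lr))
  embedding_table(vecs, vocab)
}

# Split a corpus into per-line token lists for embedding training.
corpus_sentences <- function(corpus) {
  out <- list()
  for (n in corpus$notes) {
    for (line in strsplit(n$text, "\n", fixed = TRUE)[[1]]) {
      tk <- tokenize(line)
      if (nrow(tk) > 0) out[[length(out) + 1L]] <- tk$text
    }
  }
  out
}

#' Vocabulary coverage of a corpus by an embedding table
#'
#' Counts, over the corpus's normalized tokens, how many fall outside the
#' table's vocabulary. High OOV rates are the failure mode of under-sized
#' in-domain embeddings.
#'
#' @param table an [embedding_table()].
#' @param corpus a `deid_corpus`.
#' @return list with `tokens_total`, `tokens_oov`, `oov_rate` (occurrence
#'   level; 0 for an empty corpus) and `types_total`, `types_oov`,
#'   `type_oov_rate` (vocabulary level).
#' @export
coverage_report <- function(table, corpus) {
  toks <- unlist(lapply(corpus$notes, function(n) tokenize(n$text)$norm))
  total <- length(toks)
  if (total == 0L)
    return(list(tokens_total = 0L, tokens_oov = 0L, oov_rate = 0,
                types_total = 0L, types_oov = 0L, type_oov_rate = 0))
  oov <- sum(!(toks %in% table$vocab))
  types <- unique(toks)
  toov <- sum(!(types %in% table$vocab))
  list(tokens_total = total, tokens_oov = oov, oov_rate = oov / total,
       types_total = length(types), types_oov = toov,
       type_oov_rate = toov / length(types))
}

#' Random baseline embeddings
#'
#' Assigns each vocabulary token an independent Gaussian vector (scaled by
#' `1/sqrt(dim)`). Such a table carries token identity but no distributional
#' similarity; it serves as a coverage-controlled baseline against trained
#' skip-gram tables.
#'
#' @param vocab character vector of tokens (normalized internally).
#' @param dim dimensionality.
#' @param seed integer seed.
#' @return an [embedding_table()].
#' @export
random_embeddings <- function(vocab, dim = 50L, seed = 1L) {
  vocab <- unique(normalize_token(vocab))
  vecs <- with_seed(seed,
    matrix(stats::rnorm(dim * length(vocab), sd = 1 / sqrt(dim)),
           nrow = dim))
  embedding_table(vecs, vocab)
}
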
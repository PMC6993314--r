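# Shared fixtures and independent oracles for the test suite.

# small architecture used wherever a model must actually be trained
small_mcfg <- function(...) {
  model_config(token_embedding_dim = 30L, char_input_dim = 10L,
               char_hidden = 10L, char_embedding_dim = 10L,
               token_hidden = 30L, ...)
}

small_tcfg <- function(max_epochs = 8L, seed = 1L, ...) {
  train_config(max_epochs = max_epochs, seed = seed, ...)
}

tiny_corpus <- function(n_notes = 40L, seed = 1L, preset = "i2b2-2014", ...) {
  generate_corpus(gen_preset(preset, n_notes = n_notes, seed = seed, ...))
}

tiny_table <- function(corpus, dim = 30L, seed = 1L) {
  train_skipgram(corpus, dim = dim, min_count = 2L, seed = seed)
}

# brute-force CRF oracles: enumerate every path
bf_paths <- function(n, L) as.matrix(expand.grid(rep(list(seq_len(L)), n)))

bf_path_score <- function(emis, y, trans) {
  L <- ncol(emis); n <- nrow(emis)
  s <- trans[L + 1L, y[1]] + emis[1, y[1]]
  if (n > 1) for (t in 2:n) s <- s + trans[y[t - 1], y[t]] + emis[t, y[t]]
  s + trans[y[n], L + 2L]
}

bf_logZ <- function(emis, trans) {
  sc <- apply(bf_paths(nrow(emis), ncol(emis)), 1, bf_path_score,
              emis = emis, trans = trans)
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

bf_viterbi <- function(emis, trans) {
  paths <- bf_paths(nrow(emis), ncol(emis))
  sc <- apply(paths, 1, bf_path_score, emis = emis, trans = trans)
  # expand.grid varies the first position fastest, so among ties the
  # lexicographically-lowest path (in label indices) comes first
  best <- which(sc == max(sc))
  list(path = as.integer(paths[best[1], ]), score = max(sc),
       n_ties = length(best))
}

random_crf_instance <- function(max_len = 6L, max_labels = 5L) {
  n <- sample(seq_len(max_len), 1)
  L <- sample(2:max_labels, 1)
  list(emis = matrix(stats::rnorm(n * L), n, L),
       trans = matrix(stats::rnorm((L + 2)^2), L + 2, L + 2))
}

# Independent token labeling oracle: for each token find the covering span
# by scanning all spans (quadratic, unlike the implementation's loop).
oracle_token_types <- function(tokens, spans) {
  vapply(seq_len(nrow(tokens)), function(i) {
    for (j in seq_len(nrow(spans))) {
      if (tokens$start[i] < spans$end[j] && tokens$end[i] > spans$start[j])
        return(spans$type[j])
    }
    NA_character_
  }, character(1))
}
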
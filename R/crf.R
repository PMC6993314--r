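#' Linear-chain CRF log-likelihood
#'
#' Computes `score(gold) - logZ`, where the path score sums per-token emission
#' scores and pairwise transition scores (including virtual start/stop
#' transitions), and the partition function `logZ` is computed by the forward
#' algorithm in log space. The result is always `<= 0`.
#'
#' @param emissions numeric matrix, one row per token, one column per label.
#' @param gold integer vector of 1-based label indices, or a character vector
#'   of labels resolved against `labels`.
#' @param transitions square matrix of size `nlabels + 2`; row = from,
#'   column = to. Index `nlabels + 1` is the virtual start state,
#'   `nlabels + 2` the stop state; neither is ever emitted.
#' @param labels optional label set used to resolve a character `gold`.
#' @return the log-likelihood, a scalar `<= 0`.
#' @export
crf_log_likelihood <- function(emissions, gold, transitions, labels = NULL) {
  emissions <- as.matrix(emissions)
  gold <- resolve_labels(gold, ncol(emissions), labels)
  if (length(gold) != nrow(emissions))
    stop("gold length (", length(gold), ") != sequence length (",
         nrow(emissions), ")")
  check_transitions(transitions, ncol(emissions))
  cpp_crf_loglik(emissions, as.integer(gold - 1L), transitions)
}

#' CRF partition function (forward algorithm)
#'
#' @inheritParams crf_log_likelihood
#' @return `logZ`, the log-sum-exp of all path scores.
#' @export
crf_logZ <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  check_transitions(transitions, ncol(emissions))
  cpp_crf_logZ(emissions, transitions)
}

#' CRF Viterbi decoding
#'
#' Returns an argmax-scoring label path. Ties are broken toward the lowest
#' label index at every backpointer, so under fully uniform scores the path
#' is all label 1 (the `"O"` tag in this package's label order).
#'
#' @inheritParams crf_log_likelihood
#' @return list with `path` (1-based label indices) and `score`.
#' @export
crf_viterbi <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) == 0L) stop("empty emission matrix")
  check_transitions(transitions, ncol(emissions))
  res <- cpp_crf_viterbi(emissions, transitions)
  list(path = as.integer(res$path) + 1L, score = res$score)
}

check_transitions <- function(transitions, n_labels) {
  if (!is.matrix(transitions) || nrow(transitions) != n_labels + 2L ||
      ncol(transitions) != n_labels + 2L)
    stop("transitions must be a square matrix of size nlabels + 2 (start/stop)")
  invisible(TRUE)
}

resolve_labels <- function(gold, n_labels, labels) {
  if (is.character(gold)) {
    if (is.null(labels)) labels <- bio_labels()
    idx <- match(gold, labels)
    if (anyNA(idx)) stop("unknown label: '", gold[which(is.na(idx))[1]], "'")
    idx
  } else {
    gold <- as.integer(gold)
    if (any(gold < 1L | gold > n_labels))
      stop("gold label index outside 1..", n_labels)
    gold
  }
}
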
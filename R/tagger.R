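#' Tagger architecture configuration
#'
#' Dimensions and regularization of the neural tagger: a character-level
#' bidirectional recurrent encoder (per-direction size `char_hidden`, final
#' states concatenated and affinely mapped to `char_embedding_dim`), a
#' token-level bidirectional recurrent context encoder (per-direction size
#' `token_hidden`, so the contextual output has `2 * token_hidden`
#' dimensions), and an affine projection onto the BIO label scores consumed
#' by the CRF. Defaults follow the reference architecture: 200-dimensional
#' pretrained token embeddings, a 25-dimensional character encoding, a
#' 200-dimensional contextual output, dropout 0.5 on the concatenated
#' per-token input and on the contextual output.
#'
#' @param token_embedding_dim dimensionality of the pretrained embeddings.
#' @param char_input_dim size of the learned per-character input embedding.
#' @param char_hidden per-direction recurrent size of the character encoder.
#' @param char_embedding_dim output size of the character encoder.
#' @param token_hidden per-direction recurrent size of the token encoder.
#' @param dropout dropout rate in `[0, 1)`.
#' @param cell recurrent cell type, `"lstm"` (default) or `"rnn"` (plain
#'   tanh cell).
#' @param train_embeddings if `TRUE`, pretrained embedding rows receive
#'   gradient updates; frozen by default.
#' @param labels BIO label set (fixed order; `"O"` first).
#' @return a `model_config` list.
#' @export
model_config <- function(token_embedding_dim = 200L, char_input_dim = 25L,
                         char_hidden = 25L, char_embedding_dim = 25L,
                         token_hidden = 100L, dropout = 0.5,
                         cell = c("lstm", "rnn"), train_embeddings = FALSE,
                         labels = bio_labels()) {
  cell <- match.arg(cell)
  stopifnot(token_embedding_dim > 0, char_input_dim > 0, char_hidden > 0,
            char_embedding_dim > 0, token_hidden > 0,
            dropout >= 0, dropout < 1)
  structure(list(token_embedding_dim = as.integer(token_embedding_dim),
                 char_input_dim = as.integer(char_input_dim),
                 char_hidden = as.integer(char_hidden),
                 char_embedding_dim = as.integer(char_embedding_dim),
                 token_hidden = as.integer(token_hidden),
                 dropout = dropout, cell = cell,
                 train_embeddings = isTRUE(train_embeddings),
                 labels = labels, feat_dim = 6L),
            class = "model_config")
}

#' Training configuration
#'
#' Stochastic training with Adagrad (learning rate 0.1) on minibatches of 20
#' notes, minimizing the mean negative CRF log-likelihood (cross-entropy over
#' label sequences). A patient-level fraction of the training notes is held
#' out as a development set; training stops when the development token F1 has
#' not improved for `patience` epochs and the best-development checkpoint is
#' returned.
#'
#' @param lr Adagrad learning rate.
#' @param batch_size notes per minibatch.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience on development F1.
#' @param dev_fraction fraction of training notes held out, in (0, 1).
#' @param seed integer seed governing parameter initialization, dropout
#'   masks and batch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.1, batch_size = 20L, max_epochs = 100L,
                         patience = 5L, dev_fraction = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, dev_fraction > 0, dev_fraction < 1, lr > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 dev_fraction = dev_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter initialization ---------------------------------------------

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

recur_params <- function(hidden, input, cell) {
  g <- if (cell == "lstm") 4L else 1L
  b <- numeric(g * hidden)
  if (cell == "lstm") b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(W = glorot(g * hidden, input), U = glorot(g * hidden, hidden), b = b)
}

init_params <- function(mcfg, n_chars) {
  L <- length(mcfg$labels)
  din <- mcfg$token_embedding_dim + mcfg$char_embedding_dim + mcfg$feat_dim
  cf <- recur_params(mcfg$char_hidden, mcfg$char_input_dim, mcfg$cell)
  cb <- recur_params(mcfg$char_hidden, mcfg$char_input_dim, mcfg$cell)
  tf <- recur_params(mcfg$token_hidden, din, mcfg$cell)
  tb <- recur_params(mcfg$token_hidden, din, mcfg$cell)
  list(C_emb = glorot(mcfg$char_input_dim, n_chars),
       Wc_f = cf$W, Uc_f = cf$U, bc_f = cf$b,
       Wc_b = cb$W, Uc_b = cb$U, bc_b = cb$b,
       Pc = glorot(mcfg$char_embedding_dim, 2L * mcfg$char_hidden),
       pc = numeric(mcfg$char_embedding_dim),
       Wt_f = tf$W, Ut_f = tf$U, bt_f = tf$b,
       Wt_b = tb$W, Ut_b = tb$U, bt_b = tb$b,
       Wo = glorot(L, 2L * mcfg$token_hidden), bo = numeric(L),
       trans = matrix(0, L + 2L, L + 2L))
}

# character vocabulary: index 1 is the reserved unknown-character slot
build_char_vocab <- function(corpus) {
  chars <- unique(unlist(strsplit(corpus_texts(corpus), "")))
  chars <- setdiff(sort(chars), c(" ", "\n", "\t", "\r"))
  c("<unk>", chars)
}

char_indices <- function(surface, char_vocab) {
  idx <- match(strsplit(surface, "")[[1]], char_vocab)
  idx[is.na(idx)] <- 1L
  as.integer(idx - 1L)  # 0-based for the C++ core
}

#' Initialize an untrained tagger
#'
#' @param mcfg a [model_config()].
#' @param char_vocab character vocabulary (first entry is the unknown slot);
#'   typically built from the training corpus.
#' @param seed integer seed for parameter initialization.
#' @return a `deid_tagger` with zero-initialized CRF transitions, a zero
#'   not-PHI bias and randomly initialized encoder weights.
#' @export
init_tagger <- function(mcfg, char_vocab, seed = 1L) {
  params <- with_seed(seed, init_params(mcfg, length(char_vocab)))
  structure(list(schema_version = 1L, config = mcfg, char_vocab = char_vocab,
                 params = params, not_phi_bias = 0,
                 history = data.frame()),
            class = "deid_tagger")
}

#' @export
print.deid_tagger <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<deid_tagger: %s cells, %d labels, %d chars, %d parameters%s>\n",
    x$config$cell, length(x$config$labels), length(x$char_vocab), np,
    if (nrow(x$history) > 0)
      sprintf(", best dev F1 %.3f", max(x$history$dev_f1, na.rm = TRUE))
    else ", untrained"))
  invisible(x)
}

# ---- input preparation -----------------------------------------------------

# Assemble the C++-facing representation of one token sequence.
prepare_seq <- function(tokens, table, model) {
  list(emb = embedding_lookup(table, tokens$text),
       chars = lapply(tokens$text, char_indices,
                      char_vocab = model$char_vocab),
       feats = t(casing_spacing_features(tokens)))
}

prepare_note <- function(note, table, model, labels = TRUE) {
  tokens <- tokenize(note$text, note$note_id)
  if (nrow(tokens) == 0L) return(NULL)
  x <- prepare_seq(tokens, table, model)
  if (labels) {
    tags <- token_bio_tags(tokens, note$spans, warn_straddle = FALSE)
    x$labels <- as.integer(match(tags, model$config$labels) - 1L)
  }
  x$tokens <- tokens
  x
}

#' Character-level encoding of a single token
#'
#' Runs the character bidirectional encoder over the token's surface
#' characters and maps the concatenated final states to the character
#' embedding space. Deterministic at inference; depends only on the surface
#' string. Characters outside the model's vocabulary map to the reserved
#' unknown index.
#'
#' @param token a token surface string.
#' @param model a `deid_tagger`.
#' @return numeric vector of length `char_embedding_dim`.
#' @export
encode_chars <- function(token, model) {
  stopifnot(is.character(token), length(token) == 1L, nchar(token) > 0L)
  as.numeric(cpp_char_encode(model$params, char_indices(token, model$char_vocab),
                             model$config$cell == "lstm"))
}

#' Emission scores for a token sequence
#'
#' Concatenates, per token, the pretrained embedding, the character encoding
#' and the casing/spacing features; runs the token-level bidirectional
#' encoder; and projects the contextual output onto BIO label scores. The
#' not-PHI bias is added to every `"O"` score before the CRF consumes the
#' matrix. Dropout (on the concatenated input and on the contextual output)
#' is applied only when `train_mode = TRUE`.
#'
#' @param seq a `token_seq` from [tokenize()] (non-empty).
#' @param table an [embedding_table()].
#' @param model a `deid_tagger`.
#' @param train_mode draw dropout masks (from the current RNG state).
#' @param not_phi_bias scalar added to the `"O"` column; defaults to the
#'   model's stored bias.
#' @return numeric matrix, `nrow(seq)` rows by `length(labels)` columns.
#' @export
encode_sequence <- function(seq, table, model, train_mode = FALSE,
                            not_phi_bias = model$not_phi_bias) {
  if (nrow(seq) == 0L) stop("empty token sequence")
  x <- prepare_seq(seq, table, model)
  emis <- cpp_emissions(model$params, x, model$config$cell == "lstm",
                        if (train_mode) model$config$dropout else 0)
  colnames(emis) <- model$config$labels
  emis[, 1L] <- emis[, 1L] + not_phi_bias
  emis
}

# ---- training --------------------------------------------------------------

adagrad_state <- function(params) lapply(params, function(p) p * 0)

adagrad_step <- function(params, grads, acc, lr, eps = 1e-8) {
  for (nm in names(params)) {
    acc[[nm]] <- acc[[nm]] + grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * grads[[nm]] / (sqrt(acc[[nm]]) + eps)
  }
  list(params = params, acc = acc)
}

# token-level all-PHI F1 on prepared dev notes (bias 0)
dev_f1 <- function(params, dev_prep, lstm) {
  tp <- fp <- fn <- 0L
  for (x in dev_prep) {
    emis <- cpp_emissions(params, x, lstm)
    pred <- as.integer(cpp_crf_viterbi(emis, params$trans)$path)  # 0-based
    gold <- x$labels
    tp <- tp + sum(pred > 0L & gold > 0L)
    fp <- fp + sum(pred > 0L & gold == 0L)
    fn <- fn + sum(pred == 0L & gold > 0L)
  }
  if (tp == 0L) return(0)
  r <- tp / (tp + fn); p <- tp / (tp + fp)
  2 * r * p / (r + p)
}

split_dev <- function(corpus, dev_fraction, seed) {
  pats <- unique(corpus_patients(corpus))
  if (length(pats) >= 2L) {
    sp <- split_by_patient(corpus, train_fraction = 1 - dev_fraction,
                           seed = seed)
    list(train = sp$train, dev = sp$test)
  } else {
    n <- length(corpus)
    ndev <- max(1L, round(dev_fraction * n))
    idx <- with_seed(seed, sample(n, ndev))
    list(train = corpus[setdiff(seq_len(n), idx)], dev = corpus[idx])
  }
}

#' Train the tagger
#'
#' Minimizes the mean negative CRF log-likelihood over minibatches with
#' Adagrad, evaluating token-level PHI F1 on a held-out development split
#' after every epoch, and returns the parameters of the best-development
#' epoch. Fully deterministic given `tcfg$seed`.
#'
#' @param train_corpus labeled `deid_corpus`; must contain at least one PHI
#'   span.
#' @param table an [embedding_table()] supplying (frozen, unless
#'   `mcfg$train_embeddings`) token vectors.
#' @param mcfg a [model_config()]; its `token_embedding_dim` must match the
#'   table (it is aligned automatically).
#' @param tcfg a [train_config()].
#' @param mix_with optional second labeled corpus: every minibatch is then
#'   drawn half from `train_corpus` and half from `mix_with`, the smaller
#'   side resampled with replacement (the "A mix B" regime).
#' @param init_model optional `deid_tagger` to continue from (used by
#'   [fine_tune()]); optimizer accumulators start fresh.
#' @param verbose print per-epoch loss and development F1.
#' @return a trained `deid_tagger`; `$history` records per-epoch mean loss
#'   and development F1, `$table` echoes the embedding table when embedding
#'   fine-tuning is on.
#' @export
train_tagger <- function(train_corpus, table, mcfg = model_config(),
                         tcfg = train_config(), mix_with = NULL,
                         init_model = NULL, verbose = FALSE) {
  n_spans <- sum(vapply(train_corpus$notes, function(n) nrow(n$spans),
                        integer(1)))
  if (length(train_corpus) == 0L || n_spans == 0L)
    stop("training corpus contains no PHI spans; cannot learn a tagger")
  if (mcfg$token_embedding_dim != table$dim) {
    mcfg$token_embedding_dim <- table$dim
  }

  sp <- split_dev(train_corpus, tcfg$dev_fraction, tcfg$seed)
  model <- if (is.null(init_model))
    init_tagger(mcfg, build_char_vocab(sp$train), seed = tcfg$seed)
  else init_model
  mcfg <- model$config
  lstm <- mcfg$cell == "lstm"

  prep <- function(corp) Filter(Negate(is.null),
    lapply(corp$notes, prepare_note, table = table, model = model))
  train_prep <- prep(sp$train)
  dev_prep <- prep(sp$dev)
  mix_prep <- if (!is.null(mix_with)) prep(mix_with) else NULL
  if (length(train_prep) == 0L) stop("no non-empty training notes")

  params <- model$params
  acc <- adagrad_state(params)
  emb_vectors <- table$vectors
  emb_acc <- if (mcfg$train_embeddings) emb_vectors * 0 else NULL

  # when continuing from a pre-trained model, the unmodified parameters are
  # the epoch-0 candidate: further training must beat them on dev to replace
  # them
  best <- if (!is.null(init_model) && length(dev_prep) > 0)
    list(f1 = dev_f1(params, dev_prep, lstm), params = params, epoch = 0L)
  else list(f1 = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric())
  wait <- 0L
  b <- tcfg$batch_size

  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample(length(train_prep))
      losses <- c()
      half <- if (!is.null(mix_prep)) max(1L, b %/% 2L) else b
      starts <- seq(1L, length(ord), by = half)
      for (s in starts) {
        idx <- ord[s:min(s + half - 1L, length(ord))]
        batch <- train_prep[idx]
        if (!is.null(mix_prep)) {
          # even mixture: supplement with an equal-sized draw from the
          # other corpus, resampling with replacement if it is smaller
          j <- sample(length(mix_prep), length(idx),
                      replace = length(mix_prep) < length(idx))
          batch <- c(batch, mix_prep[j])
        }
        if (mcfg$train_embeddings)
          batch <- lapply(batch, function(x) {
            x$emb <- embedding_lookup_mat(emb_vectors, table, x$tokens$text)
            x
          })
        res <- cpp_batch_grad(params, batch, lstm, mcfg$dropout,
                              mcfg$train_embeddings)
        losses <- c(losses, res$loss)
        st <- adagrad_step(params, res$grads, acc, tcfg$lr)
        params <- st$params; acc <- st$acc
        if (mcfg$train_embeddings) {
          for (k in seq_along(batch)) {
            hit <- match(batch[[k]]$tokens$norm, table$vocab)
            ok <- which(!is.na(hit))
            if (length(ok) == 0L) next
            g <- res$demb[[k]][, ok, drop = FALSE] / length(batch)
            cols <- hit[ok]
            emb_acc[, cols] <- emb_acc[, cols] + g^2
            emb_vectors[, cols] <- emb_vectors[, cols] -
              tcfg$lr * g / (sqrt(emb_acc[, cols]) + 1e-8)
          }
        }
      }
      # with no usable dev notes fall back to training loss as the criterion
      f1 <- if (length(dev_prep) > 0) dev_f1(params, dev_prep, lstm)
            else -mean(losses)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = mean(losses), dev_f1 = f1))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dev F1 %.4f", epoch,
                        mean(losses), f1))
      if (f1 > best$f1 + 1e-9) {
        best <- list(f1 = f1, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tcfg$patience) break
      }
    }
  })

  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$not_phi_bias <- 0
  if (mcfg$train_embeddings)
    model$table <- embedding_table(emb_vectors, table$vocab, table$oov_vector)
  model
}

# lookup against a (possibly updated) vector matrix sharing `table`'s vocab
embedding_lookup_mat <- function(vectors, table, tokens) {
  keys <- normalize_token(tokens)
  idx <- match(keys, table$vocab)
  out <- matrix(table$oov_vector, nrow = nrow(vectors), ncol = length(tokens))
  hit <- !is.na(idx)
  if (any(hit)) out[, hit] <- vectors[, idx[hit], drop = FALSE]
  out
}

#' Continue training a tagger on a new corpus
#'
#' The "A then B" customization regime: optimization continues from the
#' model's current parameters on corpus B only, with fresh Adagrad
#' accumulators and the usual development-split early stopping on B. With
#' `max_epochs = 0` the model is returned unchanged.
#'
#' @param model a trained `deid_tagger`.
#' @param corpus_b labeled target-domain corpus.
#' @param table an [embedding_table()].
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the adapted `deid_tagger`.
#' @export
fine_tune <- function(model, corpus_b, table, tcfg = train_config(),
                      verbose = FALSE) {
  if (tcfg$max_epochs == 0L) return(model)
  train_tagger(corpus_b, table, mcfg = model$config, tcfg = tcfg,
               init_model = model, verbose = verbose)
}

# ---- prediction ------------------------------------------------------------

# Decode BIO tags over tokens into character-offset spans. An ill-formed
# leading I-X (possible because transitions are learned, not constrained) is
# repaired to B-X.
bio_to_spans <- function(tags, tokens) {
  spans <- empty_spans()
  open_type <- NA_character_
  open_start <- NA_integer_
  last_end <- NA_integer_
  close_span <- function() {
    if (!is.na(open_type))
      spans <<- rbind(spans, phi_span(open_start, last_end, open_type))
    open_type <<- NA_character_
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      close_span()
    } else {
      typ <- sub("^[BI]-", "", t)
      if (startsWith(t, "B-") || is.na(open_type) || open_type != typ) {
        close_span()
        open_type <- typ
        open_start <- tokens$start[i]
      }
      last_end <- tokens$end[i]
    }
  }
  close_span()
  spans
}

#' Predict PHI spans in a note
#'
#' Tokenizes the text, computes emission scores (with the model's not-PHI
#' bias applied to the `"O"` column), Viterbi-decodes the CRF, and converts
#' the BIO tag sequence back to character-offset spans. Sequences longer
#' than `max_tokens` are chunked at line breaks before decoding.
#'
#' @param model a trained `deid_tagger`.
#' @param note_text the note text (a single string).
#' @param table an [embedding_table()].
#' @param not_phi_bias decode-time recall/precision knob; defaults to the
#'   model's stored bias.
#' @param max_tokens chunking bound on the sequence length.
#' @return data.frame of predicted spans (`start`, `end`, `type`, `text`).
#' @export
predict_phi <- function(model, note_text, table,
                        not_phi_bias = model$not_phi_bias,
                        max_tokens = 1000L) {
  tokens <- tokenize(note_text)
  if (nrow(tokens) == 0L) return(empty_spans())
  tags <- predict_tags(model, tokens, table, not_phi_bias, max_tokens)
  spans <- bio_to_spans(tags, tokens)
  if (nrow(spans) > 0)
    spans$text <- substring(note_text, spans$start + 1L, spans$end)
  spans
}

# BIO tags for a token_seq (chunked decode); internal workhorse shared by
# predict_phi and the evaluation sweep.
predict_tags <- function(model, tokens, table, not_phi_bias = 0,
                         max_tokens = 1000L) {
  labels <- model$config$labels
  unlist(lapply(chunk_token_seq(tokens, max_tokens), function(idx) {
    emis <- encode_sequence(tokens[idx, , drop = FALSE], table, model,
                            not_phi_bias = not_phi_bias)
    labels[crf_viterbi(emis, model$params$trans)$path]
  }))
}

# ---- checkpointing ---------------------------------------------------------

#' Save a tagger checkpoint
#'
#' Single-file archive holding the schema version, configuration, character
#' vocabulary and all parameter tensors.
#'
#' @param model a `deid_tagger`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_tagger <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a tagger checkpoint
#'
#' @param path file written by [save_tagger()].
#' @return a `deid_tagger`.
#' @export
load_tagger <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported checkpoint schema")
  structure(obj, class = "deid_tagger")
}
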
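#' Tokenize clinical text
#'
#' Splits text into maximal runs of letters, maximal runs of digits, and
#' single non-space symbols, so alphanumeric boundaries split ("50mg" becomes
#' `50`, `mg`) and multi-part PHI such as phone numbers stays decomposable.
#' Whitespace is never emitted as a token; instead each token records how many
#' spaces and line breaks precede it. Character classes follow Unicode
#' categories (letters `L*`, decimal digits `Nd`); anything else is a symbol.
#'
#' @param text a single character string (may be empty).
#' @param note_id optional note identifier attached to the result.
#' @return a `token_seq`: a data.frame with one row per token and columns
#'   `text`, `norm` (see [normalize_token()]), `start`/`end` (0-based,
#'   half-open character offsets), `casing` (one of `UPPER`, `LOWER`, `MIXED`,
#'   `NONE-ALPHA`) and `n_spaces_before`/`n_newlines_before`.
#' @export
#' @examples
#' tokenize("Patient prescribed 50mg")$text
tokenize <- function(text, note_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    seq <- data.frame(text = character(), norm = character(),
                      start = integer(), end = integer(),
                      casing = character(),
                      n_spaces_before = integer(),
                      n_newlines_before = integer(),
                      stringsAsFactors = FALSE)
    return(structure(seq, note_id = note_id, class = c("token_seq", "data.frame")))
  }
  m <- gregexpr("\\p{L}+|\\p{Nd}+|[^\\p{L}\\p{Nd}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tokenize("", note_id))
  }
  starts1 <- as.integer(m)                       # 1-based
  lens <- attr(m, "match.length")
  surf <- substring(text, starts1, starts1 + lens - 1L)
  start0 <- starts1 - 1L
  end0 <- start0 + lens

  # whitespace between previous token end and this token start
  gap_from <- c(0L, end0[-length(end0)])
  gaps <- substring(text, gap_from + 1L, start0)
  n_nl <- vapply(gaps, function(g) sum(strsplit(g, "")[[1]] == "\n"),
                 integer(1), USE.NAMES = FALSE)
  n_sp <- nchar(gaps) - n_nl  # every non-newline whitespace char counts as a space

  seq <- data.frame(text = surf,
                    norm = normalize_token(surf),
                    start = start0, end = end0,
                    casing = casing_of(surf),
                    n_spaces_before = as.integer(n_sp),
                    n_newlines_before = as.integer(n_nl),
                    stringsAsFactors = FALSE)
  structure(seq, note_id = note_id, class = c("token_seq", "data.frame"))
}

#' Normalize a token
#'
#' Lowercases every letter and maps every decimal digit to `"0"`; all other
#' characters (and the string length) are unchanged. Embedding lookups key on
#' this normalized form. The map is idempotent.
#'
#' @param x character vector of token surfaces.
#' @return character vector of normalized forms.
#' @export
#' @examples
#' normalize_token(c("50", "A1c"))  # "00", "a0c"
normalize_token <- function(x) {
  gsub("\\p{Nd}", "0", tolower(x), perl = TRUE)
}

casing_of <- function(x) {
  has_alpha <- grepl("\\p{L}", x, perl = TRUE)
  all_upper <- x == toupper(x)
  all_lower <- x == tolower(x)
  out <- rep("MIXED", length(x))
  out[!has_alpha] <- "NONE-ALPHA"
  out[has_alpha & all_upper] <- "UPPER"
  out[has_alpha & all_lower & !all_upper] <- "LOWER"
  out
}

#' Casing and spacing feature matrix
#'
#' One row per token: a one-hot casing category (`UPPER`, `LOWER`, `MIXED`,
#' `NONE-ALPHA`) followed by the space and line-break counts before the token,
#' clipped at `cap` and scaled to `[0, 1]`. The cap (default 4) is the
#' smallest value that still distinguishes same-line, new-line and
#' blank-line-separated tokens; unbounded counts destabilize training.
#'
#' @param seq a `token_seq` from [tokenize()].
#' @param cap clip for the whitespace counts before scaling.
#' @return numeric matrix with `nrow(seq)` rows and 6 columns.
#' @export
casing_spacing_features <- function(seq, cap = 4) {
  cats <- c("UPPER", "LOWER", "MIXED", "NONE-ALPHA")
  onehot <- matrix(0, nrow(seq), 4L, dimnames = list(NULL, cats))
  if (nrow(seq) > 0) onehot[cbind(seq_len(nrow(seq)), match(seq$casing, cats))] <- 1
  sp <- pmin(seq$n_spaces_before, cap) / cap
  nl <- pmin(seq$n_newlines_before, cap) / cap
  cbind(onehot, spaces = sp, newlines = nl)
}

# Split an over-long token sequence into chunks of at most max_tokens,
# preferring to break where a line break precedes the token. Returns a list
# of row-index vectors covering 1..nrow(seq) in order.
chunk_token_seq <- function(seq, max_tokens = 1000L) {
  n <- nrow(seq)
  if (n <= max_tokens) return(list(seq_len(n)))
  chunks <- list()
  lo <- 1L
  while (lo <= n) {
    hi <- min(lo + max_tokens - 1L, n)
    if (hi < n) {
      nl <- which(seq$n_newlines_before[(lo + 1L):hi] > 0L)
      if (length(nl) > 0) hi <- lo + nl[length(nl)] - 1L
    }
    chunks[[length(chunks) + 1L]] <- lo:hi
    lo <- hi + 1L
  }
  chunks
}
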
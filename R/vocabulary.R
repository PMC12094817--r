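#' Token vocabulary for one modality
#'
#' A vocabulary is an ordered set of token symbols for a single modality
#' (sequence or structure), with one distinguished absorbing mask symbol from
#' which generation starts. Token ids are 1-based positions into `symbols`.
#'
#' @param symbols Character vector of unique token labels, including the mask.
#' @param mask_symbol The label of the mask token; must occur in `symbols`.
#' @return An object of class `mf_vocab` with fields `symbols`, `mask_index`
#'   and `size` (count including the mask).
#' @examples
#' v <- vocabulary(c("A", "C", "D", "-"), mask_symbol = "-")
#' v$mask_index
#' @export
vocabulary <- function(symbols, mask_symbol = "-") {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("vocabulary symbols must be unique")
  if (length(symbols) < 2L) stop("a vocabulary needs at least one real token plus the mask")
  mask_index <- match(mask_symbol, symbols)
  if (is.na(mask_index)) stop("mask_symbol '", mask_symbol, "' not among symbols")
  structure(
    list(symbols = symbols, mask_index = mask_index, size = length(symbols)),
    class = "mf_vocab"
  )
}

#' @export
print.mf_vocab <- function(x, ...) {
  cat("<mf_vocab> size", x$size, "mask", shQuote(x$symbols[x$mask_index]),
      ":", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

# first n amino-acid letters in alphabetical one-letter order
.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default sequence and structure vocabularies
#'
#' The sequence vocabulary uses the first `n_tokens` amino-acid one-letter
#' codes (A, C, D, E, F, G, ...); the structure vocabulary uses geometry codes
#' g1, g2, ... . Both append the mask symbol `"-"` as the last id.
#'
#' @param n_tokens Number of real (non-mask) tokens.
#' @return An `mf_vocab`.
#' @export
seq_vocabulary <- function(n_tokens = 6L) {
  if (n_tokens > length(.aa_letters)) stop("at most ", length(.aa_letters), " sequence tokens")
  vocabulary(c(.aa_letters[seq_len(n_tokens)], "-"))
}

#' @rdname seq_vocabulary
#' @export
struct_vocabulary <- function(n_tokens = 8L) {
  vocabulary(c(paste0("g", seq_len(n_tokens)), "-"))
}

#' Number of real (non-mask) tokens in a vocabulary
#' @param vocab An `mf_vocab`.
#' @export
n_real_tokens <- function(vocab) vocab$size - 1L

#' Ids of the real (non-mask) tokens
#' @param vocab An `mf_vocab`.
#' @export
real_token_ids <- function(vocab) setdiff(seq_len(vocab$size), vocab$mask_index)

#' A single token track
#'
#' One modality's tokens for a length-N protein, as integer ids into a
#' vocabulary.
#'
#' @param tokens Integer vector of token ids (1-based into `vocab$symbols`).
#' @param vocab The track's `mf_vocab`.
#' @param modality `"sequence"` or `"structure"`.
#' @return An object of class `mf_track`.
#' @export
token_track <- function(tokens, vocab, modality = c("sequence", "structure")) {
  modality <- match.arg(modality)
  stopifnot(inherits(vocab, "mf_vocab"))
  tokens <- as.integer(tokens)
  if (length(tokens) < 1L) stop("a track needs at least one position")
  if (anyNA(tokens) || any(tokens < 1L) || any(tokens > vocab$size))
    stop("token ids must lie in [1, ", vocab$size, "]")
  structure(list(tokens = tokens, vocab = vocab, modality = modality),
            class = "mf_track")
}

#' @export
print.mf_track <- function(x, ...) {
  cat("<mf_track>", x$modality, "N =", length(x$tokens), ":",
      paste(x$vocab$symbols[x$tokens], collapse = ""), "\n")
  invisible(x)
}

#' @export
length.mf_track <- function(x) length(x$tokens)

#' Does a track contain any mask tokens?
#' @param track An `mf_track`.
#' @export
has_mask <- function(track) any(track$tokens == track$vocab$mask_index)

#' A fully masked track
#' @param n Track length.
#' @param vocab The track's vocabulary.
#' @param modality `"sequence"` or `"structure"`.
#' @export
masked_track <- function(n, vocab, modality = "sequence") {
  token_track(rep(vocab$mask_index, n), vocab, modality)
}

#' Paired sequence/structure token tracks
#'
#' The package's protein representation x = (s, r): two equal-length token
#' tracks, one per modality.
#'
#' @param seq An `mf_track` with modality `"sequence"`.
#' @param struct An `mf_track` with modality `"structure"`.
#' @return An object of class `mf_protein`.
#' @export
protein_tokens <- function(seq, struct) {
  stopifnot(inherits(seq, "mf_track"), inherits(struct, "mf_track"))
  if (seq$modality != "sequence" || struct$modality != "structure")
    stop("tracks must be (sequence, structure) in that order")
  if (length(seq$tokens) != length(struct$tokens))
    stop("sequence and structure tracks must have identical length")
  structure(list(seq = seq, struct = struct), class = "mf_protein")
}

#' @export
print.mf_protein <- function(x, ...) {
  cat("<mf_protein> N =", length(x$seq$tokens), "\n")
  cat("  seq   :", paste(x$seq$vocab$symbols[x$seq$tokens], collapse = ""), "\n")
  cat("  struct:", paste(x$struct$vocab$symbols[x$struct$tokens], collapse = " "), "\n")
  invisible(x)
}

#' @export
length.mf_protein <- function(x) length(x$seq$tokens)

#' Per-position categorical distributions over one vocabulary
#'
#' An N x K row-stochastic matrix: one probability vector per position. Houses
#' denoiser outputs, interpolation fields and transition kernels.
#'
#' @param probs Numeric N x K matrix, rows summing to 1.
#' @param vocab The `mf_vocab` the columns index.
#' @param tol Row-sum tolerance.
#' @return An object of class `mf_field`.
#' @export
categorical_field <- function(probs, vocab, tol = 1e-9) {
  stopifnot(inherits(vocab, "mf_vocab"))
  probs <- as.matrix(probs)
  if (ncol(probs) != vocab$size)
    stop("field has ", ncol(probs), " columns but vocabulary size is ", vocab$size)
  if (any(probs < -tol) || any(probs > 1 + tol))
    stop("field entries must lie in [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop("field rows must sum to 1 (max deviation ", format(max(abs(rs - 1))), ")")
  structure(list(probs = probs, vocab = vocab), class = "mf_field")
}

#' @export
print.mf_field <- function(x, ...) {
  cat("<mf_field>", nrow(x$probs), "positions x", ncol(x$probs), "tokens\n")
  invisible(x)
}

#' Total probability the field assigns to the mask token, per position
#' @param field An `mf_field`.
#' @export
mask_mass <- function(field) field$probs[, field$vocab$mask_index]
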
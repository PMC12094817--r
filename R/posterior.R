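# exact posteriors from an enumerated joint: the ideal denoiser f = p(x1 | xt)

# core: conditional per-position marginals of x1 given the observed (non-mask)
# coordinates of xt, by filtering and summing the enumerated joint
.posterior_fields <- function(joint, seq_tokens, struct_tokens) {
  world <- joint$world
  np <- joint$length
  sv <- world$seq_vocab
  rv <- world$struct_vocab
  sel <- rep(TRUE, length(joint$p))
  for (i in seq_len(np)) {
    if (seq_tokens[i] != sv$mask_index)
      sel <- sel & joint$seq_tokens[, i] == seq_tokens[i]
    if (struct_tokens[i] != rv$mask_index)
      sel <- sel & joint$struct_tokens[, i] == struct_tokens[i]
  }
  w <- joint$p * sel
  tot <- sum(w)
  if (tot <= 0) stop("observed tokens have zero probability under the joint")
  w <- w / tot
  marg <- function(tok_mat, k, kfull, mask_index) {
    pr <- matrix(0, np, kfull)
    for (i in seq_len(np)) {
      acc <- rowsum(w, tok_mat[, i])
      pr[i, as.integer(rownames(acc))] <- acc[, 1]
    }
    # real-token columns only; the mask column stays exactly zero
    stopifnot(all(pr[, mask_index] == 0))
    pr
  }
  list(seq = marg(joint$seq_tokens, ncol(world$emit_seq), sv$size, sv$mask_index),
       struct = marg(joint$struct_tokens, ncol(world$emit_struct), rv$size, rv$mask_index))
}

#' Exact-posterior denoiser from an enumerated joint
#'
#' The ideal denoiser: treats the non-mask tokens of the current state as
#' observed coordinates of the data point and returns the exact per-position
#' conditionals of x1 under the enumerated joint, with zero mass on the mask
#' tokens. Used as the oracle that lets the Euler sampler be tested for exact
#' distribution recovery.
#'
#' @param joint An `mf_joint` from [enumerate_joint()].
#' @param xt An `mf_protein` (may contain masks) of the enumerated length.
#' @return List of two `mf_field`s, `seq` and `struct`.
#' @export
exact_posterior_denoiser <- function(joint, xt) {
  stopifnot(inherits(joint, "mf_joint"), inherits(xt, "mf_protein"))
  if (length(xt) != joint$length)
    stop("xt has length ", length(xt), " but the joint enumerates N = ", joint$length)
  f <- .posterior_fields(joint, xt$seq$tokens, xt$struct$tokens)
  list(seq = categorical_field(f$seq, joint$world$seq_vocab),
       struct = categorical_field(f$struct, joint$world$struct_vocab))
}

#' Engine-ready, memoised exact-posterior denoiser
#'
#' Wraps [exact_posterior_denoiser()] for the batched sampler: posteriors are
#' computed once per distinct partial-observation pattern and cached, so
#' sampling tens of thousands of trajectories stays fast.
#'
#' @param joint An `mf_joint`.
#' @return A function of class `mf_batch_denoiser` usable by [euler_sample()],
#'   [euler_sample_batch()] and [euler_sample_set()].
#' @export
make_posterior_denoiser <- function(joint) {
  stopifnot(inherits(joint, "mf_joint"))
  np <- joint$length
  ks <- joint$world$seq_vocab$size
  kr <- joint$world$struct_vocab$size
  pow_s <- ks^(seq_len(np) - 1)
  pow_r <- kr^(seq_len(np) - 1)
  cache <- new.env(parent = emptyenv())
  f <- function(S, R, t) {
    b <- ncol(S)
    code <- colSums((S - 1) * pow_s) + ks^np * colSums((R - 1) * pow_r)
    keys <- as.character(code)
    out_s <- matrix(0, np * b, ks)
    out_r <- matrix(0, np * b, kr)
    for (grp in split(seq_len(b), keys)) {
      key <- keys[grp[1]]
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- .posterior_fields(joint, S[, grp[1]], R[, grp[1]])
        cache[[key]] <- hit
      }
      rows <- as.vector(outer(seq_len(np), (grp - 1L) * np, `+`))
      rep_idx <- rep(seq_len(np), length(grp))
      out_s[rows, ] <- hit$seq[rep_idx, , drop = FALSE]
      out_r[rows, ] <- hit$struct[rep_idx, , drop = FALSE]
    }
    list(seq = out_s, struct = out_r)
  }
  structure(f, class = "mf_batch_denoiser")
}
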
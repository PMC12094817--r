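#' Parameters of the enumerable toy protein world
#'
#' A hidden-state chain (mimicking local secondary-structure state, e.g.
#' helix/sheet/coil) emits one sequence token and one structure token per
#' residue, coupling the two tracks: the world's exact joint distribution over
#' (s, r) is computable by the forward recursion for small N, which is what
#' makes end-to-end distribution-recovery claims testable.
#'
#' Defaults give strong sequence-structure coupling: diagonally dominant
#' transitions (`stay` = 0.8) and peaked emissions (`peak` = 0.7 on a
#' state-preferred token), so recovery metrics have headroom over chance.
#'
#' @param n_hidden Number of hidden states H (default 3).
#' @param n_seq_tokens Real (non-mask) sequence-token count (default 6).
#' @param n_struct_tokens Real (non-mask) structure-token count (default 8).
#' @param stay Hidden-state self-transition probability.
#' @param peak Emission probability of each state's preferred token.
#' @param trans,emit_seq,emit_struct,init Optional explicit row-stochastic
#'   matrices / initial distribution overriding the built defaults.
#' @return An object of class `mf_toy_world`.
#' @export
toy_world_params <- function(n_hidden = 3L, n_seq_tokens = 6L,
                             n_struct_tokens = 8L, stay = 0.8, peak = 0.7,
                             trans = NULL, emit_seq = NULL, emit_struct = NULL,
                             init = NULL) {
  h <- as.integer(n_hidden)
  peaked <- function(k) {
    m <- matrix((1 - peak) / (k - 1), h, k)
    for (i in seq_len(h)) m[i, 1L + (i - 1L) %% k] <- peak
    m
  }
  if (is.null(trans)) {
    trans <- if (h == 1L) matrix(1, 1, 1) else {
      m <- matrix((1 - stay) / (h - 1), h, h)
      diag(m) <- stay
      m
    }
  }
  if (is.null(emit_seq)) emit_seq <- peaked(n_seq_tokens)
  if (is.null(emit_struct)) emit_struct <- peaked(n_struct_tokens)
  if (is.null(init)) init <- rep(1 / h, h)
  check_rows <- function(m, what) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
      stop(what, " rows must be nonnegative and sum to 1")
  }
  check_rows(trans, "trans")
  check_rows(emit_seq, "emit_seq")
  check_rows(emit_struct, "emit_struct")
  check_rows(matrix(init, 1), "init")
  stopifnot(nrow(trans) == h, ncol(trans) == h,
            nrow(emit_seq) == h, nrow(emit_struct) == h, length(init) == h)
  structure(list(
    n_hidden = h, trans = trans, emit_seq = emit_seq, emit_struct = emit_struct,
    init = init,
    seq_vocab = seq_vocabulary(ncol(emit_seq)),
    struct_vocab = struct_vocabulary(ncol(emit_struct))
  ), class = "mf_toy_world")
}

#' @export
print.mf_toy_world <- function(x, ...) {
  cat("<mf_toy_world> H =", x$n_hidden, "| seq tokens", ncol(x$emit_seq),
      "| struct tokens", ncol(x$emit_struct), "\n")
  invisible(x)
}

#' The small enumeration world used for exact distribution-recovery checks
#'
#' Two hidden states, three tokens per track. Emissions and transitions are
#' sharper (0.9) than the default world so that the exact joint distribution
#' is concentrated enough for total-variation comparisons against a few tens
#' of thousands of Monte-Carlo draws to be conclusive: the expected
#' multinomial TV error, computable in closed form from the enumerated joint,
#' sits well below the bounds the tests assert.
#'
#' @export
small_toy_world <- function() {
  toy_world_params(n_hidden = 2L, n_seq_tokens = 3L, n_struct_tokens = 3L,
                   stay = 0.9, peak = 0.9)
}

#' Sample paired-token proteins from the toy world
#'
#' Per item: a hidden chain from `init`/`trans`, then one sequence and one
#' structure token per residue from the state's emission rows.
#'
#' @param world An `mf_toy_world`.
#' @param n Number of proteins.
#' @param length Residue count N.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG state.
#' @return A list of `n` fully observed `mf_protein` objects.
#' @export
sample_toy_proteins <- function(world, n, length, seed = NULL) {
  stopifnot(inherits(world, "mf_toy_world"), n >= 1, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  np <- as.integer(length)
  h <- world$n_hidden
  z <- matrix(0L, n, np)
  z[, 1] <- .sample_rows(matrix(world$init, n, h, byrow = TRUE))
  if (np > 1) for (i in 2:np)
    z[, i] <- .sample_rows(world$trans[z[, i - 1], , drop = FALSE])
  s <- matrix(.sample_rows(world$emit_seq[as.vector(z), , drop = FALSE]), n, np)
  r <- matrix(.sample_rows(world$emit_struct[as.vector(z), , drop = FALSE]), n, np)
  lapply(seq_len(n), function(i) {
    protein_tokens(token_track(s[i, ], world$seq_vocab, "sequence"),
                   token_track(r[i, ], world$struct_vocab, "structure"))
  })
}

# emission over per-residue (s, r) pairs: H x (Ks-1)(Kr-1), pair code
# c = (s - 1) * Krm1 + r, structure token fastest
.pair_emission <- function(world) {
  krm1 <- ncol(world$emit_struct)
  ksm1 <- ncol(world$emit_seq)
  e <- matrix(0, world$n_hidden, ksm1 * krm1)
  for (s in seq_len(ksm1)) for (r in seq_len(krm1))
    e[, (s - 1L) * krm1 + r] <- world$emit_seq[, s] * world$emit_struct[, r]
  e
}

#' Enumerate the exact joint distribution of the toy world
#'
#' Computes P(s, r) for every outcome of an N-residue protein by the forward
#' recursion over hidden chains. Guarded to at most one million outcomes.
#'
#' @param world An `mf_toy_world`.
#' @param length Residue count N.
#' @return An object of class `mf_joint`: outcome token matrices `seq_tokens`,
#'   `struct_tokens` (one row per outcome) and the probability vector `p`.
#' @export
enumerate_joint <- function(world, length) {
  stopifnot(inherits(world, "mf_toy_world"))
  np <- as.integer(length)
  ksm1 <- ncol(world$emit_seq)
  krm1 <- ncol(world$emit_struct)
  kp <- ksm1 * krm1
  n_out <- kp^np
  if (n_out > 1e6) stop("enumeration guard: ", n_out, " outcomes exceed 1e6")
  e <- .pair_emission(world)
  # alpha[o, h]: probability of pair-outcome prefix o ending in hidden state h
  alpha <- t(e * world$init)
  if (np > 1) for (i in 2:np) {
    a <- alpha %*% world$trans              # M x H
    m <- nrow(a)
    # new outcome index (o, c) -> (o - 1) * kp + c: prefix-major, pair fastest
    alpha <- a[rep(seq_len(m), each = kp), , drop = FALSE] *
      t(e)[rep(seq_len(kp), m), , drop = FALSE]
  }
  p <- rowSums(alpha)
  # decode outcome index into per-position pair codes (position 1 most
  # significant), then into (s, r)
  idx0 <- seq_len(n_out) - 1L
  seq_tokens <- matrix(0L, n_out, np)
  struct_tokens <- matrix(0L, n_out, np)
  for (i in np:1) {
    c0 <- idx0 %% kp
    idx0 <- idx0 %/% kp
    seq_tokens[, i] <- as.integer(c0 %/% krm1) + 1L
    struct_tokens[, i] <- as.integer(c0 %% krm1) + 1L
  }
  structure(list(world = world, length = np, p = p,
                 seq_tokens = seq_tokens, struct_tokens = struct_tokens),
            class = "mf_joint")
}

#' @export
print.mf_joint <- function(x, ...) {
  cat("<mf_joint> N =", x$length, "|", length(x$p), "outcomes | total mass",
      format(sum(x$p)), "\n")
  invisible(x)
}

#' Exact per-position marginals of the toy world
#'
#' Forward-computed hidden-state marginals at each position, pushed through
#' the emission rows. Exact at any N (no enumeration needed).
#'
#' @param world An `mf_toy_world`.
#' @param length Residue count N.
#' @return List of N x (K-1) matrices `seq` and `struct` over real tokens.
#' @export
position_marginals <- function(world, length) {
  np <- as.integer(length)
  pz <- matrix(0, np, world$n_hidden)
  pz[1, ] <- world$init
  if (np > 1) for (i in 2:np) pz[i, ] <- pz[i - 1, ] %*% world$trans
  list(seq = pz %*% world$emit_seq, struct = pz %*% world$emit_struct)
}

# hidden-state posteriors given one fully observed track (forward-backward)
.fb_posterior <- function(world, obs, emit) {
  np <- length(obs)
  h <- world$n_hidden
  alpha <- matrix(0, np, h)
  alpha[1, ] <- world$init * emit[, obs[1]]
  if (np > 1) for (i in 2:np)
    alpha[i, ] <- (alpha[i - 1, ] %*% world$trans) * emit[, obs[i]]
  if (sum(alpha[np, ]) <= 0) stop("observed track has zero likelihood")
  beta <- matrix(1, np, h)
  if (np > 1) for (i in (np - 1):1)
    beta[i, ] <- world$trans %*% (emit[, obs[i + 1]] * beta[i + 1, ])
  g <- alpha * beta
  g / rowSums(g)
}

#' Exact conditional sequence distribution given a structure track
#'
#' P(s_i | r) for every position, via forward-backward over the hidden chain.
#'
#' @param world An `mf_toy_world`.
#' @param struct_track An `mf_track` (structure modality, no masks).
#' @return N x (Ks-1) matrix of conditionals over real sequence tokens.
#' @export
seq_posterior_given_struct <- function(world, struct_track) {
  if (has_mask(struct_track)) stop("structure track must be fully observed")
  g <- .fb_posterior(world, struct_track$tokens, world$emit_struct)
  g %*% world$emit_seq
}

#' Co-fold oracle: maximum-a-posteriori structure for a sequence
#'
#' The max-product (joint Viterbi) decode over hidden states and structure
#' tokens: maximises P(z, r | s) and reads off each state's best structure
#' token. Ties break deterministically to the lowest index within each decode
#' step (among exactly tied maximisers the returned track is one attaining
#' the maximal joint probability). Stands in for a folding model when scoring
#' sequence-structure self-consistency in token space.
#'
#' @param s An `mf_track` (sequence modality, no masks).
#' @param world An `mf_toy_world`.
#' @return An `mf_track` (structure modality).
#' @export
cofold_oracle <- function(s, world) {
  stopifnot(inherits(s, "mf_track"), inherits(world, "mf_toy_world"))
  if (has_mask(s)) stop("sequence must be fully observed")
  obs <- s$tokens
  np <- length(obs)
  h <- world$n_hidden
  best_p <- apply(world$emit_struct, 1, max)
  best_tok <- max.col(world$emit_struct, ties.method = "first")
  # log-space Viterbi over hidden states with per-state weight
  # emit_seq[h, s_i] * max_r emit_struct[h, r]
  w <- log(world$emit_seq[, obs, drop = FALSE] * best_p)  # H x N
  delta <- log(world$init) + w[, 1]
  back <- matrix(0L, h, np)
  if (np > 1) for (i in 2:np) {
    cand <- delta + log(world$trans)  # H x H: from-state rows
    back[, i] <- apply(cand, 2, which.max)
    delta <- cand[cbind(back[, i], seq_len(h))] + w[, i]
  }
  if (max(delta) == -Inf) stop("sequence has zero likelihood under the world")
  z <- integer(np)
  z[np] <- which.max(delta)
  if (np > 1) for (i in np:2) z[i - 1] <- back[z[i], i]
  token_track(best_tok[z], world$struct_vocab, "structure")
}

#' Mutual information between the two tracks of an enumerated world
#'
#' I(s; r) in nats between the whole sequence outcome and the whole structure
#' outcome, from the enumerated joint. Positive mutual information is what
#' makes co-design a meaningful task in the toy world.
#'
#' @param joint An `mf_joint`.
#' @export
joint_mutual_information <- function(joint) {
  ks <- max(joint$seq_tokens)
  s_id <- as.vector((joint$seq_tokens - 1L) %*% ks^(seq_len(joint$length) - 1L))
  kr <- max(joint$struct_tokens)
  r_id <- as.vector((joint$struct_tokens - 1L) %*% kr^(seq_len(joint$length) - 1L))
  ps <- rowsum(joint$p, s_id)[as.character(s_id), 1]
  names(ps) <- NULL
  pr <- rowsum(joint$p, r_id)[as.character(r_id), 1]
  names(pr) <- NULL
  ok <- joint$p > 0
  sum(joint$p[ok] * log(joint$p[ok] / (ps[ok] * pr[ok])))
}

#' Inverse-folding Bayes ceiling and majority baseline
#'
#' The best achievable native-sequence-recovery rate given the structure
#' track: the expectation over structures of the mean per-position maximum of
#' the exact conditional P(s_i | r). Estimated over a supplied set of
#' structure tracks (the conditional itself is exact). The majority baseline
#' is the best structure-blind constant predictor: the mean over positions of
#' the maximum marginal sequence-token probability.
#'
#' @param world An `mf_toy_world`.
#' @param struct_tracks List of `mf_track` structures to average over.
#' @return List with `ceiling`, `majority` and `n`.
#' @export
recovery_bounds <- function(world, struct_tracks) {
  stopifnot(length(struct_tracks) >= 1)
  ceil_i <- vapply(struct_tracks, function(r) {
    mean(apply(seq_posterior_given_struct(world, r), 1, max))
  }, numeric(1))
  np <- length(struct_tracks[[1]]$tokens)
  marg <- position_marginals(world, np)$seq
  list(ceiling = mean(ceil_i), majority = mean(apply(marg, 1, max)),
       n = length(struct_tracks))
}
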
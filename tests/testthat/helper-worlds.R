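# shared fixtures and independent brute-force oracles

# brute-force joint enumeration by direct looping over all outcomes and all
# hidden chains; deliberately naive and independent of enumerate_joint()
brute_force_joint <- function(world, np) {
  ks <- ncol(world$emit_seq)
  kr <- ncol(world$emit_struct)
  h <- world$n_hidden
  outs <- expand.grid(rep(list(seq_len(ks)), np))
  outr <- expand.grid(rep(list(seq_len(kr)), np))
  zs <- as.matrix(expand.grid(rep(list(seq_len(h)), np)))
  res <- list()
  for (i in seq_len(nrow(outs))) for (j in seq_len(nrow(outr))) {
    s <- as.integer(outs[i, ])
    r <- as.integer(outr[j, ])
    tot <- 0
    for (zi in seq_len(nrow(zs))) {
      z <- zs[zi, ]
      pz <- world$init[z[1]]
      if (np > 1) for (q in 2:np) pz <- pz * world$trans[z[q - 1], z[q]]
      pe <- 1
      for (q in seq_len(np))
        pe <- pe * world$emit_seq[z[q], s[q]] * world$emit_struct[z[q], r[q]]
      tot <- tot + pz * pe
    }
    res[[length(res) + 1]] <- list(s = s, r = r, p = tot)
  }
  res
}

# look up an outcome's probability in an mf_joint by token matching
joint_prob_of <- function(joint, s, r) {
  hit <- apply(joint$seq_tokens, 1, function(x) all(x == s)) &
    apply(joint$struct_tokens, 1, function(x) all(x == r))
  sum(joint$p[hit])
}

fully_masked_x0 <- function(world, np) {
  protein_tokens(masked_track(np, world$seq_vocab, "sequence"),
                 masked_track(np, world$struct_vocab, "structure"))
}

# closed-form expected total-variation distance of an n-draw multinomial
# estimate of p (normal approximation, E|phat_i - p_i| per cell)
expected_multinomial_tv <- function(p, n) {
  0.5 * sum(sqrt(2 * p * (1 - p) / (pi * n)))
}

# a deterministic one-state world: single possible protein
degenerate_world <- function() {
  toy_world_params(n_hidden = 1L, n_seq_tokens = 3L, n_struct_tokens = 3L,
                   trans = matrix(1, 1, 1),
                   emit_seq = matrix(c(1, 0, 0), 1),
                   emit_struct = matrix(c(0, 1, 0), 1),
                   init = 1)
}
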
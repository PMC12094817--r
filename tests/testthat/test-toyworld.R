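test_that("single-state worlds emit i.i.d. tokens at the emission frequencies", {
  w <- toy_world_params(n_hidden = 1L, n_seq_tokens = 4L, n_struct_tokens = 4L,
                        emit_seq = matrix(c(0.4, 0.3, 0.2, 0.1), 1),
                        emit_struct = matrix(0.25, 1, 4),
                        trans = matrix(1, 1, 1), init = 1)
  ps <- sample_toy_proteins(w, 200, 20, seed = 5)
  toks <- unlist(lapply(ps, function(x) x$seq$tokens))
  emp <- tabulate(toks, 4) / length(toks)
  expect_true(all(abs(emp - c(0.4, 0.3, 0.2, 0.1)) <
                    3 * sqrt(0.4 * 0.6 / length(toks)) + 1e-9))
})

test_that("a deterministic world collapses to a single protein", {
  w <- degenerate_world()
  ps <- sample_toy_proteins(w, 10, 6, seed = 1)
  for (x in ps) {
    expect_identical(x$seq$tokens, rep(1L, 6))
    expect_identical(x$struct$tokens, rep(2L, 6))
  }
  expect_identical(cofold_oracle(ps[[1]]$seq, w)$tokens, rep(2L, 6))
})

test_that("enumerated joints match closed forms and brute-force summation", {
  w <- toy_world_params(n_hidden = 2L, n_seq_tokens = 2L, n_struct_tokens = 2L,
                        stay = 0.7, peak = 0.8)
  j1 <- enumerate_joint(w, 1)
  expect_equal(sum(j1$p), 1, tolerance = 1e-12)
  for (i in seq_along(j1$p)) {
    s <- j1$seq_tokens[i, 1]
    r <- j1$struct_tokens[i, 1]
    expect_equal(j1$p[i], sum(w$init * w$emit_seq[, s] * w$emit_struct[, r]))
  }
  j2 <- enumerate_joint(w, 2)
  expect_equal(sum(j2$p), 1, tolerance = 1e-9)
  bf <- brute_force_joint(w, 2)
  for (o in bf)
    expect_equal(joint_prob_of(j2, o$s, o$r), o$p, tolerance = 1e-12)
})

test_that("sampled marginals agree with forward-computed marginals", {
  w <- toy_world_params()
  ps <- sample_toy_proteins(w, 5000, 16, seed = 21)
  S <- t(vapply(ps, function(x) x$seq$tokens, integer(16)))
  R <- t(vapply(ps, function(x) x$struct$tokens, integer(16)))
  expect_lt(marginal_tv(S, R, position_marginals(w, 16)), 0.05)
})

test_that("the co-fold oracle equals brute-force argmax over structures", {
  w <- toy_world_params(n_hidden = 2L, n_seq_tokens = 3L, n_struct_tokens = 3L,
                        stay = 0.85, peak = 0.8)
  j <- enumerate_joint(w, 3)
  # independent brute force of the same max-product objective: enumerate all
  # structure outcomes and all hidden chains, maximise P(z, s, r)
  zs <- as.matrix(expand.grid(rep(list(1:2), 3)))
  rs <- as.matrix(expand.grid(rep(list(1:3), 3)))
  set.seed(3)
  for (rep in 1:20) {
    s <- sample(1:3, 3, TRUE)
    score <- apply(rs, 1, function(r) {
      max(apply(zs, 1, function(z) {
        w$init[z[1]] * w$trans[z[1], z[2]] * w$trans[z[2], z[3]] *
          prod(w$emit_seq[cbind(z, s)]) * prod(w$emit_struct[cbind(z, r)])
      }))
    })
    got <- cofold_oracle(token_track(s, w$seq_vocab), w)
    got_score <- score[which(apply(rs, 1, function(r) all(r == got$tokens)))]
    # the decode must attain the global max-product score (outcome identity is
    # ill-posed when distinct hidden chains tie exactly)
    expect_equal(got_score, max(score), tolerance = 1e-12)
    expect_identical(got$tokens, cofold_oracle(token_track(s, w$seq_vocab), w)$tokens)
  }
})

test_that("co-fold with one hidden state repeats the modal structure token", {
  w <- toy_world_params(n_hidden = 1L, n_seq_tokens = 3L, n_struct_tokens = 4L,
                        trans = matrix(1, 1, 1),
                        emit_seq = matrix(1 / 3, 1, 3),
                        emit_struct = matrix(c(0.1, 0.2, 0.6, 0.1), 1), init = 1)
  got <- cofold_oracle(token_track(c(1L, 2L, 3L), w$seq_vocab), w)
  expect_identical(got$tokens, rep(3L, 3))
})

test_that("the toy world couples tracks and leaves recovery headroom", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 3)
  expect_gt(joint_mutual_information(j), 0)
  structs <- lapply(sample_toy_proteins(w, 200, 8, seed = 9),
                    function(x) x$struct)
  b <- recovery_bounds(w, structs)
  expect_gt(b$ceiling, b$majority)
})

test_that("invalid parameters and oversized enumerations are rejected", {
  expect_error(toy_world_params(trans = matrix(c(0.5, 0.2, 0.3, 0.9), 2)),
               "sum to 1")
  w <- toy_world_params()
  expect_error(enumerate_joint(w, 16), "guard")
  expect_error(sample_toy_proteins(w, 0, 4))
})
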
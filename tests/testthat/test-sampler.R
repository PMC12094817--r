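test_that("a point-mass denoiser makes the sampler deterministic", {
  w <- toy_world_params()
  x1 <- sample_toy_proteins(w, 1, 12, seed = 31)[[1]]
  den <- delta_denoiser(x1)
  x0 <- fully_masked_x0(w, 12)
  for (strategy in c("synchronous", "asynchronous", "sequence_first",
                     "structure_first")) {
    out <- euler_sample(den, x0, config = sampler_config(
      steps = 24, strategy = strategy, seed = 5))
    expect_identical(out$x1$seq$tokens, x1$seq$tokens)
    expect_identical(out$x1$struct$tokens, x1$struct$tokens)
    expect_false(has_mask(out$x1$seq) || has_mask(out$x1$struct))
    expect_equal(generation_entropy(out$trajectory), 0)
  }
})

test_that("sampling is seed-reproducible and seed-sensitive", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 3)
  den <- make_posterior_denoiser(j)
  x0 <- fully_masked_x0(w, 3)
  a <- euler_sample_batch(den, 50, x0, config = sampler_config(steps = 40, seed = 1))
  b <- euler_sample_batch(den, 50, x0, config = sampler_config(steps = 40, seed = 1))
  c <- euler_sample_batch(den, 50, x0, config = sampler_config(steps = 40, seed = 2))
  expect_identical(a$seq, b$seq)
  expect_identical(a$struct, b$struct)
  expect_false(identical(a$seq, c$seq) && identical(a$struct, c$struct))
  # single-trajectory sampler consumes the identical stream as a batch of one
  s1 <- euler_sample(den, x0, config = sampler_config(steps = 40, seed = 3))
  b1 <- euler_sample_batch(den, 1, x0, config = sampler_config(steps = 40, seed = 3))
  expect_identical(s1$x1$seq$tokens, as.integer(b1$seq[1, ]))
})

test_that("with eta = 0 unmasked tokens are absorbed for good", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 3)
  den <- make_posterior_denoiser(j)
  out <- euler_sample(den, fully_masked_x0(w, 3),
                      config = sampler_config(steps = 60, eta = 0, seed = 11))
  prev_s <- rep(w$seq_vocab$mask_index, 3)
  prev_r <- rep(w$struct_vocab$mask_index, 3)
  for (st in out$trajectory$steps) {
    chs <- prev_s != w$seq_vocab$mask_index & st$seq_tokens != prev_s
    chr <- prev_r != w$struct_vocab$mask_index & st$struct_tokens != prev_r
    expect_false(any(chs) || any(chr))
    prev_s <- st$seq_tokens
    prev_r <- st$struct_tokens
  }
  expect_identical(out$remask_events, 0L)
})

test_that("eta > 0 produces transient re-masking but a mask-free result", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 2)
  den <- make_posterior_denoiser(j)
  out <- euler_sample_batch(den, 100, fully_masked_x0(w, 2),
                            config = sampler_config(steps = 40, eta = 1, seed = 6))
  expect_gt(out$remask_events, 0)
  expect_false(any(out$seq == w$seq_vocab$mask_index))
  expect_false(any(out$struct == w$struct_vocab$mask_index))
})

test_that("conditioning tokens pass through every task mode untouched", {
  w <- toy_world_params()
  x1 <- sample_toy_proteins(w, 1, 10, seed = 17)[[1]]
  den <- delta_denoiser(sample_toy_proteins(w, 1, 10, seed = 18)[[1]])
  tasks <- list(
    task_spec("folding", given_seq = x1$seq),
    task_spec("inverse_folding", given_struct = x1$struct),
    task_spec("motif_scaffolding", given_seq = x1$seq,
              given_struct = x1$struct, motif_positions = c(2L, 3L, 7L)))
  for (task in tasks) {
    cm <- make_condition_mask(task, 10, w$seq_vocab, w$struct_vocab)
    out <- euler_sample(den, cm$x0, cm$cond,
                        config = sampler_config(steps = 20, eta = 1, seed = 8))
    expect_identical(out$x1$seq$tokens[cm$cond[, "seq"]],
                     x1$seq$tokens[cm$cond[, "seq"]])
    expect_identical(out$x1$struct$tokens[cm$cond[, "struct"]],
                     x1$struct$tokens[cm$cond[, "struct"]])
    expect_false(has_mask(out$x1$seq) || has_mask(out$x1$struct))
  }
})

test_that("the sampler recovers an enumerable joint distribution", {
  w <- toy_world_params(n_hidden = 2L, n_seq_tokens = 3L, n_struct_tokens = 3L,
                        stay = 0.9, peak = 0.9)
  j <- enumerate_joint(w, 2)
  den <- make_posterior_denoiser(j)
  n <- 5000
  out <- euler_sample_batch(den, n, fully_masked_x0(w, 2),
                            config = sampler_config(steps = 100, seed = 13))
  tv <- tv_distance(tabulate(outcome_index(j, out$seq, out$struct),
                             nbins = length(j$p)), j)
  # the sampling-error floor is known in closed form from the enumerated
  # joint; a correct sampler cannot sit far above it
  expect_lt(tv, 1.5 * expected_multinomial_tv(j$p, n))
})

test_that("trajectory-recomputed entropy matches the online bookkeeping", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 3)
  den <- make_posterior_denoiser(j)
  for (eta in c(0, 1)) {
    out <- euler_sample(den, fully_masked_x0(w, 3),
                        config = sampler_config(steps = 30, eta = eta, seed = 19))
    expect_equal(generation_entropy(out$trajectory), out$gen_entropy,
                 tolerance = 1e-12)
  }
})

test_that("sampler preconditions are enforced", {
  w <- small_toy_world()
  x1 <- sample_toy_proteins(w, 1, 3, seed = 23)[[1]]
  x0 <- fully_masked_x0(w, 3)
  # a denoiser leaking probability onto the mask must be rejected
  leaky <- function(x, t) {
    k <- w$seq_vocab$size
    list(seq = categorical_field(matrix(1 / k, 3, k), w$seq_vocab),
         struct = categorical_field(matrix(1 / k, 3, k), w$struct_vocab))
  }
  expect_error(euler_sample(leaky, x0, config = sampler_config(steps = 4)),
               "mask token")
  cond <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 3, 2,
                 dimnames = list(NULL, c("seq", "struct")))
  expect_error(euler_sample(delta_denoiser(x1), x0, cond), "mask tokens")
  expect_error(euler_sample(delta_denoiser(x1), x1, NULL), "start masked")
})
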
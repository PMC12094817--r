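test_that("generation entropy has its closed forms at the extremes", {
  w <- toy_world_params(n_hidden = 1L, n_seq_tokens = 4L, n_struct_tokens = 4L,
                        trans = matrix(1, 1, 1),
                        emit_seq = matrix(0.25, 1, 4),
                        emit_struct = matrix(0.25, 1, 4), init = 1)
  # uniform denoiser over 4 real tokens on each track: every unmasking event
  # draws from a uniform row, so per-residue entropy is exactly 2 ln 4
  uniform_den <- function(x, t) {
    k <- w$seq_vocab$size
    p <- matrix(c(rep(0.25, 4), 0), length(x), k, byrow = TRUE)
    list(seq = categorical_field(p, w$seq_vocab),
         struct = categorical_field(p, w$struct_vocab))
  }
  out <- euler_sample(uniform_den, fully_masked_x0(w, 5),
                      config = sampler_config(steps = 25, seed = 3))
  expect_equal(generation_entropy(out$trajectory), 2 * log(4), tolerance = 1e-12)
})

test_that("recovery rate counts matching positions", {
  v <- seq_vocabulary(4)
  a <- token_track(c(1L, 2L, 3L, 4L), v)
  b <- token_track(c(1L, 2L, 4L, 3L), v)
  expect_equal(recovery_rate(a, a), 1)
  expect_equal(recovery_rate(a, token_track(c(2L, 3L, 4L, 1L), v)), 0)
  expect_equal(recovery_rate(a, b), 0.5)
  expect_error(recovery_rate(a, token_track(1L, v)), "length")
  expect_error(recovery_rate(a, token_track(c(1L, 2L, 3L, v$mask_index), v)),
               "mask")
})

test_that("total-variation distance behaves on known cases", {
  w <- small_toy_world()
  j <- enumerate_joint(w, 2)
  n_out <- length(j$p)
  exact_counts <- round(j$p * 1e9)
  expect_lt(tv_distance(exact_counts, j), 1e-6)
  point <- rep(0, n_out)
  point[which.min(j$p)] <- 100
  expect_gt(tv_distance(point, j), 0.9)
  expect_error(tv_distance(rep(1, 5), j), "outcome spaces")
  expect_error(tv_distance(rep(0, n_out), j), "empty")
})

test_that("untrained uniform heads predict at chance level", {
  # fully symmetric world: uniform token marginals, so any input-independent
  # predictor (including the all-ties argmax) sits at 1/(K-1)
  w <- toy_world_params(n_hidden = 4L, n_seq_tokens = 4L, n_struct_tokens = 4L,
                        stay = 0.8, peak = 0.7)
  cfg <- denoiser_config(n_blocks = 1L, model_dim = 16L, n_heads = 2L,
                         time_feature_dim = 8L, max_len = 8L)
  m <- init_denoiser(cfg, w$seq_vocab, w$struct_vocab, seed = 21)
  m$params$Ws[] <- 0; m$params$bs[] <- 0
  m$params$Wr[] <- 0; m$params$br[] <- 0
  ds <- sample_toy_proteins(w, 150, 8, seed = 22)
  acc <- unmasking_accuracy(make_model_denoiser(m), ds, c(0.3, 0.6), seed = 23)
  for (i in seq_len(nrow(acc))) {
    se <- sqrt(0.25 * 0.75 / acc$n_masked[i])
    expect_lt(abs(acc$accuracy[i] - 0.25), 3 * se)
  }
  expect_error(unmasking_accuracy(make_model_denoiser(m), list(), 0.5), "empty")
  expect_error(unmasking_accuracy(make_model_denoiser(m), ds, numeric(0)),
               "empty")
  expect_error(unmasking_accuracy(make_model_denoiser(m), ds, c(0, 0.5)),
               "strictly")
})

test_that("self-consistency is perfect in a deterministic world and beats a
           shuffled baseline in a coupled one", {
  wd <- degenerate_world()
  ps <- sample_toy_proteins(wd, 20, 6, seed = 24)
  expect_equal(as.numeric(self_consistency(ps, wd)), 1)
  w <- small_toy_world()
  ps <- sample_toy_proteins(w, 200, 8, seed = 25)
  sc <- as.numeric(self_consistency(ps, w))
  set.seed(26)
  perm <- sample(length(ps))
  shuffled <- lapply(seq_along(ps), function(i)
    protein_tokens(ps[[i]]$seq, ps[[perm[i]]]$struct))
  expect_gt(sc, as.numeric(self_consistency(shuffled, w)))
})

test_that("metric reports validate and tabulate", {
  m <- metric_report("nsr", 0.61, 200, 0.01, config = list(steps = 100))
  df <- as.data.frame(m)
  expect_equal(df$value, 0.61)
  expect_equal(df$n, 200L)
  expect_error(metric_report("x", 1, 0), "n >= 1")
  expect_error(metric_report("x", 1, 10, -1), "dispersion")
})
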
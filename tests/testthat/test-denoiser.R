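tiny_cfg <- denoiser_config(n_blocks = 2L, model_dim = 16L, n_heads = 2L,
                            time_feature_dim = 8L, ffn_mult = 2L, max_len = 8L)
tiny_world <- toy_world_params(n_hidden = 2L, n_seq_tokens = 3L,
                               n_struct_tokens = 3L, stay = 0.9, peak = 0.9)

test_that("fourier time features hit their closed forms and separate times", {
  f0 <- fourier_time_features(0, 32)
  expect_equal(f0, c(rep(0, 16), rep(1, 16)))
  f <- fourier_time_features(0.37, 32)
  expect_length(f, 32)
  expect_true(all(abs(f) <= 1))
  expect_gt(max(abs(fourier_time_features(0.3, 32) -
                      fourier_time_features(0.7, 32))), 1e-3)
  expect_error(fourier_time_features(0.5, 7), "even")
  expect_error(fourier_time_features(1.5, 8), "0, 1")
})

test_that("forward output is normalised, mask-free and deterministic", {
  m <- init_denoiser(tiny_cfg, tiny_world$seq_vocab, tiny_world$struct_vocab,
                     seed = 2)
  xt <- corrupt_seeded <- {
    set.seed(3)
    corrupt(sample_toy_proteins(tiny_world, 1, 6, seed = 3)[[1]], 0.5, 0.5)
  }
  f1 <- denoiser_forward(m, xt, 0.5)
  f2 <- denoiser_forward(m, xt, 0.5)
  expect_identical(f1$seq$probs, f2$seq$probs)
  expect_equal(rowSums(f1$seq$probs), rep(1, 6), tolerance = 1e-12)
  expect_true(all(mask_mass(f1$seq) == 0))
  expect_true(all(mask_mass(f1$struct) == 0))
  expect_error(
    protein_tokens(masked_track(6, tiny_world$seq_vocab, "sequence"),
                   masked_track(5, tiny_world$struct_vocab, "structure")),
    "identical length")
})

test_that("zeroed output heads give exactly uniform cross-entropy", {
  m <- init_denoiser(tiny_cfg, tiny_world$seq_vocab, tiny_world$struct_vocab,
                     seed = 4)
  m$params$Ws[] <- 0
  m$params$bs[] <- 0
  m$params$Wr[] <- 0
  m$params$br[] <- 0
  x <- sample_toy_proteins(tiny_world, 1, 6, seed = 5)[[1]]
  f <- denoiser_forward(m, fully_masked_x0(tiny_world, 6), 0.2)
  ce <- -log(f$seq$probs[cbind(1:6, x$seq$tokens)]) -
    log(f$struct$probs[cbind(1:6, x$struct$tokens)])
  expect_equal(ce, rep(log(3) + log(3), 6), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  sv <- tiny_world$seq_vocab
  rv <- tiny_world$struct_vocab
  m <- init_denoiser(tiny_cfg, sv, rv, seed = 6)
  set.seed(7)
  S <- matrix(sample(seq_len(sv$size), 8, TRUE), 4, 2)
  R <- matrix(sample(seq_len(rv$size), 8, TRUE), 4, 2)
  S1 <- matrix(sample(seq_len(sv$size - 1L), 8, TRUE), 4, 2)
  R1 <- matrix(sample(seq_len(rv$size - 1L), 8, TRUE), 4, 2)
  tv <- c(0.25, 0.8)
  loss <- function(model) {
    fw <- maskflow:::.den_forward(model, S, R, tv)
    -sum(log(fw$ps[cbind(1:8, as.vector(S1))])) -
      sum(log(fw$pr[cbind(1:8, as.vector(R1))]))
  }
  fw <- maskflow:::.den_forward(m, S, R, tv, need_cache = TRUE)
  dls <- fw$ps
  dls[cbind(1:8, as.vector(S1))] <- dls[cbind(1:8, as.vector(S1))] - 1
  dlr <- fw$pr
  dlr[cbind(1:8, as.vector(R1))] <- dlr[cbind(1:8, as.vector(R1))] - 1
  g <- maskflow:::.den_backward(m, fw$cache, dls, dlr)
  eps <- 1e-5
  probe <- function(get, set, gmat) {
    set.seed(8)
    for (r in 1:3) {
      i <- sample(nrow(gmat), 1)
      jj <- sample(ncol(gmat), 1)
      up <- m
      v <- get(up)
      v[i, jj] <- v[i, jj] + eps
      up <- set(up, v)
      dn <- m
      v <- get(dn)
      v[i, jj] <- v[i, jj] - eps
      dn <- set(dn, v)
      fd <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(gmat[i, jj], fd, tolerance = 1e-5)
    }
  }
  probe(function(m) m$params$emb_seq,
        function(m, v) { m$params$emb_seq <- v; m }, g$emb_seq)
  probe(function(m) m$params$blocks[[1]]$Wq,
        function(m, v) { m$params$blocks[[1]]$Wq <- v; m }, g$blocks[[1]]$Wq)
  probe(function(m) m$params$blocks[[2]]$W1,
        function(m, v) { m$params$blocks[[2]]$W1 <- v; m }, g$blocks[[2]]$W1)
  probe(function(m) m$params$blocks[[1]]$W_time,
        function(m, v) { m$params$blocks[[1]]$W_time <- v; m },
        g$blocks[[1]]$W_time)
})

test_that("the denoiser memorises a single repeated example", {
  x <- sample_toy_proteins(tiny_world, 1, 6, seed = 9)[[1]]
  fit <- train_denoiser(rep(list(x), 8), tiny_cfg,
                        train_config(epochs = 120, batch_size = 8,
                                     learning_rate = 3e-3, seed = 10))
  expect_lt(fit$trace$loss[nrow(fit$trace)], 0.05)
  f <- denoiser_forward(fit$model, fully_masked_x0(tiny_world, 6), 0)
  expect_identical(max.col(f$seq$probs), x$seq$tokens)
  expect_identical(max.col(f$struct$probs), x$struct$tokens)
})

test_that("training is seed-deterministic and the loss decreases", {
  ds <- sample_toy_proteins(tiny_world, 150, 6, seed = 11)
  a <- train_denoiser(ds, tiny_cfg, train_config(epochs = 4, batch_size = 50,
                                                 seed = 12))
  b <- train_denoiser(ds, tiny_cfg, train_config(epochs = 4, batch_size = 50,
                                                 seed = 12))
  expect_identical(a$trace, b$trace)
  expect_lt(a$trace$loss[4], a$trace$loss[1])
  expect_error(train_denoiser(list(), tiny_cfg), "empty")
  xm <- fully_masked_x0(tiny_world, 6)
  expect_error(train_denoiser(list(xm), tiny_cfg), "fully observed")
})

test_that("checkpoints round-trip through disk", {
  m <- init_denoiser(tiny_cfg, tiny_world$seq_vocab, tiny_world$struct_vocab,
                     seed = 13)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m$params, m2$params)
  x <- fully_masked_x0(tiny_world, 6)
  expect_identical(denoiser_forward(m, x, 0.4)$seq$probs,
                   denoiser_forward(m2, x, 0.4)$seq$probs)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
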
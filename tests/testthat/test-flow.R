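va <- vocabulary(c("a", "b", "c", "d", "-"))  # 4 real tokens + mask

test_that("conditional interpolation hits its endpoints and linear midpoints", {
  tr <- token_track(c(1L, 3L, 2L), va)
  f0 <- interpolate_conditional(tr, 0)
  expect_true(all(f0$probs[, va$mask_index] == 1))
  f1 <- interpolate_conditional(tr, 1)
  expect_equal(f1$probs[cbind(1:3, tr$tokens)], rep(1, 3))
  f <- interpolate_conditional(tr, 0.25)
  expect_equal(f$probs[1, 1], 0.25)
  expect_equal(f$probs[1, va$mask_index], 0.75)
  expect_equal(sum(f$probs[1, c(2, 3, 4)]), 0)
  expect_error(interpolate_conditional(tr, 1.2), "0, 1")
  expect_error(interpolate_conditional(token_track(c(1L, 5L), va), 0.5), "observed")
})

test_that("corruption keeps tokens with probability t and masks the rest", {
  w <- toy_world_params()
  x1 <- sample_toy_proteins(w, 1, 1000, seed = 1)[[1]]
  expect_identical(corrupt(x1, 1, 1)$seq$tokens, x1$seq$tokens)
  x0 <- corrupt(x1, 0, 0)
  expect_true(all(x0$seq$tokens == w$seq_vocab$mask_index))
  expect_true(all(x0$struct$tokens == w$struct_vocab$mask_index))
  # binomial concentration at t = 0.5 over 1000 positions per track
  set.seed(42)
  xt <- corrupt(x1, 0.5, 0.5)
  frac <- mean(xt$seq$tokens == w$seq_vocab$mask_index)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(corrupt(x0, 0.5), "observed")
})

test_that("transition kernel matches the closed-form unmasking rates", {
  f_uniform <- categorical_field(
    matrix(c(rep(0.25, 4), 0), 1), va)
  m <- token_track(va$mask_index, va)
  a <- token_track(1L, va)
  # masked position, eta = 0: coefficient dt/(1-t) spread over predictions
  k <- transition_kernel(m, f_uniform, flow_time(0.5, 0.1), eta = 0)
  expect_equal(k$probs[1, 1:4], rep(0.05, 4))
  expect_equal(k$probs[1, va$mask_index], 0.8)
  # observed position, eta = 0: point mass
  k <- transition_kernel(a, f_uniform, flow_time(0.3, 0.1), eta = 0)
  expect_equal(k$probs[1, 1], 1)
  # observed position, eta = 2: remask probability eta * dt
  k <- transition_kernel(a, f_uniform, flow_time(0.3, 0.01), eta = 2)
  expect_equal(k$probs[1, va$mask_index], 0.02)
  expect_equal(k$probs[1, 1], 0.98)
  # masked position, eta = 2: bonus unmasking mass (1 + eta t) dt / (1 - t)
  k <- transition_kernel(m, f_uniform, flow_time(0.5, 0.1), eta = 2)
  expect_equal(sum(k$probs[1, 1:4]), 0.4)
  expect_equal(k$probs[1, va$mask_index], 0.6)
  # last step: remasking switched off entirely
  k <- transition_kernel(a, f_uniform, flow_time(0.9, 0.1, is_last = TRUE), eta = 2)
  expect_equal(k$probs[1, 1], 1)
})

test_that("the unmask coefficient clamps at 1 and rows stay normalised", {
  fp <- matrix(c(rep(0.25, 4), 0), 1)
  probs <- maskflow:::.kernel_probs(va$mask_index, fp, t = 0.95, dt = 0.1,
                                    eta = 0, is_last = FALSE,
                                    mask_index = va$mask_index)
  # raw dt/(1-t) = 2 would break normalisation; clamped to 1 = full unmask
  expect_equal(probs[1, ], c(rep(0.25, 4), 0))
  expect_equal(sum(probs), 1)
})

test_that("kernel rejects invalid inputs", {
  bad <- categorical_field(matrix(c(rep(0.2, 5)), 1), va)
  m <- token_track(va$mask_index, va)
  expect_error(transition_kernel(m, bad, flow_time(0.5, 0.1)), "mask")
  good <- categorical_field(matrix(c(rep(0.25, 4), 0), 1), va)
  expect_error(transition_kernel(m, good, flow_time(0.5, 0.1), eta = 20), "exceeds 1")
  expect_error(flow_time(1, 0.1), "exceeds 1")
  expect_error(flow_time(0.5, 0))
})

test_that("interpolation and kernel rows sum to one across random draws", {
  set.seed(99)
  tr <- token_track(sample(1:4, 8, TRUE), va)
  worst <- 0
  for (i in 1:1000) {
    t <- runif(1, 0, 0.99)
    dt <- runif(1, 0, 1 - t)
    eta <- runif(1, 0, min(2, 1 / max(dt, 1e-9)))
    fp <- matrix(runif(8 * 4), 8, 4)
    fp <- fp / rowSums(fp)
    fpred <- categorical_field(cbind(fp[, 1:4], 0), va)
    xt <- token_track(sample(1:5, 8, TRUE), va)
    ki <- transition_kernel(xt, fpred, flow_time(t, dt, is_last = i %% 7 == 0),
                            eta = eta)
    fi <- interpolate_conditional(tr, t)
    worst <- max(worst, abs(rowSums(ki$probs) - 1), abs(rowSums(fi$probs) - 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("mask fraction after corruption follows the 1 - t law", {
  w <- toy_world_params()
  proteins <- sample_toy_proteins(w, 500, 16, seed = 7)
  set.seed(8)
  for (t in c(0.2, 0.5, 0.8)) {
    fr <- mean(vapply(proteins, function(x) {
      mean(corrupt(x, t, t)$seq$tokens == w$seq_vocab$mask_index)
    }, numeric(1)))
    expect_lt(abs(fr - (1 - t)), 3 * sqrt(t * (1 - t) / (500 * 16)))
  }
})
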
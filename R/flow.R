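#' Position on the sampling time grid
#'
#' Bundles the current flow time t, the step width dt and bookkeeping for the
#' final step, where the kernel must not re-mask.
#'
#' @param t Real in `[0, 1]`.
#' @param dt Real in `(0, 1]`; `t + dt` may not exceed 1 (up to rounding).
#' @param step_index 0-based index of the step in its schedule.
#' @param is_last TRUE iff this is the schedule's final step.
#' @export
flow_time <- function(t, dt, step_index = 0L, is_last = FALSE) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1]")
  if (t + dt > 1 + 1e-12) stop("t + dt exceeds 1")
  structure(list(t = t, dt = dt, step_index = as.integer(step_index),
                 is_last = isTRUE(is_last)), class = "mf_time")
}

#' Sampler configuration
#'
#' The sampling contract of the posterior transition kernel: number of Euler
#' steps on the uniform grid t_k = k/steps, the balanced-noise rate eta that
#' permits temporary re-masking, the track-scheduling strategy, the softmax
#' temperature applied to denoiser rows, and the RNG seed.
#'
#' @param steps Positive integer number of Euler steps (default 400).
#' @param eta Nonnegative noise rate (default 0: pure absorbing unmasking).
#' @param strategy One of `"synchronous"`, `"asynchronous"`,
#'   `"sequence_first"`, `"structure_first"`.
#' @param temperature Positive real; denoiser rows are raised to the power
#'   `1/temperature` and renormalised before sampling (default 1).
#' @param seed Integer RNG seed.
#' @export
sampler_config <- function(steps = 400L, eta = 0, strategy = "synchronous",
                           temperature = 1, seed = 1L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (eta < 0) stop("eta must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  strategy <- match.arg(strategy, c("synchronous", "asynchronous",
                                    "sequence_first", "structure_first"))
  structure(list(steps = steps, eta = eta, strategy = strategy,
                 temperature = temperature, seed = as.integer(seed)),
            class = "mf_sampler_config")
}

#' Conditional interpolation field p(x_t | x_1)
#'
#' The linear-interpolation conditional flow for one track: at each position
#' the distribution puts probability t on the data token and 1 - t on the
#' mask, so t = 0 is pure mask noise and t = 1 the data point.
#'
#' @param x1_track An `mf_track` with no mask tokens (the observed data point).
#' @param t Interpolation time in `[0, 1]`.
#' @param vocab Vocabulary of the track (defaults to the track's own).
#' @return An `mf_field` with rows `t * onehot(x1) + (1 - t) * onehot(mask)`.
#' @export
interpolate_conditional <- function(x1_track, t, vocab = x1_track$vocab) {
  stopifnot(inherits(x1_track, "mf_track"))
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  if (has_mask(x1_track)) stop("x1 must be fully observed (no mask tokens)")
  n <- length(x1_track$tokens)
  probs <- matrix(0, n, vocab$size)
  probs[cbind(seq_len(n), x1_track$tokens)] <- t
  probs[, vocab$mask_index] <- probs[, vocab$mask_index] + (1 - t)
  categorical_field(probs, vocab)
}

#' Corrupt a protein by masking towards time t
#'
#' Samples x_t from the conditional flow: each sequence position independently
#' keeps its token with probability `t_seq`, else becomes the sequence mask;
#' likewise the structure track with `t_struct`.
#'
#' @param x1 A fully observed `mf_protein`.
#' @param t_seq,t_struct Interpolation times in `[0, 1]` per track.
#' @return A corrupted `mf_protein`.
#' @export
corrupt <- function(x1, t_seq, t_struct = t_seq) {
  stopifnot(inherits(x1, "mf_protein"))
  if (t_seq < 0 || t_seq > 1 || t_struct < 0 || t_struct > 1)
    stop("interpolation times must lie in [0, 1]")
  if (has_mask(x1$seq) || has_mask(x1$struct))
    stop("x1 must be fully observed (no mask tokens)")
  n <- length(x1)
  s <- x1$seq$tokens
  keep <- stats::runif(n) < t_seq
  s[!keep] <- x1$seq$vocab$mask_index
  r <- x1$struct$tokens
  keep <- stats::runif(n) < t_struct
  r[!keep] <- x1$struct$vocab$mask_index
  protein_tokens(token_track(s, x1$seq$vocab, "sequence"),
                 token_track(r, x1$struct$vocab, "structure"))
}

# matrix variants used by the batched sampler and the trainer: tokens as an
# n_items x N integer matrix per track

.corrupt_matrix <- function(tokens, t_keep, mask_index) {
  keep <- matrix(stats::runif(length(tokens)) < t_keep,
                 nrow(tokens), ncol(tokens))
  tokens[!keep] <- mask_index
  tokens
}
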
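#' Posterior transition kernel of the discrete flow
#'
#' One Euler step of the continuous-time Markov chain, per position. For a
#' masked position the kernel unmasks with coefficient
#' `c = min(1, dt * (1 + eta * t) / (1 - t))`, spreading `c` over the
#' denoiser's predicted distribution and keeping `1 - c` on the mask. For an
#' observed position the token is kept with probability `1 - eta * dt` and
#' re-masked with probability `eta * dt`; at the schedule's last step the
#' re-mask probability becomes zero so the final sample is mask-free.
#'
#' @param xt_track Current `mf_track` (may contain masks).
#' @param f_pred An `mf_field` of predicted distributions with zero mass on
#'   the mask token.
#' @param time An `mf_time` (t, dt, last-step flag).
#' @param eta Nonnegative balanced-noise rate.
#' @param vocab Track vocabulary (defaults to the track's own).
#' @return An `mf_field`: the per-position transition distributions.
#' @export
transition_kernel <- function(xt_track, f_pred, time, eta = 0,
                              vocab = xt_track$vocab) {
  stopifnot(inherits(xt_track, "mf_track"), inherits(f_pred, "mf_field"),
            inherits(time, "mf_time"))
  if (time$t >= 1) stop("transition kernel requires t < 1")
  if (eta < 0) stop("eta must be >= 0")
  if (eta * time$dt > 1) stop("eta * dt exceeds 1: no valid distribution")
  if (max(mask_mass(f_pred)) > 1e-12)
    stop("f_pred must put zero probability on the mask token")
  probs <- .kernel_probs(xt_track$tokens, f_pred$probs, time$t, time$dt,
                         eta, time$is_last, vocab$mask_index)
  categorical_field(probs, vocab)
}

# vectorised kernel over flat token vectors; fpred rows align with tokens
.kernel_probs <- function(tokens, fpred, t, dt, eta, is_last, mask_index) {
  m <- length(tokens)
  out <- matrix(0, m, ncol(fpred))
  is_m <- tokens == mask_index
  if (any(is_m)) {
    cc <- min(1, dt * (1 + eta * t) / (1 - t))
    out[is_m, ] <- cc * fpred[is_m, , drop = FALSE]
    out[is_m, mask_index] <- 1 - cc
  }
  if (any(!is_m)) {
    stay <- if (is_last) 1 else 1 - eta * dt
    idx <- which(!is_m)
    out[cbind(idx, tokens[idx])] <- stay
    if (stay < 1) out[idx, mask_index] <- 1 - stay
  }
  out
}

# one categorical draw per row by inverse CDF; one uniform per row, rows in
# index order, so trajectories are bit-reproducible given the seed
.sample_rows <- function(probs) {
  m <- nrow(probs)
  k <- ncol(probs)
  u <- stats::runif(m)
  acc <- numeric(m)
  cnt <- integer(m)
  for (j in seq_len(k - 1L)) {
    acc <- acc + probs[, j]
    cnt <- cnt + (u > acc)
  }
  cnt + 1L
}

# temperature as a power transform on the non-mask mass, renormalised
.apply_temperature <- function(probs, temperature) {
  if (temperature == 1) return(probs)
  p <- probs^(1 / temperature)
  p / rowSums(p)
}

.row_entropy <- function(probs) {
  p <- probs
  p[p <= 0] <- 1  # 0 log 0 = 0
  -rowSums(probs * log(p))
}

#' Degenerate denoiser concentrated on a fixed target
#'
#' Always predicts one-hot distributions on the tokens of `x1`, whatever the
#' input. Useful as a determinism oracle: the Euler sampler must reproduce
#' `x1` exactly.
#'
#' @param x1 A fully observed `mf_protein`.
#' @return A denoiser function `(x, t) -> list(seq, struct)` of `mf_field`s.
#' @export
delta_denoiser <- function(x1) {
  stopifnot(inherits(x1, "mf_protein"))
  if (has_mask(x1$seq) || has_mask(x1$struct)) stop("x1 must be fully observed")
  onehot <- function(tokens, vocab) {
    p <- matrix(0, length(tokens), vocab$size)
    p[cbind(seq_along(tokens), tokens)] <- 1
    p
  }
  fs <- categorical_field(onehot(x1$seq$tokens, x1$seq$vocab), x1$seq$vocab)
  fr <- categorical_field(onehot(x1$struct$tokens, x1$struct$vocab), x1$struct$vocab)
  structure(function(x, t) list(seq = fs, struct = fr), class = "mf_denoiser")
}

# engine-facing denoiser contract: f(S, R, t) -> list(seq, struct) of
# (N*B) x K probability matrices, rows ordered position-fastest (sample-major),
# given N x B token matrices S, R. Class "mf_batch_denoiser" marks functions
# already in this form.
.as_engine_denoiser <- function(denoiser, seq_vocab, struct_vocab) {
  if (inherits(denoiser, "mf_batch_denoiser")) return(denoiser)
  function(S, R, t) {
    b <- ncol(S)
    outs <- vector("list", b)
    for (i in seq_len(b)) {
      x <- protein_tokens(token_track(S[, i], seq_vocab, "sequence"),
                          token_track(R[, i], struct_vocab, "structure"))
      f <- denoiser(x, t)
      outs[[i]] <- list(f$seq$probs, f$struct$probs)
    }
    list(seq = do.call(rbind, lapply(outs, `[[`, 1)),
         struct = do.call(rbind, lapply(outs, `[[`, 2)))
  }
}

# core batched Euler loop over the uniform global grid t_k = k/steps.
# Each track follows its own internal clock over the steps where its strategy
# makes it active; the denoiser is conditioned on the global time.
.euler_engine <- function(engine_den, S, R, cond_seq, cond_struct, config,
                          seq_vocab, struct_vocab, record = FALSE) {
  n <- nrow(S)
  b <- ncol(S)
  steps <- config$steps
  sched <- .track_schedule(config$strategy, steps)
  tracks <- list(
    sequence = list(active = sched$sequence, m = length(sched$sequence), j = 0L,
                    mask = seq_vocab$mask_index, cond = cond_seq),
    structure = list(active = sched$structure, m = length(sched$structure), j = 0L,
                     mask = struct_vocab$mask_index, cond = cond_struct)
  )
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    tok0 <- if (nm == "sequence") S else R
    if (tr$m == 0L && any(tok0 == tr$mask & !tr$cond))
      stop("strategy '", config$strategy, "' never activates the ", nm,
           " track; masks would remain")
  }
  ent_seq <- matrix(NA_real_, n, b)
  ent_struct <- matrix(NA_real_, n, b)
  remask_events <- 0L
  traj <- if (record) vector("list", steps)
  cond_flat <- list(sequence = rep(cond_seq, b), structure = rep(cond_struct, b))

  for (k in seq_len(steps) - 1L) {
    t_global <- k / steps
    den <- engine_den(S, R, t_global)
    for (nm in c("sequence", "structure")) {
      if (max(den[[if (nm == "sequence") "seq" else "struct"]][, tracks[[nm]]$mask]) > 1e-12)
        stop("denoiser emitted probability mass on the ", nm, " mask token")
    }
    fs <- .apply_temperature(den$seq, config$temperature)
    fr <- .apply_temperature(den$struct, config$temperature)
    if (record) {
      traj_step <- list(step_index = k, t = t_global, active = character(0))
    }
    for (nm in c("sequence", "structure")) {
      tr <- tracks[[nm]]
      if (!(k %in% tr$active)) next
      tr$j <- tr$j + 1L
      t_tr <- (tr$j - 1L) / tr$m
      dt_tr <- 1 / tr$m
      is_last <- tr$j == tr$m
      tok <- if (nm == "sequence") S else R
      fpred <- if (nm == "sequence") fs else fr
      flat <- as.vector(tok)  # N x B, column-major: position-fastest
      kern <- .kernel_probs(flat, fpred, t_tr, dt_tr, config$eta, is_last, tr$mask)
      cf <- cond_flat[[nm]]
      if (any(cf)) {
        # conditioning tokens are frozen: identity kernel, exempt from eta
        kern[cf, ] <- 0
        kern[cbind(which(cf), flat[cf])] <- 1
      }
      new_flat <- .sample_rows(kern)
      unmasked <- flat == tr$mask & new_flat != tr$mask
      if (any(unmasked)) {
        ent <- .row_entropy(fpred[unmasked, , drop = FALSE])
        if (nm == "sequence") ent_seq[unmasked] <- ent else ent_struct[unmasked] <- ent
      }
      remask_events <- remask_events + sum(flat != tr$mask & new_flat == tr$mask & !cf)
      newtok <- matrix(new_flat, n, b)
      if (nm == "sequence") S <- newtok else R <- newtok
      tracks[[nm]] <- tr
      if (record) {
        traj_step$active <- c(traj_step$active, nm)
        slot <- if (nm == "sequence") "seq" else "struct"
        traj_step[[paste0(slot, "_time")]] <- list(t = t_tr, dt = dt_tr, is_last = is_last)
        traj_step[[paste0("p_sampled_", slot)]] <- kern[cbind(seq_along(new_flat), new_flat)]
        traj_step[[paste0("f_", slot)]] <- fpred
      }
    }
    if (record) {
      traj_step$seq_tokens <- S[, 1]
      traj_step$struct_tokens <- R[, 1]
      traj[[k + 1L]] <- traj_step
    }
  }
  if (any(S == seq_vocab$mask_index) || any(R == struct_vocab$mask_index))
    stop("internal error: masks remained after the full schedule")
  ent_total <- colSums(rbind(ent_seq, ent_struct), na.rm = TRUE) / n
  out <- list(seq = S, struct = R, gen_entropy = ent_total,
              entropy_seq = ent_seq, entropy_struct = ent_struct,
              remask_events = remask_events)
  if (record) {
    out$trajectory <- structure(
      list(steps = traj, config = config, cond = cbind(seq = cond_seq, struct = cond_struct),
           seq_vocab = seq_vocab, struct_vocab = struct_vocab),
      class = "mf_trajectory")
  }
  out
}

.check_x0 <- function(x0, cond) {
  n <- length(x0)
  if (is.null(cond)) cond <- matrix(FALSE, n, 2, dimnames = list(NULL, c("seq", "struct")))
  cond <- as.matrix(cond)
  stopifnot(nrow(cond) == n, ncol(cond) == 2)
  for (nm in c("seq", "struct")) {
    track <- x0[[nm]]
    ism <- track$tokens == track$vocab$mask_index
    if (any(cond[, nm] & ism))
      stop("conditioning flags point at mask tokens in the ", nm, " track")
    if (any(!cond[, nm] & !ism))
      stop("non-conditioning ", nm, " positions must start masked")
  }
  cond
}

#' Euler-sample one protein from the discrete flow
#'
#' Runs the continuous-time Markov chain from the (partially) masked state x0
#' at t = 0 to a fully observed protein at t = 1, on the uniform schedule
#' `t_k = k/steps`, querying the denoiser once per step and sampling every
#' active position independently from its transition kernel. Conditioning
#' positions are never resampled and never re-masked.
#'
#' @param denoiser Either a function `(mf_protein, t) -> list(seq, struct)` of
#'   `mf_field`s with zero mask mass, or an engine-ready batch denoiser of
#'   class `mf_batch_denoiser` (see [make_posterior_denoiser()]).
#' @param x0 Starting `mf_protein`; non-conditioning positions must be masks.
#' @param cond Optional N x 2 logical matrix (columns seq, struct) of
#'   conditioning flags, e.g. from [make_condition_mask()].
#' @param config An `mf_sampler_config`.
#' @return A list with `x1` (the sampled `mf_protein`), `trajectory` (an
#'   `mf_trajectory` usable by [generation_entropy()]) and `remask_events`.
#' @export
euler_sample <- function(denoiser, x0, cond = NULL, config = sampler_config()) {
  stopifnot(inherits(x0, "mf_protein"))
  cond <- .check_x0(x0, cond)
  sv <- x0$seq$vocab
  rv <- x0$struct$vocab
  eng <- .as_engine_denoiser(denoiser, sv, rv)
  if (!is.na(config$seed)) set.seed(config$seed)
  res <- .euler_engine(eng, matrix(x0$seq$tokens, ncol = 1),
                       matrix(x0$struct$tokens, ncol = 1),
                       cond[, 1], cond[, 2], config, sv, rv, record = TRUE)
  x1 <- protein_tokens(token_track(res$seq[, 1], sv, "sequence"),
                       token_track(res$struct[, 1], rv, "structure"))
  list(x1 = x1, trajectory = res$trajectory, remask_events = res$remask_events,
       gen_entropy = res$gen_entropy[1])
}

#' Euler-sample a batch of independent proteins
#'
#' Vectorised variant of [euler_sample()]: `n` independent trajectories share
#' the schedule and denoiser calls. Per-sample generation entropies (sum of
#' the entropy of the predicted row in force at each position's final
#' unmasking event, both tracks, divided by N) are accumulated online.
#'
#' @inheritParams euler_sample
#' @param n Number of independent samples.
#' @return A list with `seq` and `struct` (`n` x N token-id matrices),
#'   `gen_entropy` (length-`n` vector), and `remask_events` (total count).
#' @export
euler_sample_batch <- function(denoiser, n, x0, cond = NULL,
                               config = sampler_config()) {
  stopifnot(inherits(x0, "mf_protein"), n >= 1)
  cond <- .check_x0(x0, cond)
  sv <- x0$seq$vocab
  rv <- x0$struct$vocab
  eng <- .as_engine_denoiser(denoiser, sv, rv)
  if (!is.na(config$seed)) set.seed(config$seed)
  S <- matrix(x0$seq$tokens, length(x0), n)
  R <- matrix(x0$struct$tokens, length(x0), n)
  res <- .euler_engine(eng, S, R, cond[, 1], cond[, 2], config, sv, rv)
  list(seq = t(res$seq), struct = t(res$struct),
       gen_entropy = res$gen_entropy, remask_events = res$remask_events)
}

#' Euler-sample once per starting state, sharing conditioning flags
#'
#' Runs one trajectory per element of `x0_list` in a single vectorised pass.
#' All starting states must share the same conditioning flag pattern (e.g.
#' inverse folding over a set of proteins: the whole structure track is given
#' for every item, but the given tokens differ).
#'
#' @inheritParams euler_sample
#' @param x0_list List of `mf_protein` starting states of equal length.
#' @return As [euler_sample_batch()]; row i of the outputs corresponds to
#'   `x0_list[[i]]`.
#' @export
euler_sample_set <- function(denoiser, x0_list, cond = NULL,
                             config = sampler_config()) {
  stopifnot(length(x0_list) >= 1)
  cond <- .check_x0(x0_list[[1]], cond)
  sv <- x0_list[[1]]$seq$vocab
  rv <- x0_list[[1]]$struct$vocab
  n_pos <- length(x0_list[[1]])
  for (x in x0_list) {
    stopifnot(inherits(x, "mf_protein"))
    if (length(x) != n_pos) stop("all starting states must share one length")
    .check_x0(x, cond)
  }
  eng <- .as_engine_denoiser(denoiser, sv, rv)
  if (!is.na(config$seed)) set.seed(config$seed)
  S <- vapply(x0_list, function(x) x$seq$tokens, integer(n_pos))
  R <- vapply(x0_list, function(x) x$struct$tokens, integer(n_pos))
  res <- .euler_engine(eng, matrix(S, nrow = n_pos), matrix(R, nrow = n_pos),
                       cond[, 1], cond[, 2], config, sv, rv)
  list(seq = t(res$seq), struct = t(res$struct),
       gen_entropy = res$gen_entropy, remask_events = res$remask_events)
}
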
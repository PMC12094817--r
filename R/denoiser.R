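#' Denoiser architecture configuration
#'
#' A small bidirectional transformer: summed sequence/structure/position
#' embeddings in, one trunk of pre-norm attention + feed-forward blocks with a
#' learned projection of Fourier time features added to every block's input,
#' and two per-residue output distributions (sequence and structure) with the
#' mask logits excluded before normalisation.
#'
#' @param n_blocks Transformer blocks (default 4; a desk-scale trunk).
#' @param model_dim Residue embedding width (default 128).
#' @param n_heads Attention heads (default 4); must divide `model_dim`.
#' @param time_feature_dim Even length of the Fourier time-feature vector
#'   (default 32).
#' @param ffn_mult Feed-forward hidden width as a multiple of `model_dim`
#'   (default 1; a slim desk-scale trunk).
#' @param max_len Longest protein the positional table supports (default 64).
#' @return An object of class `mf_denoiser_config`.
#' @export
denoiser_config <- function(n_blocks = 4L, model_dim = 128L, n_heads = 4L,
                            time_feature_dim = 32L, ffn_mult = 1L,
                            max_len = 64L) {
  if (time_feature_dim %% 2L != 0L) stop("time_feature_dim must be even")
  if (model_dim %% n_heads != 0L) stop("model_dim must be divisible by n_heads")
  structure(list(n_blocks = as.integer(n_blocks), model_dim = as.integer(model_dim),
                 n_heads = as.integer(n_heads),
                 time_feature_dim = as.integer(time_feature_dim),
                 ffn_mult = as.integer(ffn_mult), max_len = as.integer(max_len)),
            class = "mf_denoiser_config")
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Examples per gradient step.
#' @param learning_rate Adam step size.
#' @param seed RNG seed covering initialisation, shuffling, time draws and
#'   corruption.
#' @param loss_positions `"masked_only"` (default: unmasked positions are
#'   given under the flow factorisation and carry no learning signal) or
#'   `"all"`.
#' @param per_track_times If TRUE, sequence and structure are corrupted with
#'   independent times; default FALSE (one shared t per example).
#' @return An object of class `mf_train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 500L, learning_rate = 1e-3,
                         seed = 1L, loss_positions = c("masked_only", "all"),
                         per_track_times = FALSE) {
  loss_positions <- match.arg(loss_positions)
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss_positions = loss_positions,
                 per_track_times = isTRUE(per_track_times)),
            class = "mf_train_config")
}

#' Fourier time features
#'
#' Sines and cosines of the flow time at `dim/2` log-spaced frequencies in
#' `[1, 1000]`: `c(sin(2*pi*f*t), cos(2*pi*f*t))`.
#'
#' @param t Time in `[0, 1]`.
#' @param dim Even output length.
#' @return Numeric vector of length `dim` with values in `[-1, 1]`.
#' @export
fourier_time_features <- function(t, dim) {
  if (dim %% 2L != 0L || dim < 2L) stop("dim must be an even integer >= 2")
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  freqs <- 10^seq(0, 3, length.out = dim / 2L)
  c(sin(2 * pi * freqs * t), cos(2 * pi * freqs * t))
}

#' Initialise denoiser parameters
#'
#' @param dcfg An `mf_denoiser_config`.
#' @param seq_vocab,struct_vocab Track vocabularies (sizes include the mask;
#'   the output heads cover real tokens only).
#' @param seed Integer seed for the random initialisation.
#' @return An object of class `mf_denoiser_model`.
#' @export
init_denoiser <- function(dcfg, seq_vocab, struct_vocab, seed = 1L) {
  stopifnot(inherits(dcfg, "mf_denoiser_config"))
  set.seed(seed)
  d <- dcfg$model_dim
  dh <- d * dcfg$ffn_mult
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  blocks <- lapply(seq_len(dcfg$n_blocks), function(l) list(
    W_time = rn(dcfg$time_feature_dim, d, 0.02),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = rn(d, d, 1 / sqrt(d)), Wk = rn(d, d, 1 / sqrt(d)),
    Wv = rn(d, d, 1 / sqrt(d)), Wo = rn(d, d, 1 / sqrt(d)),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = rn(d, dh, 1 / sqrt(d)), b1 = rep(0, dh),
    W2 = rn(dh, d, 1 / sqrt(dh)), b2 = rep(0, d)
  ))
  params <- list(
    emb_seq = rn(seq_vocab$size, d, 0.02),
    emb_struct = rn(struct_vocab$size, d, 0.02),
    pos = rn(dcfg$max_len, d, 0.02),
    blocks = blocks,
    lnf_g = rep(1, d), lnf_b = rep(0, d),
    Ws = rn(d, seq_vocab$size - 1L, 1 / sqrt(d)), bs = rep(0, seq_vocab$size - 1L),
    Wr = rn(d, struct_vocab$size - 1L, 1 / sqrt(d)), br = rep(0, struct_vocab$size - 1L)
  )
  structure(list(config = dcfg, params = params,
                 seq_vocab = seq_vocab, struct_vocab = struct_vocab),
            class = "mf_denoiser_model")
}

#' @export
print.mf_denoiser_model <- function(x, ...) {
  cat("<mf_denoiser_model>", x$config$n_blocks, "blocks, dim",
      x$config$model_dim, ",", x$config$n_heads, "heads | vocabs",
      x$seq_vocab$size, "/", x$struct_vocab$size, "\n")
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

# column-wise scale/shift by recycling; avoids sweep()'s aperm copies
.col_scale <- function(x, g) x * rep(g, each = nrow(x))
.col_add <- function(x, b) x + rep(b, each = nrow(x))

.ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-5)
  xhat <- xc * inv
  list(y = .col_add(.col_scale(xhat, g), b), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- .col_scale(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.gelu <- function(x) .cpp_gelu(x)
.gelu_grad <- function(x) .cpp_gelu_grad(x)
.softmax_rows <- function(z) .cpp_softmax_rows(z)

# ---- forward ---------------------------------------------------------------

# S, R: np x B integer token matrices; t scalar or per-sample vector (length
# B). Returns real-token probability matrices (B*np rows, position-fastest)
# and, optionally, the cache for backprop.
.den_forward <- function(model, S, R, t, need_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  np <- nrow(S)
  b <- ncol(S)
  if (np > cfg$max_len)
    stop("protein length ", np, " exceeds the positional table (max_len = ",
         cfg$max_len, ")")
  if (!identical(dim(S), dim(R))) stop("track length mismatch")
  d <- cfg$model_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  sflat <- as.vector(S)
  rflat <- as.vector(R)
  pidx <- rep(seq_len(np), b)
  h <- p$emb_seq[sflat, , drop = FALSE] + p$emb_struct[rflat, , drop = FALSE] +
    p$pos[pidx, , drop = FALSE]
  if (length(t) == 1L) t <- rep(t, b)
  if (length(t) != b) stop("t must be scalar or one time per sample")
  ftm <- t(vapply(t, fourier_time_features, numeric(cfg$time_feature_dim),
                  dim = cfg$time_feature_dim))        # B x F
  FT <- ftm[rep(seq_len(b), each = np), , drop = FALSE]
  cache <- if (need_cache) list(sflat = sflat, rflat = rflat, pidx = pidx,
                                FT = FT, np = np, b = b, blocks = vector("list", cfg$n_blocks))
  for (l in seq_len(cfg$n_blocks)) {
    bp <- p$blocks[[l]]
    h <- h + FT %*% bp$W_time
    ln1 <- .ln_fwd(h, bp$ln1_g, bp$ln1_b)
    u <- ln1$y
    Q <- u %*% bp$Wq
    K <- u %*% bp$Wk
    V <- u %*% bp$Wv
    mha <- .cpp_mha_forward(Q, K, V, np, nh)
    ctx <- mha$ctx
    A <- mha$A
    att <- ctx %*% bp$Wo
    h_mid <- h + att
    ln2 <- .ln_fwd(h_mid, bp$ln2_g, bp$ln2_b)
    v <- ln2$y
    z1 <- .col_add(v %*% bp$W1, bp$b1)
    a1 <- .gelu(z1)
    h_out <- h_mid + .col_add(a1 %*% bp$W2, bp$b2)
    if (need_cache)
      cache$blocks[[l]] <- list(ln1 = ln1, u = u, Q = Q, K = K, V = V, A = A,
                                ctx = ctx, ln2 = ln2, v = v,
                                z1 = z1, a1 = a1)
    h <- h_out
  }
  lnf <- .ln_fwd(h, p$lnf_g, p$lnf_b)
  uf <- lnf$y
  logit_s <- .col_add(uf %*% p$Ws, p$bs)
  logit_r <- .col_add(uf %*% p$Wr, p$br)
  ps <- .softmax_rows(logit_s)
  pr <- .softmax_rows(logit_r)
  if (need_cache) {
    cache$lnf <- lnf
    cache$uf <- uf
    cache$ps <- ps
    cache$pr <- pr
  }
  list(ps = ps, pr = pr, cache = cache)
}

# dls, dlr: gradients w.r.t. the two logit matrices. Returns a gradient tree
# shaped like model$params.
.den_backward <- function(model, cache, dls, dlr) {
  p <- model$params
  cfg <- model$config
  np <- cache$np
  b <- cache$b
  d <- cfg$model_dim
  nh <- cfg$n_heads
  g <- list()
  g$Ws <- crossprod(cache$uf, dls)
  g$bs <- colSums(dls)
  g$Wr <- crossprod(cache$uf, dlr)
  g$br <- colSums(dlr)
  duf <- tcrossprod(dls, p$Ws) + tcrossprod(dlr, p$Wr)
  bk <- .ln_bwd(duf, cache$lnf, p$lnf_g)
  g$lnf_g <- bk$dg
  g$lnf_b <- bk$db
  dh_out <- bk$dx
  g$blocks <- vector("list", cfg$n_blocks)
  for (l in rev(seq_len(cfg$n_blocks))) {
    bp <- p$blocks[[l]]
    cb <- cache$blocks[[l]]
    gb <- list()
    # FFN branch
    da1 <- tcrossprod(dh_out, bp$W2)
    gb$W2 <- crossprod(cb$a1, dh_out)
    gb$b2 <- colSums(dh_out)
    dz1 <- da1 * .gelu_grad(cb$z1)
    gb$W1 <- crossprod(cb$v, dz1)
    gb$b1 <- colSums(dz1)
    dv <- tcrossprod(dz1, bp$W1)
    bk2 <- .ln_bwd(dv, cb$ln2, bp$ln2_g)
    gb$ln2_g <- bk2$dg
    gb$ln2_b <- bk2$db
    dh_mid <- dh_out + bk2$dx
    # attention branch
    datt <- dh_mid
    dctx <- tcrossprod(datt, bp$Wo)
    gb$Wo <- crossprod(cb$ctx, datt)
    mb <- .cpp_mha_backward(cb$A, cb$Q, cb$K, cb$V, dctx, np, nh)
    dQ <- mb$dQ
    dK <- mb$dK
    dV <- mb$dV
    gb$Wq <- crossprod(cb$u, dQ)
    gb$Wk <- crossprod(cb$u, dK)
    gb$Wv <- crossprod(cb$u, dV)
    du <- tcrossprod(dQ, bp$Wq) + tcrossprod(dK, bp$Wk) + tcrossprod(dV, bp$Wv)
    bk1 <- .ln_bwd(du, cb$ln1, bp$ln1_g)
    gb$ln1_g <- bk1$dg
    gb$ln1_b <- bk1$db
    dh_in <- dh_mid + bk1$dx
    gb$W_time <- crossprod(cache$FT, dh_in)
    g$blocks[[l]] <- gb
    dh_out <- dh_in
  }
  g$emb_seq <- .scatter_rows(dh_out, cache$sflat, nrow(p$emb_seq))
  g$emb_struct <- .scatter_rows(dh_out, cache$rflat, nrow(p$emb_struct))
  g$pos <- .scatter_rows(dh_out, cache$pidx, nrow(p$pos))
  g
}

.scatter_rows <- function(dm, idx, n_rows) {
  acc <- rowsum(dm, idx)
  out <- matrix(0, n_rows, ncol(dm))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# elementwise map over parallel parameter trees
.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    keys <- if (!is.null(names(trees[[1]]))) names(trees[[1]])
            else seq_along(trees[[1]])
    out <- lapply(keys, function(i)
      do.call(.tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

# ---- user-facing forward ---------------------------------------------------

#' Run the denoiser on one partially masked protein
#'
#' Returns the two per-residue categorical fields over the full vocabularies,
#' rows summing to 1 with exactly zero mass on the mask tokens (mask logits
#' are excluded before normalisation). Deterministic in (input, t, params).
#'
#' @param model An `mf_denoiser_model`.
#' @param xt An `mf_protein` (may contain masks).
#' @param t Flow time in `[0, 1]`.
#' @return List of two `mf_field`s, `seq` and `struct`.
#' @export
denoiser_forward <- function(model, xt, t) {
  stopifnot(inherits(model, "mf_denoiser_model"), inherits(xt, "mf_protein"))
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  f <- .den_forward(model, matrix(xt$seq$tokens, ncol = 1),
                    matrix(xt$struct$tokens, ncol = 1), t)
  list(seq = categorical_field(.embed_real(f$ps, model$seq_vocab), model$seq_vocab),
       struct = categorical_field(.embed_real(f$pr, model$struct_vocab), model$struct_vocab))
}

# place real-token probabilities into full-vocabulary columns, mask exactly 0
.embed_real <- function(p_real, vocab) {
  out <- matrix(0, nrow(p_real), vocab$size)
  out[, real_token_ids(vocab)] <- p_real
  out
}

#' Engine-ready batch denoiser from a trained model
#'
#' @param model An `mf_denoiser_model`.
#' @return A function of class `mf_batch_denoiser` for the Euler sampler.
#' @export
make_model_denoiser <- function(model) {
  stopifnot(inherits(model, "mf_denoiser_model"))
  f <- function(S, R, t) {
    out <- .den_forward(model, S, R, t)
    list(seq = .embed_real(out$ps, model$seq_vocab),
         struct = .embed_real(out$pr, model$struct_vocab))
  }
  structure(f, class = "mf_batch_denoiser")
}

# ---- training --------------------------------------------------------------

#' Train the denoiser on fully observed proteins
#'
#' Per example and epoch: draw t ~ Uniform(0, 1), corrupt both tracks to x_t
#' under the linear-interpolation flow, and minimise the summed per-track
#' cross-entropy of the predictions against x_1 at the positions selected by
#' `loss_positions` (per-masked-position mean within each track, so the
#' uniform-prediction baseline is `log(Ks - 1) + log(Kr - 1)`). Adam updates;
#' fully seeded and reproducible.
#'
#' @param dataset Nonempty list of fully observed `mf_protein`s of one length.
#' @param dcfg An `mf_denoiser_config`.
#' @param tcfg An `mf_train_config`.
#' @return List with `model` (trained `mf_denoiser_model`) and `trace` (one
#'   row per epoch: mean loss, per-track components).
#' @export
train_denoiser <- function(dataset, dcfg = denoiser_config(),
                           tcfg = train_config()) {
  if (length(dataset) == 0) stop("dataset is empty")
  np <- length(dataset[[1]])
  for (x in dataset) {
    if (has_mask(x$seq) || has_mask(x$struct))
      stop("training items must be fully observed")
    if (length(x) != np) stop("all training items must share one length")
  }
  sv <- dataset[[1]]$seq$vocab
  rv <- dataset[[1]]$struct$vocab
  set.seed(tcfg$seed)
  model <- init_denoiser(dcfg, sv, rv,
                         seed = as.integer(stats::runif(1, 1, 2^30)))
  S1 <- vapply(dataset, function(x) x$seq$tokens, integer(np))
  R1 <- vapply(dataset, function(x) x$struct$tokens, integer(np))
  n <- length(dataset)
  adam_m <- .tree_map(function(x) x * 0, model$params)
  adam_v <- .tree_map(function(x) x * 0, model$params)
  step <- 0L
  b1 <- 0.9
  b2 <- 0.999
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      loss_seq = numeric(0), loss_struct = numeric(0))
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    ep_ce <- c(seq = 0, struct = 0)
    ep_cnt <- c(seq = 0L, struct = 0L)
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      bs <- length(idx)
      ts <- stats::runif(bs)
      tr <- if (tcfg$per_track_times) stats::runif(bs) else ts
      S <- .corrupt_matrix(S1[, idx, drop = FALSE], rep(ts, each = np), sv$mask_index)
      R <- .corrupt_matrix(R1[, idx, drop = FALSE], rep(tr, each = np), rv$mask_index)
      t_in <- if (tcfg$per_track_times) (ts + tr) / 2 else ts
      fw <- .den_forward(model, S, R, t_in, need_cache = TRUE)
      tgt <- function(tok1, tokt, probs, mask_index) {
        t1 <- as.vector(tok1)
        sel <- if (tcfg$loss_positions == "masked_only")
          as.vector(tokt) == mask_index else rep(TRUE, length(t1))
        cnt <- sum(sel)
        dl <- probs
        dl[cbind(seq_along(t1), t1)] <- dl[cbind(seq_along(t1), t1)] - 1
        dl[!sel, ] <- 0
        ce <- -sum(log(pmax(probs[cbind(which(sel), t1[sel])], 1e-12)))
        list(dl = if (cnt > 0) dl / cnt else dl * 0, ce = ce, cnt = cnt)
      }
      ls <- tgt(S1[, idx, drop = FALSE], S, fw$ps, sv$mask_index)
      lr_ <- tgt(R1[, idx, drop = FALSE], R, fw$pr, rv$mask_index)
      ep_ce <- ep_ce + c(ls$ce, lr_$ce)
      ep_cnt <- ep_cnt + c(ls$cnt, lr_$cnt)
      grads <- .den_backward(model, fw$cache, ls$dl, lr_$dl)
      step <- step + 1L
      lr_t <- tcfg$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      adam_m <- .tree_map(function(m, g) b1 * m + (1 - b1) * g, adam_m, grads)
      adam_v <- .tree_map(function(v, g) b2 * v + (1 - b2) * g * g, adam_v, grads)
      model$params <- .tree_map(function(p, m, v) p - lr_t * m / (sqrt(v) + 1e-8),
                                model$params, adam_m, adam_v)
    }
    trace <- rbind(trace, data.frame(
      epoch = ep,
      loss = ep_ce["seq"] / max(1L, ep_cnt["seq"]) +
        ep_ce["struct"] / max(1L, ep_cnt["struct"]),
      loss_seq = ep_ce["seq"] / max(1L, ep_cnt["seq"]),
      loss_struct = ep_ce["struct"] / max(1L, ep_cnt["struct"])))
  }
  rownames(trace) <- NULL
  list(model = model, trace = trace)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a denoiser checkpoint
#'
#' One binary file holding a header (format version, architecture config,
#' vocabularies) plus the parameter tree.
#'
#' @param model An `mf_denoiser_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mf_denoiser_model"))
  saveRDS(list(header = list(format = "maskflow-checkpoint-1",
                             config = model$config,
                             seq_vocab = model$seq_vocab,
                             struct_vocab = model$struct_vocab),
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$header$format, "maskflow-checkpoint-1"))
    stop("not a maskflow checkpoint: ", path)
  structure(list(config = x$header$config, params = x$params,
                 seq_vocab = x$header$seq_vocab,
                 struct_vocab = x$header$struct_vocab),
            class = "mf_denoiser_model")
}
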
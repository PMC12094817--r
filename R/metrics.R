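#' Generation entropy of a sampling trajectory
#'
#' Sum over positions and both tracks of the Shannon entropy (natural log) of
#' the predicted distribution in force at each position's final unmasking
#' event, divided by N. A confidence measure of the sampler: a denoiser
#' concentrated on point masses yields entropy 0. Conditioning positions were
#' given, not generated, and contribute zero; a non-conditioning position
#' without an unmasking event is an error.
#'
#' @param trajectory An `mf_trajectory` from [euler_sample()].
#' @return Per-residue generation entropy (nats).
#' @export
generation_entropy <- function(trajectory) {
  stopifnot(inherits(trajectory, "mf_trajectory"))
  steps <- trajectory$steps
  np <- length(steps[[1]]$seq_tokens)
  cond <- trajectory$cond
  final <- steps[[length(steps)]]
  masks <- c(seq = trajectory$seq_vocab$mask_index,
             struct = trajectory$struct_vocab$mask_index)
  ent <- list(seq = rep(NA_real_, np), struct = rep(NA_real_, np))
  prev <- list(seq = ifelse(cond[, "seq"], final$seq_tokens, masks["seq"]),
               struct = ifelse(cond[, "struct"], final$struct_tokens, masks["struct"]))
  for (st in steps) {
    for (nm in c("seq", "struct")) {
      cur <- st[[paste0(nm, "_tokens")]]
      ev <- prev[[nm]] == masks[nm] & cur != masks[nm]
      if (any(ev)) {
        f <- st[[paste0("f_", nm)]]
        ent[[nm]][ev] <- .row_entropy(f[ev, , drop = FALSE])
      }
      prev[[nm]] <- cur
    }
  }
  for (nm in c("seq", "struct")) {
    missing <- is.na(ent[[nm]]) & !cond[, nm]
    if (any(missing))
      stop(sum(missing), " ", nm, " positions were never unmasked")
  }
  (sum(ent$seq, na.rm = TRUE) + sum(ent$struct, na.rm = TRUE)) / np
}

#' Masked-token prediction accuracy across interpolation times
#'
#' For each time on the grid, corrupts the held-out proteins to x_t, queries
#' the denoiser once, takes the per-position argmax at masked positions and
#' reports the fraction of correctly recovered tokens per track. More context
#' (larger t) should make prediction easier.
#'
#' @param denoiser A denoiser as accepted by [euler_sample()].
#' @param dataset Nonempty list of fully observed `mf_protein` objects.
#' @param t_grid Times in (0, 1).
#' @param seed Optional seed for the corruption draws.
#' @return A data.frame with columns `t`, `track`, `accuracy`, `n_masked`.
#' @export
unmasking_accuracy <- function(denoiser, dataset, t_grid, seed = NULL) {
  if (length(dataset) == 0) stop("dataset is empty")
  if (length(t_grid) == 0) stop("t_grid is empty")
  if (any(t_grid <= 0 | t_grid >= 1)) stop("t_grid must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sv <- dataset[[1]]$seq$vocab
  rv <- dataset[[1]]$struct$vocab
  np <- length(dataset[[1]])
  eng <- .as_engine_denoiser(denoiser, sv, rv)
  S1 <- vapply(dataset, function(x) x$seq$tokens, integer(np))
  R1 <- vapply(dataset, function(x) x$struct$tokens, integer(np))
  out <- list()
  for (t in t_grid) {
    S <- .corrupt_matrix(S1, t, sv$mask_index)
    R <- .corrupt_matrix(R1, t, rv$mask_index)
    f <- eng(S, R, t)
    acc <- function(pred, tok_t, tok_1, mask_index) {
      is_m <- as.vector(tok_t) == mask_index
      hit <- max.col(pred, ties.method = "first")[is_m] == as.vector(tok_1)[is_m]
      c(accuracy = mean(hit), n_masked = sum(is_m))
    }
    a_s <- acc(f$seq, S, S1, sv$mask_index)
    a_r <- acc(f$struct, R, R1, rv$mask_index)
    out[[length(out) + 1L]] <- data.frame(
      t = t, track = c("sequence", "structure"),
      accuracy = c(a_s["accuracy"], a_r["accuracy"]),
      n_masked = c(a_s["n_masked"], a_r["n_masked"]))
  }
  do.call(rbind, out)
}

#' Native sequence recovery rate
#'
#' Fraction of positions whose predicted token matches the reference token.
#'
#' @param predicted,reference Two mask-free `mf_track`s of equal length.
#' @return Real in `[0, 1]`.
#' @export
recovery_rate <- function(predicted, reference) {
  stopifnot(inherits(predicted, "mf_track"), inherits(reference, "mf_track"))
  if (length(predicted$tokens) != length(reference$tokens))
    stop("tracks differ in length")
  if (has_mask(predicted) || has_mask(reference))
    stop("recovery is defined over mask-free tracks")
  mean(predicted$tokens == reference$tokens)
}

#' Map sampled token matrices to enumerated outcome indices
#'
#' @param joint An `mf_joint`.
#' @param seq_mat,struct_mat n x N integer token matrices (rows = samples).
#' @return Integer outcome indices into `joint$p`.
#' @export
outcome_index <- function(joint, seq_mat, struct_mat) {
  np <- joint$length
  krm1 <- max(joint$struct_tokens)
  kp <- max(joint$seq_tokens) * krm1
  pair <- (seq_mat - 1L) * krm1 + (struct_mat - 1L)  # 0-based pair codes
  as.integer(pair %*% kp^(np - seq_len(np)) + 1L)
}

#' Total-variation distance between empirical counts and an exact joint
#'
#' `0.5 * sum(|phat - p|)` over the enumerated outcome space.
#'
#' @param counts Integer vector of outcome counts aligned with `joint$p`
#'   (e.g. from `tabulate(outcome_index(...), nbins = length(joint$p))`).
#' @param joint An `mf_joint`, or a bare probability vector of equal length.
#' @return Real in `[0, 1]`.
#' @export
tv_distance <- function(counts, joint) {
  p <- if (inherits(joint, "mf_joint")) joint$p else as.numeric(joint)
  if (length(counts) != length(p))
    stop("counts and joint live on different outcome spaces")
  if (sum(counts) <= 0) stop("counts are empty")
  0.5 * sum(abs(counts / sum(counts) - p / sum(p)))
}

#' Token-space self-consistency of sampled proteins
#'
#' Mean per-position agreement between each sample's structure track and the
#' co-fold oracle's maximum-a-posteriori structure for its sequence: the
#' token-space analog of folding the designed sequence back and comparing.
#'
#' @param samples Nonempty list of fully observed `mf_protein`s.
#' @param world An `mf_toy_world`.
#' @return Mean agreement in `[0, 1]`; per-sample values as attribute
#'   `"per_sample"`.
#' @export
self_consistency <- function(samples, world) {
  if (length(samples) == 0) stop("no samples")
  per <- vapply(samples, function(x) {
    if (has_mask(x$seq) || has_mask(x$struct)) stop("samples must be mask-free")
    mean(cofold_oracle(x$seq, world)$tokens == x$struct$tokens)
  }, numeric(1))
  structure(mean(per), per_sample = per)
}

#' A named metric value with sample size and dispersion
#'
#' @param name Metric name.
#' @param value Numeric value.
#' @param n Sample count behind the value.
#' @param dispersion Standard error (or other nonnegative spread measure).
#' @param config Optional list snapshot of the configuration that produced it.
#' @return An object of class `mf_metric`, also a one-row data.frame via
#'   [as.data.frame.mf_metric()].
#' @export
metric_report <- function(name, value, n, dispersion = NA_real_, config = NULL) {
  stopifnot(n >= 1, is.na(dispersion) || dispersion >= 0)
  structure(list(name = name, value = value, n = as.integer(n),
                 dispersion = dispersion, config = config),
            class = "mf_metric")
}

#' @export
print.mf_metric <- function(x, ...) {
  cat(sprintf("<mf_metric> %s = %.6g (n = %d, dispersion = %.3g)\n",
              x$name, x$value, x$n, x$dispersion))
  invisible(x)
}

#' @rdname metric_report
#' @param x An `mf_metric`.
#' @param ... Unused.
#' @export
as.data.frame.mf_metric <- function(x, ...) {
  data.frame(name = x$name, value = x$value, n = x$n, dispersion = x$dispersion,
             stringsAsFactors = FALSE)
}
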
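# reproducible run-level entry points tying the modules together; a thin
# command-line wrapper over these lives in inst/cli/maskflow

.msg <- function(...) message("[maskflow] ", ...)

#' Generate a toy-world dataset on disk
#'
#' Writes `dataset.tsv` (token table with record column), `dataset.fasta`
#' (sequence tracks) and `world.yaml` (the generating parameters) to
#' `out_dir`. Fully determined by `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param world An `mf_toy_world`.
#' @param n Number of proteins.
#' @param length Residue count N.
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
run_generate_data <- function(out_dir, world = toy_world_params(), n = 100L,
                              length = 16L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- sample_toy_proteins(world, n, length, seed = seed)
  paths <- list(
    dataset = file.path(out_dir, "dataset.tsv"),
    fasta = file.path(out_dir, "dataset.fasta"),
    world = file.path(out_dir, "world.yaml"))
  write_token_dataset(proteins, paths$dataset, seed = seed, config = world)
  write_fasta(proteins, paths$fasta, seed = seed, config = world)
  write_world_params(world, paths$world, seed = seed)
  .msg("wrote ", n, " proteins of length ", length, " to ", out_dir)
  invisible(paths)
}

#' Train a denoiser from a dataset directory
#'
#' Reads `dataset.tsv` and `world.yaml` (for the vocabularies) from
#' `data_dir`, trains the toy transformer and writes `checkpoint.rds` and
#' `loss_trace.csv` to `out_dir`.
#'
#' @param data_dir Directory produced by [run_generate_data()].
#' @param out_dir Output directory.
#' @param dcfg An `mf_denoiser_config`.
#' @param tcfg An `mf_train_config` (its seed governs the run).
#' @return Invisibly, a list with the trained model, trace and paths.
#' @export
run_train <- function(data_dir, out_dir, dcfg = denoiser_config(),
                      tcfg = train_config()) {
  ds_path <- file.path(data_dir, "dataset.tsv")
  if (!file.exists(ds_path)) stop("no dataset.tsv under ", data_dir)
  world <- read_world_params(file.path(data_dir, "world.yaml"))
  dataset <- read_token_dataset(ds_path, world$seq_vocab, world$struct_vocab)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- train_denoiser(dataset, dcfg, tcfg)
  ck <- file.path(out_dir, "checkpoint.rds")
  tr <- file.path(out_dir, "loss_trace.csv")
  save_checkpoint(fit$model, ck)
  write_loss_trace(fit$trace, tr, seed = tcfg$seed,
                   config = list(dcfg = dcfg, tcfg = tcfg))
  .msg("trained ", tcfg$epochs, " epochs on ", length(dataset),
       " proteins; final loss ", round(fit$trace$loss[nrow(fit$trace)], 4))
  invisible(list(model = fit$model, trace = fit$trace,
                 paths = list(checkpoint = ck, trace = tr)))
}

#' Sample proteins from a trained checkpoint
#'
#' Builds the task's starting state and conditioning flags, Euler-samples `n`
#' proteins, and writes `samples.tsv`, `samples.fasta` and (for the first
#' sample) `trajectory.jsonl` to `out_dir`. Conditioning tokens are verified
#' unchanged before anything is written.
#'
#' @param checkpoint Path to a checkpoint from [run_train()].
#' @param out_dir Output directory.
#' @param task An `mf_task` (default unconditional).
#' @param length Residue count N.
#' @param n Number of samples.
#' @param config An `mf_sampler_config`; its seed governs the run.
#' @return Invisibly, a list with token matrices, entropies and paths.
#' @export
run_sample <- function(checkpoint, out_dir, task = task_spec("unconditional"),
                       length = 16L, n = 10L, config = sampler_config()) {
  model <- load_checkpoint(checkpoint)
  cm <- make_condition_mask(task, length, model$seq_vocab, model$struct_vocab)
  if (cm$x0$seq$vocab$size != model$seq_vocab$size ||
      cm$x0$struct$vocab$size != model$struct_vocab$size)
    stop("task vocabularies do not match the checkpoint's vocabulary sizes")
  den <- make_model_denoiser(model)
  first <- euler_sample(den, cm$x0, cm$cond, config)
  res <- if (n > 1L) {
    more <- euler_sample_batch(den, n - 1L, cm$x0, cm$cond,
                               utils::modifyList(config, list(seed = config$seed + 1L)))
    list(seq = rbind(matrix(first$x1$seq$tokens, 1), more$seq),
         struct = rbind(matrix(first$x1$struct$tokens, 1), more$struct),
         gen_entropy = c(first$gen_entropy, more$gen_entropy),
         remask_events = first$remask_events + more$remask_events)
  } else {
    list(seq = matrix(first$x1$seq$tokens, 1),
         struct = matrix(first$x1$struct$tokens, 1),
         gen_entropy = first$gen_entropy, remask_events = first$remask_events)
  }
  # the task contract: given tokens must be echoed verbatim
  for (i in seq_len(nrow(res$seq))) {
    stopifnot(all(res$seq[i, cm$cond[, "seq"]] ==
                    cm$x0$seq$tokens[cm$cond[, "seq"]]),
              all(res$struct[i, cm$cond[, "struct"]] ==
                    cm$x0$struct$tokens[cm$cond[, "struct"]]))
  }
  proteins <- lapply(seq_len(nrow(res$seq)), function(i) {
    protein_tokens(token_track(res$seq[i, ], model$seq_vocab, "sequence"),
                   token_track(res$struct[i, ], model$struct_vocab, "structure"))
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(samples = file.path(out_dir, "samples.tsv"),
                fasta = file.path(out_dir, "samples.fasta"),
                trajectory = file.path(out_dir, "trajectory.jsonl"))
  snap <- list(task = task$mode, config = config, length = length, n = n)
  write_token_dataset(proteins, paths$samples, seed = config$seed, config = snap)
  write_fasta(proteins, paths$fasta, seed = config$seed, config = snap)
  write_trajectory(first$trajectory, paths$trajectory, seed = config$seed)
  .msg("sampled ", n, " proteins (", task$mode, ", ", config$strategy,
       ", steps = ", config$steps, ")")
  invisible(c(res, list(proteins = proteins, paths = paths)))
}

#' Evaluate samples against the generating world
#'
#' Reads a sample token dataset and world parameters, computes token-space
#' self-consistency (via the co-fold oracle), the mean per-position marginal
#' total-variation distance against the exact forward-computed marginals, and
#' mean generation entropy if entropies are supplied; writes `metrics.csv`.
#'
#' @param samples_path Token dataset written by [run_sample()].
#' @param world_path `world.yaml` of the generating world.
#' @param out_dir Output directory.
#' @param gen_entropy Optional per-sample generation entropies.
#' @param seed Recorded in the metric snapshot.
#' @return Invisibly, the list of `mf_metric` objects.
#' @export
run_evaluate <- function(samples_path, world_path, out_dir,
                         gen_entropy = NULL, seed = NA) {
  world <- read_world_params(world_path)
  samples <- read_token_dataset(samples_path, world$seq_vocab, world$struct_vocab)
  np <- length(samples[[1]])
  n <- length(samples)
  sc <- self_consistency(samples, world)
  marg <- position_marginals(world, np)
  S <- t(vapply(samples, function(x) x$seq$tokens, integer(np)))
  R <- t(vapply(samples, function(x) x$struct$tokens, integer(np)))
  mtv <- marginal_tv(S, R, marg)
  metrics <- list(
    metric_report("self_consistency", as.numeric(sc), n,
                  stats::sd(attr(sc, "per_sample")) / sqrt(n)),
    metric_report("marginal_tv", mtv, n))
  if (!is.null(gen_entropy))
    metrics <- c(metrics, list(metric_report(
      "generation_entropy", mean(gen_entropy), length(gen_entropy),
      stats::sd(gen_entropy) / sqrt(length(gen_entropy)))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"), seed = seed,
                    config = list(samples = basename(samples_path), n = n))
  .msg("evaluated ", n, " samples: self-consistency ", round(as.numeric(sc), 3),
       ", marginal TV ", round(mtv, 3))
  invisible(metrics)
}

#' Mean per-position marginal total-variation distance
#'
#' Compares empirical per-position token frequencies of sampled tracks with
#' exact marginals, averaged over positions and the two tracks.
#'
#' @param seq_mat,struct_mat n x N token-id matrices (rows = samples).
#' @param marginals As returned by [position_marginals()].
#' @return Mean TV in `[0, 1]`.
#' @export
marginal_tv <- function(seq_mat, struct_mat, marginals) {
  one <- function(mat, marg) {
    np <- ncol(mat)
    k <- ncol(marg)
    tvs <- vapply(seq_len(np), function(i) {
      emp <- tabulate(mat[, i], nbins = k) / nrow(mat)
      0.5 * sum(abs(emp - marg[i, ]))
    }, numeric(1))
    mean(tvs)
  }
  (one(seq_mat, marginals$seq) + one(struct_mat, marginals$struct)) / 2
}
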
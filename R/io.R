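# artifact serialization: token tables (TSV), FASTA, trajectories (JSON
# lines), world params (YAML). Every non-FASTA artifact starts with '#'
# header lines recording package version, seed and a config hash; FASTA
# records carry the same metadata in their description lines.

# 32-bit FNV-1a over a canonical text rendering; multiplication split into
# 16-bit halves to stay exact in doubles
.fnv1a <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31) , b) + (h %/% 2^31) * 2^31  # xor low bits
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Short stable hash of a configuration object
#'
#' @param x Any R object (rendered via `deparse`).
#' @return 8-hex-digit string.
#' @export
config_hash <- function(x) .fnv1a(deparse(x, control = "all"))

.pkg_version <- function() as.character(utils::packageVersion("maskflow"))

.artifact_header <- function(seed = NA, config = NULL) {
  c(paste0("# maskflow ", .pkg_version()),
    paste0("# seed: ", seed),
    paste0("# config: ", config_hash(config)))
}

.write_table_artifact <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.artifact_header(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.track_labels <- function(track) track$vocab$symbols[track$tokens]

#' Write / read a single protein as a token table
#'
#' Tab-separated columns `position` (0-based), `seq_token`, `struct_token`;
#' masks rendered as `-`.
#'
#' @param x An `mf_protein`.
#' @param path Output path.
#' @param seed,config Recorded in the artifact header.
#' @export
write_token_table <- function(x, path, seed = NA, config = NULL) {
  stopifnot(inherits(x, "mf_protein"))
  df <- data.frame(position = seq_len(length(x)) - 1L,
                   seq_token = .track_labels(x$seq),
                   struct_token = .track_labels(x$struct))
  .write_table_artifact(df, path, seed, config)
}

.labels_to_ids <- function(labels, vocab, what) {
  ids <- match(labels, vocab$symbols)
  if (anyNA(ids)) stop("unknown ", what, " token label(s): ",
                       paste(unique(labels[is.na(ids)]), collapse = ", "))
  ids
}

#' @rdname write_token_table
#' @param seq_vocab,struct_vocab Vocabularies used to decode token labels.
#' @export
read_token_table <- function(path, seq_vocab = seq_vocabulary(),
                             struct_vocab = struct_vocabulary()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df <- df[order(df$position), ]
  protein_tokens(
    token_track(.labels_to_ids(df$seq_token, seq_vocab, "sequence"),
                seq_vocab, "sequence"),
    token_track(.labels_to_ids(df$struct_token, struct_vocab, "structure"),
                struct_vocab, "structure"))
}

#' Write / read a multi-protein token dataset
#'
#' As [write_token_table()] with a leading 0-based `record` column.
#'
#' @param proteins List of `mf_protein`s.
#' @param path Output path.
#' @param seed,config Recorded in the artifact header.
#' @export
write_token_dataset <- function(proteins, path, seed = NA, config = NULL) {
  stopifnot(length(proteins) >= 1)
  dfs <- lapply(seq_along(proteins), function(i) {
    x <- proteins[[i]]
    data.frame(record = i - 1L, position = seq_len(length(x)) - 1L,
               seq_token = .track_labels(x$seq),
               struct_token = .track_labels(x$struct))
  })
  .write_table_artifact(do.call(rbind, dfs), path, seed, config)
}

#' @rdname write_token_dataset
#' @param seq_vocab,struct_vocab Vocabularies used to decode token labels.
#' @export
read_token_dataset <- function(path, seq_vocab = seq_vocabulary(),
                               struct_vocab = struct_vocabulary()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$record), function(d) {
    d <- d[order(d$position), ]
    protein_tokens(
      token_track(.labels_to_ids(d$seq_token, seq_vocab, "sequence"),
                  seq_vocab, "sequence"),
      token_track(.labels_to_ids(d$struct_token, struct_vocab, "structure"),
                  struct_vocab, "structure"))
  })
}

#' Export sequence tracks to FASTA
#'
#' Toy sequence tokens map to amino-acid one-letter codes (the vocabulary's
#' own symbols). Record descriptions carry the seed and config hash. Requires
#' the Biostrings package.
#'
#' @param tracks List of sequence `mf_track`s (or `mf_protein`s, whose
#'   sequence tracks are taken).
#' @param path Output path (60-column wrapping).
#' @param seed,config Recorded in the record descriptions.
#' @export
write_fasta <- function(tracks, path, seed = NA, config = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA export requires the Biostrings package")
  tracks <- lapply(tracks, function(x) if (inherits(x, "mf_protein")) x$seq else x)
  seqs <- vapply(tracks, function(tr) paste(.track_labels(tr), collapse = ""),
                 character(1))
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- sprintf("protein_%d maskflow=%s seed=%s config=%s",
                       seq_along(seqs) - 1L, .pkg_version(), seed,
                       config_hash(config))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @param vocab Sequence vocabulary used to decode letters.
#' @export
read_fasta <- function(path, vocab = seq_vocabulary()) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA import requires the Biostrings package")
  ss <- Biostrings::readAAStringSet(path)
  lapply(as.character(ss), function(s) {
    token_track(.labels_to_ids(strsplit(s, "")[[1]], vocab, "sequence"),
                vocab, "sequence")
  })
}

#' Write a sampling trajectory as line-delimited JSON
#'
#' After '#' header lines, one JSON object per step: global step index and
#' time, the token ids of both tracks after the step, and (for active tracks)
#' the probability each position's sampled token had under its transition
#' kernel.
#'
#' @param trajectory An `mf_trajectory`.
#' @param path Output path.
#' @param seed Recorded in the header.
#' @export
write_trajectory <- function(trajectory, path, seed = NA) {
  stopifnot(inherits(trajectory, "mf_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.artifact_header(seed, trajectory$config), con)
  for (st in trajectory$steps) {
    rec <- list(step = st$step_index, t = st$t, active = as.list(st$active),
                seq_tokens = st$seq_tokens, struct_tokens = st$struct_tokens)
    if (!is.null(st$p_sampled_seq)) rec$p_sampled_seq <- st$p_sampled_seq
    if (!is.null(st$p_sampled_struct)) rec$p_sampled_struct <- st$p_sampled_struct
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10), con)
  }
  invisible(path)
}

#' Write / read toy-world parameters as YAML
#'
#' @param world An `mf_toy_world`.
#' @param path Output path.
#' @param seed Recorded in the header.
#' @export
write_world_params <- function(world, path, seed = NA) {
  stopifnot(inherits(world, "mf_toy_world"))
  obj <- list(n_hidden = world$n_hidden,
              n_seq_tokens = ncol(world$emit_seq),
              n_struct_tokens = ncol(world$emit_struct),
              trans = apply(world$trans, 1, as.numeric, simplify = FALSE),
              emit_seq = apply(world$emit_seq, 1, as.numeric, simplify = FALSE),
              emit_struct = apply(world$emit_struct, 1, as.numeric, simplify = FALSE),
              init = as.numeric(world$init))
  txt <- yaml::as.yaml(obj, precision = 15)
  writeLines(c(.artifact_header(seed, obj), txt), path)
  invisible(path)
}

#' @rdname write_world_params
#' @export
read_world_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  obj <- yaml::yaml.load(paste(lines, collapse = "\n"))
  as_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  toy_world_params(n_hidden = obj$n_hidden,
                   n_seq_tokens = obj$n_seq_tokens,
                   n_struct_tokens = obj$n_struct_tokens,
                   trans = as_mat(obj$trans),
                   emit_seq = as_mat(obj$emit_seq),
                   emit_struct = as_mat(obj$emit_struct),
                   init = as.numeric(obj$init))
}

#' Write metric reports as a flat CSV
#'
#' @param metrics List of `mf_metric` objects.
#' @param path Output path.
#' @param seed,config Recorded in the artifact header.
#' @export
write_metrics_csv <- function(metrics, path, seed = NA, config = NULL) {
  df <- do.call(rbind, lapply(metrics, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.artifact_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a training loss trace as CSV
#'
#' @param trace Data frame from [train_denoiser()].
#' @param path Output path.
#' @param seed,config Recorded in the artifact header.
#' @export
write_loss_trace <- function(trace, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.artifact_header(seed, config), con)
  utils::write.csv(trace, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
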
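#' Task specification for conditional co-design
#'
#' The four task modes are expressed purely by which tokens start observed:
#' unconditional (nothing given), folding (sequence given, structure
#' generated), inverse folding (structure given, sequence generated) and motif
#' scaffolding (both tracks given on a subset of residues).
#'
#' @param mode One of `"unconditional"`, `"folding"`, `"inverse_folding"`,
#'   `"motif_scaffolding"`.
#' @param given_seq Optional `mf_track` (sequence modality).
#' @param given_struct Optional `mf_track` (structure modality).
#' @param motif_positions Optional integer vector of 0-based residue indices
#'   (motif scaffolding only).
#' @return An object of class `mf_task`.
#' @export
task_spec <- function(mode = c("unconditional", "folding", "inverse_folding",
                               "motif_scaffolding"),
                      given_seq = NULL, given_struct = NULL,
                      motif_positions = NULL) {
  mode <- match.arg(mode)
  if (mode == "folding" && is.null(given_seq))
    stop("folding requires given_seq")
  if (mode == "inverse_folding" && is.null(given_struct))
    stop("inverse_folding requires given_struct")
  if (mode == "motif_scaffolding" &&
      (is.null(given_seq) || is.null(given_struct) || is.null(motif_positions)))
    stop("motif_scaffolding requires given_seq, given_struct and motif_positions")
  structure(list(mode = mode, given_seq = given_seq, given_struct = given_struct,
                 motif_positions = if (!is.null(motif_positions)) as.integer(motif_positions)),
            class = "mf_task")
}

#' Build the initial state and conditioning flags for a task
#'
#' Returns the partially masked starting protein x0 and per-position,
#' per-track boolean flags marking conditioning tokens, which the sampler
#' never resamples and never re-masks.
#'
#' @param spec An `mf_task`.
#' @param length Protein length N.
#' @param seq_vocab,struct_vocab Vocabularies used for fully masked tracks
#'   when a track is not given.
#' @return A list with `x0` (an `mf_protein`) and `cond` (an N x 2 logical
#'   matrix with columns `seq`, `struct`).
#' @export
make_condition_mask <- function(spec, length,
                                seq_vocab = seq_vocabulary(),
                                struct_vocab = struct_vocabulary()) {
  stopifnot(inherits(spec, "mf_task"))
  n <- as.integer(length)
  check_given <- function(track, modality) {
    if (length(track$tokens) != n)
      stop("given ", modality, " track has length ", length(track$tokens),
           " but N = ", n)
    if (has_mask(track))
      stop("given ", modality, " track may not contain mask tokens")
    track
  }
  if (!is.null(spec$given_seq)) seq_vocab <- spec$given_seq$vocab
  if (!is.null(spec$given_struct)) struct_vocab <- spec$given_struct$vocab
  cond <- matrix(FALSE, n, 2, dimnames = list(NULL, c("seq", "struct")))
  s <- masked_track(n, seq_vocab, "sequence")
  r <- masked_track(n, struct_vocab, "structure")
  if (spec$mode == "folding") {
    s <- check_given(spec$given_seq, "sequence")
    cond[, "seq"] <- TRUE
  } else if (spec$mode == "inverse_folding") {
    r <- check_given(spec$given_struct, "structure")
    cond[, "struct"] <- TRUE
  } else if (spec$mode == "motif_scaffolding") {
    gs <- check_given(spec$given_seq, "sequence")
    gr <- check_given(spec$given_struct, "structure")
    pos <- spec$motif_positions
    if (any(pos < 0L) || any(pos >= n)) stop("motif positions out of range [0, N)")
    idx <- pos + 1L
    st <- s$tokens; st[idx] <- gs$tokens[idx]
    rt <- r$tokens; rt[idx] <- gr$tokens[idx]
    s <- token_track(st, seq_vocab, "sequence")
    r <- token_track(rt, struct_vocab, "structure")
    cond[idx, ] <- TRUE
  }
  list(x0 = protein_tokens(s, r), cond = cond)
}

#' Which tracks a scheduling strategy updates at a step
#'
#' Synchronous updates both tracks every step. Asynchronous alternates
#' strictly, sequence on even (0-based) steps, structure on odd steps.
#' `sequence_first` runs sequence only over the first half of the step budget
#' and structure over the second half; `structure_first` is the mirror image.
#' Inactive tracks are frozen (identity kernel); each track's internal time
#' grid runs over its own active steps so it always reaches t = 1.
#'
#' @param strategy Strategy name.
#' @param step_index 0-based global step index.
#' @param steps Total number of steps.
#' @return Character subset of `c("sequence", "structure")`.
#' @export
active_tracks <- function(strategy, step_index, steps) {
  if (step_index < 0L || step_index >= steps) stop("step_index out of range")
  switch(strategy,
    synchronous = c("sequence", "structure"),
    asynchronous = if (step_index %% 2L == 0L) "sequence" else "structure",
    sequence_first = if (step_index < steps %/% 2L) "sequence" else "structure",
    structure_first = if (step_index < steps %/% 2L) "structure" else "sequence",
    stop("unknown strategy '", strategy, "'")
  )
}

# 0-based global step indices at which each track is active
.track_schedule <- function(strategy, steps) {
  ks <- seq_len(steps) - 1L
  act <- lapply(ks, function(k) active_tracks(strategy, k, steps))
  list(sequence = ks[vapply(act, function(a) "sequence" %in% a, logical(1))],
       structure = ks[vapply(act, function(a) "structure" %in% a, logical(1))])
}

#' Parse motif positions from a compact range string
#'
#' Accepts comma-separated 0-based indices and ranges, e.g. `"2-3,7"`.
#'
#' @param text The range string.
#' @return Sorted integer vector of 0-based positions.
#' @export
parse_motif_positions <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  pos <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
      if (length(ab) != 2L || anyNA(ab) || ab[1] > ab[2])
        stop("bad motif range '", p, "'")
      ab[1]:ab[2]
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop("bad motif position '", p, "'")
      v
    }
  }))
  sort(unique(pos))
}
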
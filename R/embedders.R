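# The three lightweight embedders of the model zoo: fixed-length one-hot,
# MSA-aligned one-hot (new sequences are aligned to the training profile
# first), and k-mer counts.

# ---- fixed-length one-hot ----------------------------------------------------

#' One-hot encode fixed-length sequences
#'
#' 20 binary indicator channels per position: entry 1 at channel
#' \code{20*(pos-1) + alphabet_index}. Channel names follow
#' \code{"pos<i>_<aa>"}. The unknown residue \code{'X'} yields an all-zero
#' 20-channel block at its position; gaps are rejected (use the aligned
#' embedder for gapped input). The encoding is a bijection between X-free
#' fixed-length sequences and its image; [onehot_decode()] inverts it.
#'
#' @param sequences A [protein_sequence_set()], all members one length,
#'   gap-free.
#' @return Numeric matrix, one row per sequence (\code{n x 20L}), row names =
#'   sequence ids.
#' @export
onehot_encode <- function(sequences) {
  sequences <- as_sequence_set(sequences)
  if (length(sequences) == 0L) pz_stop("validation", "no sequences to encode")
  res <- sequence_residues(sequences)
  if (!uniform_length(sequences))
    pz_stop("fixed_length", sprintf(
      "one-hot encoding requires one fixed length (found %s)",
      paste(unique(nchar(res)), collapse = ", ")))
  if (any(grepl(PZ_GAP, res, fixed = TRUE)))
    pz_stop("validation", "gapped sequences cannot be one-hot encoded; use the aligned one-hot embedder")
  L <- nchar(res[1])
  mat <- matrix(0, length(res), 20L * L,
                dimnames = list(sequence_ids(sequences),
                                paste0("pos", rep(seq_len(L), each = 20L), "_",
                                       rep(PZ_CANONICAL, L))))
  for (i in seq_along(res)) {
    chars <- split_chars(res[i])
    idx <- PZ_CANONICAL_INDEX[chars]          # NA at 'X'
    on <- which(!is.na(idx))
    mat[i, 20L * (on - 1L) + idx[on]] <- 1
  }
  mat
}

#' Decode a fixed-length one-hot matrix
#'
#' Inverse of [onehot_encode()]: each 20-channel block with a single 1 maps
#' back to its residue; an all-zero block decodes to \code{'X'}.
#'
#' @param mat Matrix produced by [onehot_encode()] (or one row of it).
#' @return Character vector of residue strings, one per row.
#' @export
onehot_decode <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  if (ncol(mat) %% 20L != 0L)
    pz_stop("validation", "column count is not a multiple of 20")
  L <- ncol(mat) %/% 20L
  apply(mat, 1L, function(row) {
    blocks <- matrix(row, nrow = 20L)
    paste(apply(blocks, 2L, function(b) {
      on <- which(b != 0)
      if (length(on) == 0L) PZ_UNKNOWN
      else if (length(on) == 1L) PZ_CANONICAL[on]
      else pz_stop("validation", "block with multiple set channels is not one-hot")
    }), collapse = "")
  })
}

#' Fixed-length one-hot embedder
#'
#' Model-zoo wrapper around [onehot_encode()]. Fitting learns the fixed
#' length from the training sequences; transform enforces it.
#'
#' @return An unfitted model with \code{requires_fixed_length} capability.
#' @export
onehot_embedder <- function() {
  new_protein_model("onehot_embedder", list(),
                    model_capabilities(requires_fixed_length = TRUE))
}

#' @export
fit_state.onehot_embedder <- function(model, bundle) {
  if (length(bundle$sequences) == 0L)
    pz_stop("validation", "cannot fit on an empty sequence set")
  list(length = seq_width(bundle$sequences[[1]]))
}

#' @export
transform_state.onehot_embedder <- function(model, sequences) {
  widths <- nchar(sequence_residues(sequences))
  if (any(widths != model$state$length))
    pz_stop("fixed_length", sprintf(
      "sequences must have the fitted length %d", model$state$length))
  onehot_encode(sequences)
}

# ---- profile alignment + aligned one-hot ------------------------------------

#' Align a sequence to a column profile
#'
#' Global dynamic program over (query positions x profile columns). A query
#' residue placed in column \eqn{j} scores the log-odds
#' \eqn{\ln(f_j(a) + \epsilon) - \ln q(a)} against a uniform background
#' \eqn{q = 1/20}; a column left empty emits \code{'-'} and pays the deletion
#' penalty; a query residue consumed between columns (an insertion) pays the
#' insertion penalty and does not appear in the output, so the output width
#' always equals the profile width. Traceback is deterministic with tie
#' preference match > delete > insert. \code{'X'} residues take match score 0
#' (uninformative).
#'
#' @param seq Gap-free, non-empty [protein_sequence()].
#' @param profile A \code{column_profile}.
#' @param deletion_penalty,insertion_penalty Linear penalties (defaults
#'   \code{-1.5}).
#' @param epsilon Frequency floor inside the log (default \code{1e-9}).
#' @return Gapped string of length \code{profile$width}, with attributes
#'   \code{mapping} (per query position, its column index or \code{NA} if
#'   consumed as an insertion) and \code{score}.
#' @export
align_to_profile <- function(seq, profile, deletion_penalty = -1.5,
                             insertion_penalty = -1.5, epsilon = 1e-9) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(profile, "column_profile"))
  if (seq_has_gap(seq))
    pz_stop("validation", "align_to_profile requires a gap-free query")
  chars <- split_chars(seq$residues)
  L <- length(chars); W <- profile$width
  # match score matrix: L x W
  S <- matrix(0, L, W)
  for (i in seq_len(L)) {
    if (chars[i] == PZ_UNKNOWN) next
    S[i, ] <- log(profile$frequencies[, chars[i]] + epsilon) - log(1 / 20)
  }
  # M[i+1, j+1]: best score over first i query residues and first j columns
  M <- matrix(-Inf, L + 1L, W + 1L)
  M[1L, ] <- deletion_penalty * (0:W)
  M[, 1L] <- insertion_penalty * (0:L)
  for (i in seq_len(L)) for (j in seq_len(W)) {
    M[i + 1L, j + 1L] <- max(M[i, j] + S[i, j],
                             M[i + 1L, j] + deletion_penalty,
                             M[i, j + 1L] + insertion_penalty)
  }
  # traceback, tie preference: match > delete > insert
  i <- L; j <- W
  out <- character(W)
  mapping <- rep(NA_integer_, L)
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L && here == M[i, j] + S[i, j]) {
      out[j] <- chars[i]; mapping[i] <- j; i <- i - 1L; j <- j - 1L
    } else if (j > 0L && here == M[i + 1L, j] + deletion_penalty) {
      out[j] <- PZ_GAP; j <- j - 1L
    } else {
      i <- i - 1L                               # insertion: residue consumed
    }
  }
  structure(paste(out, collapse = ""),
            mapping = mapping, score = M[L + 1L, W + 1L])
}

#' MSA-aligned one-hot embedder
#'
#' Per profile column, 20 canonical indicator channels plus one gap channel
#' (21 per column, gap last; names \code{"col<j>_<aa>"} / \code{"col<j>_gap"});
#' embedding dimension is \code{21 * width}. Fitting stores the alignment
#' width and a column profile (used to align new sequences). At transform
#' time a sequence already at the alignment width and carrying gaps is
#' encoded directly; anything else (gap-free, or a different length) is first
#' passed through [align_to_profile()]. Every row sums to the width: one
#' indicator per column (\code{'X'} columns are the lone exception, encoding
#' to all-zero).
#'
#' @param pseudocount Pseudocount for the fitted profile (default 1).
#' @return An unfitted model with \code{requires_msa_for_fit} capability.
#' @export
onehot_aligned_embedder <- function(pseudocount = 1) {
  m <- new_protein_model("onehot_aligned_embedder",
                         list(pseudocount = pseudocount),
                         model_capabilities(requires_msa_for_fit = TRUE))
  validate_params(m)
  m
}

#' @export
validate_params.onehot_aligned_embedder <- function(model) {
  a <- model$params$pseudocount
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    pz_stop("params", "pseudocount must be a number >= 0")
  invisible(model)
}

#' @export
fit_state.onehot_aligned_embedder <- function(model, bundle) {
  profile <- fit_column_profile(bundle$alignment, model$params$pseudocount)
  list(width = family_width(bundle$alignment), profile = profile)
}

#' @export
transform_state.onehot_aligned_embedder <- function(model, sequences) {
  W <- model$state$width
  if (length(sequences) == 0L) pz_stop("validation", "no sequences to encode")
  layout <- paste0("col", rep(seq_len(W), each = 21L), "_",
                   rep(c(PZ_CANONICAL, "gap"), W))
  mat <- matrix(0, length(sequences), 21L * W,
                dimnames = list(sequence_ids(sequences), layout))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    aligned <- if (seq_width(s) == W && seq_has_gap(s)) s$residues
               else as.character(align_to_profile(s, model$state$profile))
    chars <- split_chars(aligned)
    for (j in seq_len(W)) {
      ch <- chars[j]
      k <- if (ch == PZ_GAP) 21L
           else if (ch == PZ_UNKNOWN) NA_integer_
           else PZ_CANONICAL_INDEX[[ch]]
      if (!is.na(k)) mat[i, 21L * (j - 1L) + k] <- 1
    }
  }
  mat
}

# ---- k-mer counts ------------------------------------------------------------

all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, PZ_CANONICAL, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  apply(as.matrix(grid)[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' k-mer count features
#'
#' One column per length-\code{k} word over the canonical alphabet, in
#' lexicographic order (\code{20^k} columns, names \code{"kmer_<word>"}).
#' Windows containing \code{'X'} are skipped. With \code{normalize = TRUE}
#' each row is divided by its number of counted windows (frequencies).
#' Sequences shorter than \code{k} produce an all-zero row with a warning;
#' gaps are rejected. \code{k} is capped at 3 to keep the dense output at
#' desk scale (8000 columns).
#'
#' @param sequences A [protein_sequence_set()], gap-free members.
#' @param k Word length, 1..3.
#' @param normalize Divide counts by the number of counted windows.
#' @return Numeric matrix \code{n x 20^k}, row names = sequence ids.
#' @export
kmer_counts <- function(sequences, k = 2, normalize = FALSE) {
  sequences <- as_sequence_set(sequences)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1 || k > 3)
    pz_stop("params", "k must be an integer in 1..3")
  k <- as.integer(k)
  res <- sequence_residues(sequences)
  if (any(grepl(PZ_GAP, res, fixed = TRUE)))
    pz_stop("validation", "gapped sequences have no well-defined k-mers")
  vocab <- all_kmers(k)
  mat <- matrix(0, length(res), length(vocab),
                dimnames = list(sequence_ids(sequences), paste0("kmer_", vocab)))
  for (i in seq_along(res)) {
    L <- nchar(res[i])
    if (L < k) {
      pz_warn("short_sequence", sprintf(
        "sequence '%s' (length %d) is shorter than k = %d; all-zero row",
        sequence_ids(sequences)[i], L, k))
      next
    }
    windows <- substring(res[i], seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    windows <- windows[!grepl(PZ_UNKNOWN, windows, fixed = TRUE)]
    if (length(windows) == 0L) next
    counts <- tabulate(match(windows, vocab), nbins = length(vocab))
    mat[i, ] <- if (normalize) counts / length(windows) else counts
  }
  mat
}

#' k-mer embedder
#'
#' Model-zoo wrapper around [kmer_counts()]. The model is stateless but still
#' follows the fit-then-transform lifecycle.
#'
#' @param k Word length, 1..3 (default 2).
#' @param normalize Emit frequencies instead of counts (default FALSE).
#' @return An unfitted model compatible with bare sequence sets.
#' @export
kmer_embedder <- function(k = 2, normalize = FALSE) {
  m <- new_protein_model("kmer_embedder", list(k = k, normalize = normalize),
                         model_capabilities())
  validate_params(m)
  m
}

#' @export
validate_params.kmer_embedder <- function(model) {
  k <- model$params$k
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1 || k > 3)
    pz_stop("params", "k must be an integer in 1..3")
  if (!is.logical(model$params$normalize) || length(model$params$normalize) != 1L)
    pz_stop("params", "normalize must be TRUE or FALSE")
  invisible(model)
}

#' @export
fit_state.kmer_embedder <- function(model, bundle) list()

#' @export
transform_state.kmer_embedder <- function(model, sequences) {
  kmer_counts(sequences, model$params$k, model$params$normalize)
}
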
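# Synthetic alignment families with known ground truth. Everything the other
# modules need for testing -- families drawn from a known column profile and
# variant sets with noiseless-or-noisy labels -- is generated here, so the
# whole package is exercisable with zero downloads and parameter recovery can
# be verified against the generating truth.

#' Draw a random column profile
#'
#' Each column's 20 canonical frequencies are drawn from a symmetric
#' Dirichlet(\code{concentration}) and scaled by \code{1 - gap_rate}; the gap
#' symbol receives frequency \code{gap_rate} in every column. The default
#' concentration 0.5 yields peaked columns resembling conserved alignment
#' positions, which keeps rank-based checks sharp. Deterministic under
#' \code{seed}; the caller's RNG stream is untouched.
#'
#' @param width Number of columns.
#' @param concentration Symmetric Dirichlet parameter, \code{> 0} (default 0.5).
#' @param gap_rate Probability mass on the gap symbol, in \code{[0, 1)}.
#' @param seed Integer seed (default 42, the documented fixture seed).
#' @return A \code{column_profile} (pseudocount 0; no observed counts).
#' @export
make_profile <- function(width, concentration = 0.5, gap_rate = 0, seed = 42) {
  if (!is.numeric(width) || width < 1L)
    pz_stop("validation", "width must be a positive integer")
  if (!is.numeric(concentration) || concentration <= 0)
    pz_stop("validation", "concentration must be > 0")
  if (!is.numeric(gap_rate) || gap_rate < 0 || gap_rate >= 1)
    pz_stop("validation", "gap_rate must lie in [0, 1)")
  width <- as.integer(width)
  freq <- with_seed(seed, {
    t(vapply(seq_len(width), function(j) {
      g <- stats::rgamma(20L, shape = concentration)
      c(g / sum(g) * (1 - gap_rate), gap_rate)
    }, numeric(21L)))
  })
  new_column_profile(freq, pseudocount = 0,
                     counts_per_column = rep(NA_integer_, width))
}

#' Sample an alignment family from a profile
#'
#' Every column of every member is drawn independently from that column's
#' symbol frequencies (gap included), so the family's true generating
#' distribution is exactly the profile -- [fit_column_profile()] with
#' \code{alpha = 0} on a large sample recovers it.
#'
#' @param profile A \code{column_profile}.
#' @param n Number of members, \code{>= 1}.
#' @param seed Integer seed.
#' @param id_prefix Member id prefix (ids are \code{"<prefix>1"} ...).
#' @return An [aligned_family()] of depth \code{n} and the profile's width.
#' @export
sample_family <- function(profile, n, seed = 42, id_prefix = "syn") {
  stopifnot(inherits(profile, "column_profile"))
  if (!is.numeric(n) || n < 1L) pz_stop("validation", "n must be >= 1")
  n <- as.integer(n)
  W <- profile$width
  chars <- with_seed(seed, {
    vapply(seq_len(W), function(j)
      sample(PZ_PROFILE_ALPHABET, n, replace = TRUE,
             prob = profile$frequencies[j, ]),
      character(n))
  })
  if (n == 1L) chars <- matrix(chars, nrow = 1L)
  rows <- apply(chars, 1L, paste, collapse = "")
  aligned_family(protein_sequence_set(lapply(seq_len(n), function(i)
    protein_sequence(paste0(id_prefix, i), rows[i]))))
}

#' Canonical consensus of a profile
#'
#' The most frequent canonical residue per column (gap ignored); a natural
#' wild type for synthetic variant sets.
#'
#' @param profile A \code{column_profile}.
#' @param id Sequence id (default \code{"consensus"}).
#' @return A gap-free [protein_sequence()] of the profile's width.
#' @export
profile_consensus <- function(profile, id = "consensus") {
  stopifnot(inherits(profile, "column_profile"))
  best <- apply(profile$frequencies[, PZ_CANONICAL, drop = FALSE], 1L, which.max)
  protein_sequence(id, paste(PZ_CANONICAL[best], collapse = ""))
}

#' Labeled synthetic variant set
#'
#' Draws \code{m} random single or double substitutions on \code{wt} and
#' labels each with its true delta log-likelihood under the generating
#' profile plus Gaussian noise of standard deviation \code{noise_sd}. With
#' \code{noise_sd = 0} the labels equal [variant_delta_scores()] exactly, so
#' rank agreement between scorer and labels is 1 by construction -- the
#' consistency surface the test-suite leans on.
#'
#' @param profile The generating \code{column_profile}.
#' @param wt Gap-free wild type of the profile's width, canonical residues
#'   only.
#' @param m Number of variants, \code{>= 1}.
#' @param noise_sd Label noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return List with \code{variants} (list of mutation lists),
#'   \code{mutation_strings}, \code{labels} (numeric) and \code{true_scores}
#'   (the noiseless labels).
#' @export
labeled_variants <- function(profile, wt, m, noise_sd = 0, seed = 42) {
  stopifnot(inherits(profile, "column_profile"), inherits(wt, "protein_sequence"))
  if (seq_has_gap(wt) || seq_width(wt) != profile$width)
    pz_stop("validation", "wt must be gap-free and match the profile width")
  wt_chars <- split_chars(wt$residues)
  if (any(!is_canonical(wt_chars)))
    pz_stop("validation", "wt must contain canonical residues only")
  if (!is.numeric(m) || m < 1L) pz_stop("validation", "m must be >= 1")
  m <- as.integer(m)
  L <- seq_width(wt)
  variants <- with_seed(seed, {
    lapply(seq_len(m), function(i) {
      k <- sample(c(1L, 2L), 1L)
      pos <- sort(sample.int(L, min(k, L)))
      lapply(pos, function(p)
        mutation_spec(wt_chars[p], p,
                      sample(setdiff(PZ_CANONICAL, wt_chars[p]), 1L)))
    })
  })
  true_scores <- variant_delta_scores(profile, wt, variants)$score
  labels <- true_scores +
    if (noise_sd > 0) with_seed(seed + 1L, stats::rnorm(m, 0, noise_sd)) else 0
  list(variants = variants,
       mutation_strings = vapply(variants, mutation_string, character(1)),
       labels = labels, true_scores = true_scores)
}
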
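# Alignment-based zero-shot scoring.
#
# The workhorse is the independent-sites column-frequency model: per-column
# symbol frequencies over an MSA, with the gap as a scorable 21st symbol and a
# pseudocount so unseen symbols keep finite log-likelihood. On top of it sit
# the three marginal scoring protocols (masked / wild-type / mutant marginal)
# defined over any conditional sequence model -- the same protocols protein
# language models expose; the profile-backed backend here is context-free,
# which makes the three modes provably coincide and gives the protocols an
# exactly testable reference.

new_column_profile <- function(frequencies, pseudocount, counts_per_column) {
  stopifnot(is.matrix(frequencies),
            ncol(frequencies) == length(PZ_PROFILE_ALPHABET))
  colnames(frequencies) <- PZ_PROFILE_ALPHABET
  sums <- rowSums(frequencies)
  if (any(abs(sums - 1) > 1e-12))
    pz_stop("validation", "profile rows must each sum to 1")
  structure(list(width = nrow(frequencies), frequencies = frequencies,
                 pseudocount = pseudocount,
                 counts_per_column = counts_per_column),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> %d columns x 21 symbols (pseudocount %s)\n",
              x$width, format(x$pseudocount)))
  invisible(x)
}

#' Fit an independent-sites column-frequency profile
#'
#' For column \eqn{j} and symbol \eqn{a} (20 canonical residues plus the gap),
#' \deqn{f_j(a) = (c_j(a) + \alpha) / (n_j + 21\alpha)}
#' where \eqn{c_j(a)} counts occurrences of \eqn{a} in column \eqn{j} and
#' \eqn{n_j} is the family depth minus the number of unknown residues
#' (\code{'X'}) in that column -- unknowns contribute to no symbol. With
#' \eqn{\alpha > 0} every frequency is strictly positive and every
#' log-likelihood finite; \eqn{\alpha = 0} gives the raw empirical
#' frequencies.
#'
#' @param family An [aligned_family()].
#' @param alpha Pseudocount \eqn{\alpha \ge 0} (default 1, Laplace smoothing).
#' @return A \code{column_profile} with a \code{width x 21} frequency matrix
#'   whose rows each sum to 1.
#' @export
fit_column_profile <- function(family, alpha = 1) {
  stopifnot(inherits(family, "aligned_family"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    pz_stop("validation", "pseudocount alpha must be a number >= 0")
  W <- family_width(family)
  chars <- do.call(rbind, strsplit(sequence_residues(family), "", fixed = TRUE))
  freq <- matrix(0, W, 21L)
  n_j <- integer(W)
  for (j in seq_len(W)) {
    col <- chars[, j]
    col <- col[col != PZ_UNKNOWN]
    n_j[j] <- length(col)
    counts <- tabulate(match(col, PZ_PROFILE_ALPHABET), nbins = 21L)
    denom <- n_j[j] + 21 * alpha
    if (denom == 0)
      pz_stop("validation", sprintf(
        "column %d has no countable symbols and alpha = 0", j))
    freq[j, ] <- (counts + alpha) / denom
  }
  new_column_profile(freq, alpha, n_j)
}

#' Log-likelihood of a sequence under a column profile
#'
#' \eqn{\sum_j \ln f_j(s_j)} over the profile's columns (natural log). The gap
#' is a scorable symbol; positions holding \code{'X'} are skipped with a
#' warning. A zero frequency (possible only with \code{alpha = 0}) raises a
#' score error advising a positive pseudocount.
#'
#' @param profile A \code{column_profile}.
#' @param seq A [protein_sequence()] of length equal to the profile width.
#' @return Scalar log-likelihood (natural-log units).
#' @export
profile_loglik <- function(profile, seq) {
  stopifnot(inherits(profile, "column_profile"), inherits(seq, "protein_sequence"))
  if (seq_width(seq) != profile$width)
    pz_stop("length_mismatch", sprintf(
      "sequence '%s' has length %d but profile width is %d; align it first",
      seq$id, seq_width(seq), profile$width))
  chars <- split_chars(seq$residues)
  keep <- chars != PZ_UNKNOWN
  if (!all(keep))
    pz_warn("unknown_residue", sprintf(
      "sequence '%s': %d 'X' position(s) skipped in log-likelihood",
      seq$id, sum(!keep)))
  f <- profile$frequencies[cbind(which(keep),
                                 match(chars[keep], PZ_PROFILE_ALPHABET))]
  if (any(f == 0))
    pz_stop("zero_frequency", sprintf(
      "sequence '%s' hits a zero-frequency symbol; refit the profile with alpha > 0",
      seq$id))
  sum(log(f))
}

# map ungapped wild-type positions to profile columns; NA where the residue
# was consumed as an insertion
wt_column_map <- function(profile, wt) {
  stopifnot(inherits(wt, "protein_sequence"))
  if (seq_has_gap(wt))
    pz_stop("validation", "wild type must be gap-free")
  L <- seq_width(wt)
  if (L == profile$width) return(seq_len(L))
  aln <- align_to_profile(wt, profile)
  attr(aln, "mapping")
}

#' Variant scores from a column profile
#'
#' Scores each variant as \eqn{\ell(\mathrm{mutant}) - \ell(\mathrm{wt})}
#' under the independent-sites model, which reduces exactly to
#' \eqn{\sum_i [\ln f_{j(i)}(\mathrm{mut}_i) - \ln f_{j(i)}(\mathrm{wt}_i)]}
#' over the mutated positions, where \eqn{j(i)} maps wild-type position
#' \eqn{i} to its profile column. When the wild type is shorter or longer than
#' the profile it is aligned to the profile first; a mutation at a position
#' that maps to no column (an insertion) is a mapping error. Higher scores are
#' more favorable; the empty variant scores exactly 0.
#'
#' @param profile A \code{column_profile}.
#' @param wt Gap-free wild-type [protein_sequence()].
#' @param variants List of variants, each a list of [mutation_spec()] (a
#'   single \code{mutation_spec} or a mutation string is also accepted per
#'   element).
#' @return A data frame with columns \code{variant_id},
#'   \code{mutation_string}, \code{score} (natural-log units), in input order.
#' @export
variant_delta_scores <- function(profile, wt, variants) {
  stopifnot(inherits(profile, "column_profile"))
  cmap <- wt_column_map(profile, wt)
  wt_chars <- split_chars(wt$residues)
  variants <- lapply(variants, normalize_variant)
  rows <- lapply(variants, function(muts) {
    if (length(muts) == 0L)
      return(data.frame(variant_id = wt$id, mutation_string = "", score = 0))
    s <- 0
    for (m in muts) {
      if (m$position > length(wt_chars))
        pz_stop("range", sprintf("mutation %s beyond wild-type length %d",
                                 format(m), length(wt_chars)))
      if (wt_chars[m$position] != m$wt_aa)
        pz_stop("wt_mismatch", sprintf(
          "mutation %s: wild type has '%s' at position %d",
          format(m), wt_chars[m$position], m$position))
      j <- cmap[m$position]
      if (is.na(j))
        pz_stop("mapping", sprintf(
          "position %d maps to no profile column (insertion relative to the profile)",
          m$position))
      f_mut <- profile$frequencies[j, m$mut_aa]
      f_wt <- profile$frequencies[j, m$wt_aa]
      if (f_mut == 0 || f_wt == 0)
        pz_stop("zero_frequency", sprintf(
          "zero frequency at column %d; refit the profile with alpha > 0", j))
      s <- s + log(f_mut) - log(f_wt)
    }
    data.frame(variant_id = paste0(wt$id, "_", mutation_string(muts)),
               mutation_string = mutation_string(muts), score = s)
  })
  do.call(rbind, rows)
}

normalize_variant <- function(v) {
  if (inherits(v, "mutation_spec")) return(list(v))
  if (is.character(v)) {
    if (!nzchar(v)) return(list())
    return(parse_mutation_string(v))
  }
  stopifnot(is.list(v))
  v
}

# ---- conditional sequence models & marginal protocols -----------------------

#' Conditional residue distribution (abstract contract)
#'
#' The interface a conditional sequence model must satisfy to be scored by
#' [marginal_score()]: given a context sequence and a position, return a
#' probability vector over the 20 canonical residues (named, non-negative,
#' summing to 1 within \code{1e-12}). \code{masked = TRUE} means the residue
#' at \code{position} is to be treated as unobserved. Protein language model
#' wrappers satisfy this contract; the built-in reference backend is
#' [profile_conditional_model()].
#'
#' @param model A conditional sequence model.
#' @param context A [protein_sequence()] providing the conditioning context.
#' @param position 1-based position being predicted.
#' @param masked Whether the residue at \code{position} is masked out of the
#'   context.
#' @return Named numeric vector of length 20 over [canonical_alphabet()].
#' @export
residue_distribution <- function(model, context, position, masked = FALSE) {
  UseMethod("residue_distribution")
}

#' Context-free conditional model backed by a column profile
#'
#' Predicts the residue at position \eqn{i} as the profile's column
#' \eqn{j(i)} frequencies renormalized over the 20 canonical residues,
#' ignoring the context entirely (and hence the \code{masked} flag). Because
#' the prediction is context-free, the masked, wild-type and mutant marginal
#' protocols coincide exactly on this backend and equal the profile's direct
#' delta log-likelihood.
#'
#' @param profile A \code{column_profile}.
#' @param column_map Integer vector mapping sequence positions to profile
#'   columns (default identity over the profile width).
#' @return Object of classes \code{profile_conditional_model},
#'   \code{conditional_sequence_model}.
#' @export
profile_conditional_model <- function(profile, column_map = seq_len(profile$width)) {
  stopifnot(inherits(profile, "column_profile"))
  structure(list(profile = profile, column_map = as.integer(column_map)),
            class = c("profile_conditional_model", "conditional_sequence_model"))
}

#' @export
residue_distribution.profile_conditional_model <- function(model, context,
                                                           position,
                                                           masked = FALSE) {
  j <- model$column_map[position]
  if (is.na(j) || position > length(model$column_map))
    pz_stop("mapping", sprintf("position %d maps to no profile column", position))
  f <- model$profile$frequencies[j, PZ_CANONICAL]
  f / sum(f)
}

validate_distribution <- function(p) {
  if (!is.numeric(p) || length(p) != 20L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-12 || is.null(names(p)) ||
      !identical(names(p), PZ_CANONICAL))
    pz_stop("model_contract", paste(
      "conditional model violated its contract: residue_distribution must",
      "return a named, non-negative vector over the 20 canonical residues",
      "summing to 1"))
  p
}

#' Marginal variant score under a conditional sequence model
#'
#' The three standard protocols for turning a conditional residue model into
#' a variant score, each summing over the mutated positions \eqn{i} (natural
#' log):
#' \describe{
#'   \item{masked}{\eqn{\sum_i [\ln p(\mathrm{mut}_i \mid wt\ masked\ at\ i) -
#'     \ln p(\mathrm{wt}_i \mid wt\ masked\ at\ i)]}}
#'   \item{wildtype}{contexts are the unmasked wild type}
#'   \item{mutant}{contexts are the full unmasked mutant sequence}
#' }
#' The empty mutation list scores 0 in every mode. Only canonical residues
#' are scored (the gap is not part of the conditional contract).
#'
#' @param model A conditional sequence model (see [residue_distribution()]).
#' @param wt Gap-free wild-type [protein_sequence()].
#' @param mutations List of [mutation_spec()] (or a mutation string).
#' @param mode One of \code{"masked"}, \code{"wildtype"}, \code{"mutant"}.
#' @return Scalar score; higher is more favorable relative to wild type.
#' @export
marginal_score <- function(model, wt, mutations,
                           mode = c("masked", "wildtype", "mutant")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt, "protein_sequence"))
  if (seq_has_gap(wt)) pz_stop("validation", "wild type must be gap-free")
  mutations <- normalize_variant(mutations)
  if (length(mutations) == 0L) return(0)
  wt_chars <- split_chars(wt$residues)
  for (m in mutations) {
    if (m$position > length(wt_chars) || wt_chars[m$position] != m$wt_aa)
      pz_stop("wt_mismatch", sprintf(
        "mutation %s does not match the wild type", format(m)))
  }
  mutant <- apply_mutations(wt, mutations)
  total <- 0
  for (m in mutations) {
    ctx <- switch(mode, masked = wt, wildtype = wt, mutant = mutant)
    p <- validate_distribution(
      residue_distribution(model, ctx, m$position, masked = (mode == "masked")))
    total <- total + log(p[[m$mut_aa]]) - log(p[[m$wt_aa]])
  }
  total
}

# ---- model-zoo wrappers ------------------------------------------------------

#' Column-profile zero-shot scorer
#'
#' The alignment-based scorer of the model zoo: fits an independent-sites
#' column-frequency profile on the training alignment (auto-aligning ragged
#' input with a warning) and scores sequences by summed log-likelihood.
#' Sequences whose length differs from the profile width are aligned to the
#' profile first. Raw summed log-likelihood is reported (no length
#' normalization).
#'
#' @param alpha Pseudocount (default 1).
#' @return An unfitted model; see [fit()], [predict()], [score_variants()].
#' @export
profile_scorer <- function(alpha = 1) {
  m <- new_protein_model("profile_scorer", list(alpha = alpha),
                         model_capabilities(requires_msa_for_fit = TRUE,
                                            output_kind = "per_sequence_score"))
  validate_params(m)
  m
}

#' @export
validate_params.profile_scorer <- function(model) {
  a <- model$params$alpha
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    pz_stop("params", "alpha must be a number >= 0")
  invisible(model)
}

#' @export
fit_state.profile_scorer <- function(model, bundle) {
  list(profile = fit_column_profile(bundle$alignment, model$params$alpha))
}

#' @export
predict_state.profile_scorer <- function(model, sequences) {
  profile <- model$state$profile
  scores <- vapply(sequences, function(s) {
    if (seq_width(s) != profile$width) {
      if (seq_has_gap(s))
        pz_stop("length_mismatch", sprintf(
          "sequence '%s' is gapped but does not match the profile width", s$id))
      s <- protein_sequence(s$id, as.character(align_to_profile(s, profile)))
    }
    profile_loglik(profile, s)
  }, numeric(1))
  stats::setNames(scores, sequence_ids(sequences))
}

#' Score variants with a fitted profile scorer
#'
#' Convenience wrapper over [variant_delta_scores()] using the model's fitted
#' profile.
#'
#' @param model A fitted [profile_scorer()].
#' @param wt Gap-free wild-type [protein_sequence()].
#' @param variants List of mutation lists (or mutation strings).
#' @return Data frame as for [variant_delta_scores()].
#' @export
score_variants <- function(model, wt, variants) {
  stopifnot(inherits(model, "profile_scorer"))
  check_fitted(model)
  variant_delta_scores(model$state$profile, wt, variants)
}

#' Marginal-likelihood zero-shot scorer
#'
#' Scores variants against a wild type using one of the masked / wild-type /
#' mutant marginal protocols over a conditional sequence model. With no
#' backend supplied, fitting builds the context-free
#' [profile_conditional_model()] from the training alignment, making this a
#' fully offline reference implementation of the protocols that heavier
#' language-model backends also satisfy.
#'
#' @param mode Scoring protocol: \code{"masked"} (default), \code{"wildtype"}
#'   or \code{"mutant"}.
#' @param alpha Pseudocount for the profile backend (default 1).
#' @param backend Optional pre-built conditional sequence model; when given,
#'   no alignment is needed at fit time.
#' @return An unfitted model. \code{predict()} on variant sequences returns
#'   one score per sequence (differences against the wild type are derived
#'   automatically).
#' @export
marginal_scorer <- function(mode = c("masked", "wildtype", "mutant"),
                            alpha = 1, backend = NULL) {
  mode <- match.arg(mode)
  m <- new_protein_model(
    "marginal_scorer", list(mode = mode, alpha = alpha, backend = backend),
    model_capabilities(requires_msa_for_fit = is.null(backend),
                       requires_wt = TRUE,
                       output_kind = "per_sequence_score"))
  validate_params(m)
  m
}

#' @export
validate_params.marginal_scorer <- function(model) {
  if (!model$params$mode %in% c("masked", "wildtype", "mutant"))
    pz_stop("params", "mode must be one of masked, wildtype, mutant")
  a <- model$params$alpha
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    pz_stop("params", "alpha must be a number >= 0")
  b <- model$params$backend
  if (!is.null(b) && !inherits(b, "conditional_sequence_model"))
    pz_stop("params", "backend must be a conditional_sequence_model (or NULL)")
  invisible(model)
}

#' @export
fit_state.marginal_scorer <- function(model, bundle) {
  wt <- bundle$wild_type
  backend <- model$params$backend
  if (is.null(backend)) {
    profile <- fit_column_profile(bundle$alignment, model$params$alpha)
    backend <- profile_conditional_model(profile, wt_column_map(profile, wt))
  }
  list(backend = backend, wild_type = wt)
}

#' @export
predict_state.marginal_scorer <- function(model, sequences) {
  wt <- model$state$wild_type
  scores <- vapply(sequences, function(s) {
    muts <- diff_sequences(wt, s)
    marginal_score(model$state$backend, wt, muts, model$params$mode)
  }, numeric(1))
  stats::setNames(scores, sequence_ids(sequences))
}
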
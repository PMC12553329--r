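# The uniform estimator contract: models are constructed with hyperparameters
# only, fitted on a data bundle, then transform (embedders) or predict
# (scorers). Declared capabilities are checked -- and where possible
# remediated -- before fitting.

#' Declared model capabilities
#'
#' Immutable flags describing what a model needs from its input data and what
#' it emits. They drive [check_compatibility()] and the automatic remediation
#' performed by [fit()].
#'
#' @param requires_msa_for_fit Model must be fitted on an alignment; unaligned
#'   input is aligned automatically (with a warning) when possible.
#' @param requires_structure Every input sequence must resolve a structure
#'   (its own, else the wild-type structure with a warning).
#' @param requires_wt A gap-free wild-type sequence must be present.
#' @param requires_fixed_length All input sequences must share one length.
#' @param output_kind \code{"per_sequence_vector"} (embedders) or
#'   \code{"per_sequence_score"} (zero-shot / supervised scorers).
#' @return Object of class \code{model_capabilities}.
#' @export
model_capabilities <- function(requires_msa_for_fit = FALSE,
                               requires_structure = FALSE,
                               requires_wt = FALSE,
                               requires_fixed_length = FALSE,
                               output_kind = c("per_sequence_vector",
                                               "per_sequence_score")) {
  output_kind <- match.arg(output_kind)
  structure(list(requires_msa_for_fit = isTRUE(requires_msa_for_fit),
                 requires_structure = isTRUE(requires_structure),
                 requires_wt = isTRUE(requires_wt),
                 requires_fixed_length = isTRUE(requires_fixed_length),
                 output_kind = output_kind),
            class = "model_capabilities")
}

#' Bundle of protein data handed to models
#'
#' The single argument of [fit()]: sequences plus whatever optional context a
#' model's capabilities may require.
#'
#' @param sequences A [protein_sequence_set()] (an [aligned_family()] is also
#'   accepted and doubles as the alignment).
#' @param alignment Optional [aligned_family()].
#' @param wild_type Optional wild-type [protein_sequence()].
#' @param structures Optional named list mapping sequence id to
#'   \code{structure_record}.
#' @param wt_structure Optional \code{structure_record} fallback.
#' @param labels Optional numeric vector, one value per sequence.
#' @return Object of class \code{data_bundle}.
#' @export
data_bundle <- function(sequences = NULL, alignment = NULL, wild_type = NULL,
                        structures = NULL, wt_structure = NULL, labels = NULL) {
  if (is.null(sequences)) sequences <- protein_sequence_set()
  if (inherits(sequences, "protein_sequence")) sequences <- protein_sequence_set(sequences)
  stopifnot(inherits(sequences, "protein_sequence_set"))
  if (is.null(alignment) && inherits(sequences, "aligned_family"))
    alignment <- sequences
  if (!is.null(alignment)) stopifnot(inherits(alignment, "aligned_family"))
  if (!is.null(wild_type)) stopifnot(inherits(wild_type, "protein_sequence"))
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) != length(sequences))
      pz_stop("validation", sprintf(
        "labels (%d) must have one value per sequence (%d)",
        length(labels), length(sequences)))
  }
  structure(list(sequences = sequences, alignment = alignment,
                 wild_type = wild_type, structures = structures,
                 wt_structure = wt_structure, labels = labels),
            class = "data_bundle")
}

#' @export
print.data_bundle <- function(x, ...) {
  cat(sprintf("<data_bundle> %d sequences%s%s%s%s\n", length(x$sequences),
              if (!is.null(x$alignment)) sprintf(", alignment (%dx%d)",
                length(x$alignment), family_width(x$alignment)) else "",
              if (!is.null(x$wild_type)) ", wild type" else "",
              if (!is.null(x$structures) || !is.null(x$wt_structure))
                ", structures" else "",
              if (!is.null(x$labels)) ", labels" else ""))
  invisible(x)
}

# ---- model base --------------------------------------------------------------

# All built-in models are lists with fields: params (hyperparameters, the only
# constructor input), capabilities, fitted flag, state (set by fit).
new_protein_model <- function(subclass, params, capabilities) {
  structure(list(params = params, capabilities = capabilities,
                 fitted = FALSE, state = NULL),
            class = c(subclass, "protein_model"))
}

#' @export
print.protein_model <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, function(p)
    paste(format(p), collapse = ","), character(1)), sep = "=", collapse = ", ")
  cat(sprintf("<%s> %s(%s)\n", class(x)[1],
              if (x$fitted) "fitted" else "unfitted", ps))
  invisible(x)
}

# capability accessor (kept internal: exporting `capabilities` would mask the
# base function of the same name; models expose the flags as $capabilities)
model_caps <- function(model) model$capabilities

#' Fit a protein model
#'
#' Runs the model's capability checks and remediation (alignment, structure
#' fallback, wild-type presence) on \code{bundle}, then fits. Fitting twice
#' re-fits from scratch; refitting on identical data reproduces the fitted
#' state exactly.
#'
#' @param model An unfitted (or previously fitted) protein model.
#' @param bundle A [data_bundle()], or a \code{protein_sequence_set} which is
#'   wrapped into one.
#' @param ... Unused.
#' @return The fitted model.
#' @export
fit <- function(model, bundle, ...) UseMethod("fit")

#' @export
fit.protein_model <- function(model, bundle, ...) {
  bundle <- as_bundle(bundle)
  caps <- model_caps(model)
  if (caps$requires_wt) bundle <- ensure_wt(bundle)
  if (caps$requires_msa_for_fit) bundle <- ensure_msa_on_fit(bundle)
  if (caps$requires_structure) bundle <- ensure_structure(bundle)
  if (caps$requires_fixed_length && !uniform_length(bundle$sequences))
    pz_stop("fixed_length", "model requires sequences of one fixed length")
  model$state <- fit_state(model, bundle)
  model$fitted <- TRUE
  model
}

# per-class fitting of internal state
fit_state <- function(model, bundle) UseMethod("fit_state")

as_bundle <- function(x) {
  if (inherits(x, "data_bundle")) return(x)
  data_bundle(sequences = x)
}

check_fitted <- function(model) {
  if (!isTRUE(model$fitted))
    pz_stop("not_fitted", sprintf(
      "%s has not been fitted; call fit() before transform()/predict()",
      class(model)[1]))
}

#' @export
transform.protein_model <- function(`_data`, sequences, ...) {
  model <- `_data`
  check_fitted(model)
  if (model_caps(model)$output_kind != "per_sequence_vector")
    pz_stop("contract", sprintf("%s is a scorer; use predict()", class(model)[1]))
  sequences <- as_sequence_set(sequences)
  transform_state(model, sequences)
}

transform_state <- function(model, sequences) UseMethod("transform_state")

#' @export
predict.protein_model <- function(object, sequences, ...) {
  check_fitted(object)
  if (model_caps(object)$output_kind != "per_sequence_score")
    pz_stop("contract", sprintf("%s is an embedder; use transform()", class(object)[1]))
  sequences <- as_sequence_set(sequences)
  predict_state(object, sequences)
}

predict_state <- function(model, sequences) UseMethod("predict_state")

as_sequence_set <- function(x) {
  if (inherits(x, "protein_sequence")) return(protein_sequence_set(x))
  if (inherits(x, "data_bundle")) return(x$sequences)
  stopifnot(inherits(x, "protein_sequence_set"))
  x
}

#' Score a predictive model against labels
#'
#' Returns the Spearman rank correlation between the model's predictions and
#' the bundle's labels. Rank correlation is the framework-wide score because
#' zero-shot outputs are rank-scale: only the ordering of variants is
#' comparable across scorers.
#'
#' @param model A fitted scoring model.
#' @param bundle A [data_bundle()] with \code{labels}.
#' @return Spearman correlation in \code{[-1, 1]}.
#' @export
score <- function(model, bundle) UseMethod("score")

#' @export
score.protein_model <- function(model, bundle) {
  stopifnot(inherits(bundle, "data_bundle"))
  if (is.null(bundle$labels))
    pz_stop("validation", "score() needs a bundle with labels")
  preds <- predict(model, bundle$sequences)
  stats::cor(preds, bundle$labels, method = "spearman")
}

# ---- hyperparameter introspection -------------------------------------------

#' Get or set a model's hyperparameters
#'
#' Every constructor hyperparameter is exposed by name; there is no hidden
#' state. \code{set_params} returns a new unfitted model (changing a
#' hyperparameter invalidates any fitted state); unknown names error. A model
#' rebuilt from \code{get_params} output behaves identically after an
#' identical fit.
#'
#' @param model A protein model.
#' @param ... For \code{set_params}: named hyperparameter updates.
#' @return \code{get_params}: named list; \code{set_params}: updated model.
#' @export
get_params <- function(model) UseMethod("get_params")

#' @export
get_params.protein_model <- function(model) model$params

#' @rdname get_params
#' @export
set_params <- function(model, ...) UseMethod("set_params")

#' @export
set_params.protein_model <- function(model, ...) {
  updates <- list(...)
  if (length(updates) == 0L) return(model)
  if (is.null(names(updates)) || any(!nzchar(names(updates))))
    pz_stop("params", "set_params updates must be named")
  unknown <- setdiff(names(updates), names(model$params))
  if (length(unknown))
    pz_stop("params", sprintf("unknown hyperparameter(s): %s (declared: %s)",
                              paste(unknown, collapse = ", "),
                              paste(names(model$params), collapse = ", ")))
  model$params[names(updates)] <- updates
  validate_params(model)
  model$fitted <- FALSE
  model$state <- NULL
  model
}

# constructors call this too, so set_params and construction share validation
validate_params <- function(model) UseMethod("validate_params")

#' @export
validate_params.protein_model <- function(model) invisible(model)

#' Clone a model from its hyperparameters
#'
#' Builds a fresh unfitted model of the same class from [get_params()] output.
#'
#' @param model A protein model.
#' @return A new unfitted model.
#' @export
clone_model <- function(model) {
  stopifnot(inherits(model, "protein_model"))
  fresh <- model
  fresh$fitted <- FALSE
  fresh$state <- NULL
  do.call(set_params, c(list(fresh), get_params(model)))
}

# ---- capability remediation --------------------------------------------------

#' Ensure the bundle carries an alignment
#'
#' Used by MSA-requiring models at fit time. An explicit alignment passes
#' through unchanged. Otherwise, two or more sequences of one uniform length
#' are wrapped as an [aligned_family()] as-is; ragged sequences are aligned by
#' [center_star_align()] with a warning that automatic alignment occurred.
#' The operation is idempotent.
#'
#' @param bundle A [data_bundle()].
#' @return The bundle, with \code{alignment} set.
#' @export
ensure_msa_on_fit <- function(bundle) {
  stopifnot(inherits(bundle, "data_bundle"))
  if (!is.null(bundle$alignment)) return(bundle)
  seqs <- bundle$sequences
  if (length(seqs) < 2L)
    pz_stop("capability", "need an alignment or at least 2 sequences to align")
  if (uniform_length(seqs)) {
    bundle$alignment <- aligned_family(seqs)
  } else {
    pz_warn("auto_alignment", "input sequences were not aligned; center-star alignment applied")
    bundle$alignment <- center_star_align(seqs)
  }
  bundle
}

#' Ensure every sequence resolves a structure
#'
#' A sequence keeps its own structure when one is mapped under its id;
#' otherwise it falls back to the bundle's wild-type structure, with one
#' warning per fallback. If neither exists for some sequence, a capability
#' error names the offending ids.
#'
#' @param bundle A [data_bundle()].
#' @return The bundle, with \code{structures} complete.
#' @export
ensure_structure <- function(bundle) {
  stopifnot(inherits(bundle, "data_bundle"))
  ids <- sequence_ids(bundle$sequences)
  structures <- if (is.null(bundle$structures)) list() else bundle$structures
  missing <- ids[!ids %in% names(structures)]
  if (length(missing)) {
    if (is.null(bundle$wt_structure))
      pz_stop("capability", sprintf(
        "no structure resolvable for sequence(s): %s",
        paste(missing, collapse = ", ")))
    for (id in missing) {
      pz_warn("structure_fallback", sprintf(
        "sequence '%s' has no structure; falling back to wild-type structure", id))
      structures[[id]] <- bundle$wt_structure
    }
  }
  bundle$structures <- structures
  bundle
}

#' Ensure a wild-type sequence is present
#'
#' Wild-type-requiring models error without one. The wild type must be
#' gap-free: variants are defined on wild-type coordinates.
#'
#' @param bundle A [data_bundle()].
#' @return The bundle, unchanged.
#' @export
ensure_wt <- function(bundle) {
  stopifnot(inherits(bundle, "data_bundle"))
  if (is.null(bundle$wild_type))
    pz_stop("capability", "model requires a wild-type sequence in the bundle")
  if (seq_has_gap(bundle$wild_type))
    pz_stop("capability", "wild-type sequence must be gap-free")
  bundle
}

#' Report a model's compatibility with a bundle
#'
#' Pure function: neither the model nor the bundle is mutated, and nothing is
#' raised -- every unmet requirement is listed in the report. The MSA
#' requirement counts as met only when the bundle carries an explicit
#' alignment (even though [fit()] can auto-align ragged input with a warning).
#'
#' @param model A protein model (or a \code{model_capabilities} object).
#' @param bundle A [data_bundle()].
#' @return Object of class \code{compatibility_report}: list with
#'   \code{compatible} (logical) and \code{unmet} (character vector of
#'   requirement codes among \code{"sequences"}, \code{"msa"},
#'   \code{"structure"}, \code{"wt"}, \code{"fixed_length"}).
#' @export
check_compatibility <- function(model, bundle) {
  caps <- if (inherits(model, "model_capabilities")) model else model_caps(model)
  stopifnot(inherits(bundle, "data_bundle"))
  unmet <- character(0)
  if (length(bundle$sequences) == 0L) unmet <- c(unmet, "sequences")
  if (caps$requires_msa_for_fit && is.null(bundle$alignment))
    unmet <- c(unmet, "msa")
  if (caps$requires_structure) {
    ids <- sequence_ids(bundle$sequences)
    covered <- ids %in% names(bundle$structures)
    if ((length(ids) == 0L || !all(covered)) && is.null(bundle$wt_structure))
      unmet <- c(unmet, "structure")
  }
  if (caps$requires_wt &&
      (is.null(bundle$wild_type) || seq_has_gap(bundle$wild_type)))
    unmet <- c(unmet, "wt")
  if (caps$requires_fixed_length && !uniform_length(bundle$sequences))
    unmet <- c(unmet, "fixed_length")
  structure(list(compatible = length(unmet) == 0L, unmet = unmet),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  if (x$compatible) cat("<compatibility_report> compatible\n")
  else cat("<compatibility_report> unmet:", paste(x$unmet, collapse = ", "), "\n")
  invisible(x)
}

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
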
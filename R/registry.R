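# Model registry: every tool in the zoo is described by a descriptor carrying
# its category, dependency tier and capability flags, so compatibility with a
# user's data can be checked across the whole zoo without importing any heavy
# dependency. GPU / external-environment models are present as stubs with
# faithful capability metadata; they are statically unavailable here and
# error clearly when instantiated.

model_descriptor <- function(name, category, tier, capabilities,
                             constructor = NULL, needs = NULL) {
  stopifnot(category %in% c("embedding", "zero_shot"),
            tier %in% c("base", "extra", "external_env"))
  structure(list(name = name, category = category, tier = tier,
                 capabilities = capabilities,
                 available = identical(tier, "base"),
                 constructor = constructor, needs = needs),
            class = "model_descriptor")
}

#' @export
print.model_descriptor <- function(x, ...) {
  cat(sprintf("<model_descriptor> %s [%s, tier %s, %s]\n", x$name, x$category,
              x$tier, if (x$available) "available" else "not installed"))
  invisible(x)
}

#' The built-in model registry
#'
#' One descriptor per tool in the zoo. Base-tier models (the fixed and
#' MSA-aligned one-hot embedders, the k-mer embedder, the column-profile
#' scorer, and the profile-backed marginal scorer) are always available and
#' instantiable. Extra-tier descriptors (language-model embedders and
#' likelihood scorers needing GPU deep-learning stacks) and
#' external-environment descriptors (tools run in their own environments) are
#' capability-faithful stubs: their compatibility with data can be checked,
#' but instantiating them raises a not-installed error naming the missing
#' dependency tier.
#'
#' @return Named list of \code{model_descriptor} objects (names unique).
#' @export
builtin_registry <- function() {
  caps <- model_capabilities
  entries <- list(
    model_descriptor("onehot", "embedding", "base",
                     caps(requires_fixed_length = TRUE),
                     constructor = onehot_embedder),
    model_descriptor("onehot_aligned", "embedding", "base",
                     caps(requires_msa_for_fit = TRUE),
                     constructor = onehot_aligned_embedder),
    model_descriptor("kmer", "embedding", "base", caps(),
                     constructor = kmer_embedder),
    model_descriptor("profile_scorer", "zero_shot", "base",
                     caps(requires_msa_for_fit = TRUE,
                          output_kind = "per_sequence_score"),
                     constructor = profile_scorer),
    model_descriptor("marginal_scorer", "zero_shot", "base",
                     caps(requires_msa_for_fit = TRUE, requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     constructor = marginal_scorer),
    model_descriptor("evmutation", "zero_shot", "extra",
                     caps(requires_msa_for_fit = TRUE, requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "evcouplings"),
    model_descriptor("esm2_embedding", "embedding", "extra", caps(),
                     needs = "transformers"),
    model_descriptor("esm2_likelihood", "zero_shot", "extra",
                     caps(requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "transformers"),
    model_descriptor("saprot_embedding", "embedding", "extra",
                     caps(requires_structure = TRUE),
                     needs = "transformers + foldseek"),
    model_descriptor("saprot_likelihood", "zero_shot", "extra",
                     caps(requires_structure = TRUE, requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "transformers + foldseek"),
    model_descriptor("msa_transformer_embedding", "embedding", "extra",
                     caps(requires_msa_for_fit = TRUE),
                     needs = "fair-esm"),
    model_descriptor("msa_transformer_likelihood", "zero_shot", "extra",
                     caps(requires_msa_for_fit = TRUE, requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "fair-esm"),
    model_descriptor("vespa", "zero_shot", "extra",
                     caps(requires_wt = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "vespa-effect"),
    model_descriptor("eve", "zero_shot", "external_env",
                     caps(requires_msa_for_fit = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "dedicated EVE environment"),
    model_descriptor("ssemb_embedding", "embedding", "external_env",
                     caps(requires_msa_for_fit = TRUE, requires_structure = TRUE),
                     needs = "dedicated SSEmb environment"),
    model_descriptor("ssemb_scorer", "zero_shot", "external_env",
                     caps(requires_msa_for_fit = TRUE, requires_structure = TRUE,
                          output_kind = "per_sequence_score"),
                     needs = "dedicated SSEmb environment")
  )
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  stopifnot(!anyDuplicated(names(entries)))
  entries
}

#' Instantiate a registered model by name
#'
#' @param name Registry entry name.
#' @param ... Hyperparameters forwarded to the model constructor.
#' @param registry Registry to look in (default [builtin_registry()]).
#' @return An unfitted model, for base-tier entries. Non-base entries raise a
#'   not-installed error naming their dependency tier.
#' @export
instantiate_model <- function(name, ..., registry = builtin_registry()) {
  if (!name %in% names(registry))
    pz_stop("registry", sprintf("no model named '%s' (known: %s)", name,
                                paste(names(registry), collapse = ", ")))
  d <- registry[[name]]
  if (!d$available || is.null(d$constructor))
    pz_stop("not_installed", sprintf(
      "model '%s' is a %s-tier stub in this build; it needs %s",
      name, d$tier, d$needs))
  d$constructor(...)
}

#' Which models fit the data at hand?
#'
#' Pairs every registry entry with its [check_compatibility()] report against
#' the bundle. Pure function of (registry, bundle): nothing is mutated.
#'
#' @param bundle A [data_bundle()].
#' @param registry Registry (default [builtin_registry()]).
#' @param compatible_only Keep only rows that are both available and
#'   compatible.
#' @return Data frame with columns \code{name}, \code{category}, \code{tier},
#'   \code{available}, \code{compatible}, \code{unmet} (comma-separated
#'   requirement codes) and a list-column \code{report}.
#' @export
available_models <- function(bundle, registry = builtin_registry(),
                             compatible_only = FALSE) {
  stopifnot(inherits(bundle, "data_bundle"))
  reports <- lapply(registry, function(d)
    check_compatibility(d$capabilities, bundle))
  out <- data.frame(
    name = vapply(registry, `[[`, character(1), "name"),
    category = vapply(registry, `[[`, character(1), "category"),
    tier = vapply(registry, `[[`, character(1), "tier"),
    available = vapply(registry, `[[`, logical(1), "available"),
    compatible = vapply(reports, `[[`, logical(1), "compatible"),
    unmet = vapply(reports, function(r) paste(r$unmet, collapse = ","),
                   character(1)),
    row.names = NULL)
  out$report <- unname(reports)
  if (compatible_only) out <- out[out$available & out$compatible, , drop = FALSE]
  out
}

#' Subsample an alignment
#'
#' Uniform sample of \code{n} members without replacement, preserving the
#' parent's member order; no sequence weighting. Deterministic under
#' \code{seed}, and the caller's RNG stream is left untouched.
#'
#' @param family An [aligned_family()].
#' @param n Number of members to keep, \code{1 <= n <= depth}.
#' @param seed Integer seed.
#' @return An [aligned_family()] of depth \code{n}.
#' @export
sample_msa <- function(family, n, seed = 42) {
  stopifnot(inherits(family, "aligned_family"))
  depth <- length(family)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1L || n > depth)
    pz_stop("range", sprintf("n must lie in 1..%d (family depth)", depth))
  idx <- sort(with_seed(seed, sample.int(depth, as.integer(n))))
  aligned_family(family[idx])
}
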
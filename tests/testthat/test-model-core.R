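test_that("the lifecycle contract holds: fit before transform, refits reset state", {
  seqs <- toy_family(c("ACWD", "ACWD", "AC-D"))
  model <- kmer_embedder(k = 2)
  expect_error(transform(model, seqs), class = "protzoo_not_fitted")

  plain <- protein_sequence_set(list(protein_sequence("a", "ACWD"),
                                     protein_sequence("b", "ACDD"),
                                     protein_sequence("c", "WWWW")))
  fitted <- fit(model, plain)
  out1 <- transform(fitted, plain)
  expect_equal(nrow(out1), 3)
  expect_true(all(is.finite(out1)))
  expect_equal(rownames(out1), c("a", "b", "c"))

  # refit on the same data reproduces outputs bit-identically
  refit <- fit(fitted, plain)
  expect_identical(transform(refit, plain), out1)

  # scorers reject transform(), embedders reject predict()
  scorer <- fit(profile_scorer(), data_bundle(sequences = seqs))
  expect_error(transform(scorer, seqs), class = "protzoo_contract")
  expect_error(predict(fitted, plain), class = "protzoo_contract")
})

model_needs_msa <- function(m) m$capabilities$requires_msa_for_fit

test_that("hyperparameters round-trip through get_params/set_params and clone", {
  m <- kmer_embedder(k = 2)
  expect_equal(get_params(m)$k, 2)
  m3 <- set_params(m, k = 3)
  expect_equal(get_params(m3)$k, 3)
  expect_false(m3$fitted)
  expect_error(set_params(m, bogus = 1), class = "protzoo_params")
  expect_error(set_params(m, k = 9), class = "protzoo_params")

  # clone-via-params then fit both on the same data -> identical transforms
  set.seed(3)
  data <- random_set(5, 12)
  for (ctor in list(function() kmer_embedder(k = 3, normalize = TRUE),
                    function() onehot_embedder(),
                    function() onehot_aligned_embedder(pseudocount = 0.5))) {
    orig <- ctor()
    cloned <- clone_model(orig)
    expect_identical(get_params(cloned), get_params(orig))
    b <- if (model_needs_msa(orig)) data_bundle(toy_family(c("ACWD", "AC-D")))
         else data_bundle(data)
    probe <- if (model_needs_msa(orig))
      protein_sequence_set(list(protein_sequence("q", "ACD"))) else data
    expect_identical(transform(fit(orig, b), probe),
                     transform(fit(cloned, b), probe))
  }
})

test_that("ensure_msa_on_fit passes aligned input through and aligns ragged input", {
  fam <- toy_family(c("ACWD", "AC-D"))
  b <- data_bundle(sequences = fam)
  expect_identical(ensure_msa_on_fit(b), b)  # idempotent on aligned input
  expect_identical(ensure_msa_on_fit(ensure_msa_on_fit(b)), ensure_msa_on_fit(b))

  ragged <- data_bundle(protein_sequence_set(list(
    protein_sequence("a", "ACD"), protein_sequence("b", "AD"))))
  expect_warning(out <- ensure_msa_on_fit(ragged), class = "protzoo_auto_alignment")
  expect_equal(family_width(out$alignment), 3L)
  # pairwise DP oracle by hand: ACD vs AD -> ACD / A-D (match A, gap, match D)
  expect_equal(sequence_residues(out$alignment), c("ACD", "A-D"))

  single <- data_bundle(protein_sequence_set(list(protein_sequence("a", "ACD"))))
  expect_error(ensure_msa_on_fit(single), class = "protzoo_capability")
})

test_that("ensure_structure falls back to the wild-type structure with warnings", {
  rec <- parse_chain_sequence(toy_pdb_text(c("ALA", "CYS", "ASP")), "A")
  seqs <- protein_sequence_set(list(protein_sequence("a", "ACD"),
                                    protein_sequence("b", "AWD")))
  full <- data_bundle(seqs, structures = list(a = rec, b = rec))
  expect_no_warning(out <- ensure_structure(full))
  expect_identical(out$structures, full$structures)

  fallback <- data_bundle(seqs, wt_structure = rec)
  warns <- 0L
  out2 <- withCallingHandlers(ensure_structure(fallback),
    protzoo_structure_fallback = function(w) {
      warns <<- warns + 1L; invokeRestart("muffleWarning")
    })
  expect_equal(warns, 2L)  # one per fallback
  expect_equal(sort(names(out2$structures)), c("a", "b"))

  expect_error(ensure_structure(data_bundle(seqs)), class = "protzoo_capability",
               regexp = "a, b")
})

test_that("ensure_wt demands a gap-free wild type", {
  seqs <- protein_sequence_set(list(protein_sequence("a", "ACD")))
  wt <- protein_sequence("wt", "ACD")
  expect_identical(ensure_wt(data_bundle(seqs, wild_type = wt))$wild_type, wt)
  expect_error(ensure_wt(data_bundle(seqs)), class = "protzoo_capability")
  expect_error(ensure_wt(data_bundle(seqs, wild_type = protein_sequence("g", "A-D"))),
               class = "protzoo_capability")
})

test_that("check_compatibility reports without raising and never mutates", {
  seqs <- protein_sequence_set(list(protein_sequence("a", "ACD"),
                                    protein_sequence("b", "AWDC")))
  bundle <- data_bundle(seqs)
  snapshot <- unserialize(serialize(bundle, NULL))

  rep1 <- check_compatibility(profile_scorer(), bundle)
  expect_false(rep1$compatible)
  expect_true("msa" %in% rep1$unmet)

  rep2 <- check_compatibility(kmer_embedder(), bundle)
  expect_true(rep2$compatible)

  rep3 <- check_compatibility(onehot_embedder(), bundle)
  expect_true("fixed_length" %in% rep3$unmet)

  expect_equal(bundle, snapshot)  # untouched
})

test_that("center-star alignment restores a consistent multiple alignment", {
  s <- protein_sequence_set(list(protein_sequence("a", "ACWDE"),
                                 protein_sequence("b", "ACDE"),
                                 protein_sequence("c", "AWDE"),
                                 protein_sequence("d", "CWDE")))
  fam <- center_star_align(s)
  expect_s3_class(fam, "aligned_family")
  expect_equal(sequence_ids(fam), sequence_ids(s))  # order preserved
  # removing gaps recovers the inputs
  expect_equal(gsub("-", "", sequence_residues(fam), fixed = TRUE),
               sequence_residues(s))
  expect_error(center_star_align(protein_sequence_set(list(
    protein_sequence("a", "ACD")))), class = "protzoo_validation")
})

test_that("score() is the Spearman correlation against bundle labels", {
  prof <- make_profile(width = 8, seed = 5)
  fam <- sample_family(prof, 400, seed = 6)
  wt <- profile_consensus(prof)
  lv <- labeled_variants(prof, wt, 25, noise_sd = 0, seed = 7)
  # random draws can repeat a variant; the duplicate-id warning is expected
  variants <- suppressWarnings(protein_sequence_set(lapply(lv$variants, function(m)
    apply_mutations(wt, m))))
  model <- fit(profile_scorer(alpha = 1), data_bundle(sequences = fam))
  # fitted on a finite sample: high but not perfect agreement with the truth
  s <- score(model, data_bundle(variants, labels = lv$labels))
  expect_gt(s, 0.8)
  expect_error(score(model, data_bundle(variants)), class = "protzoo_validation")
})
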
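test_that("column profile frequencies follow the pseudocount formula", {
  # 4 identical sequences, alpha = 0: observed symbol has frequency 1
  prof0 <- fit_column_profile(toy_family(rep("ACD", 4)), alpha = 0)
  expect_equal(unname(prof0$frequencies[1, "A"]), 1)
  expect_equal(unname(prof0$frequencies[2, "C"]), 1)
  expect_equal(rowSums(prof0$frequencies), rep(1, 3), tolerance = 1e-12)

  # column {A, C} over 2 sequences, alpha = 0 -> 0.5 / 0.5
  prof2 <- fit_column_profile(toy_family(c("A", "C")), alpha = 0)
  expect_equal(unname(prof2$frequencies[1, c("A", "C")]), c(0.5, 0.5))

  # column {A} over 1 sequence, alpha = 1 -> f(A) = 2/22, others 1/22
  prof1 <- fit_column_profile(toy_family("A"), alpha = 1)
  expect_equal(unname(prof1$frequencies[1, "A"]), 2 / 22)
  expect_equal(unname(prof1$frequencies[1, "C"]), 1 / 22)

  # gap is a counted symbol; X is excluded from counts and from the depth
  profg <- fit_column_profile(toy_family(c("-", "A", "X", "A")), alpha = 0)
  expect_equal(unname(profg$frequencies[1, "A"]), 2 / 3)
  expect_equal(unname(profg$frequencies[1, "-"]), 1 / 3)
  expect_equal(profg$counts_per_column, 3L)

  # alpha -> infinity limit approaches uniform 1/21
  profu <- fit_column_profile(toy_family(rep("ACD", 4)), alpha = 1e6)
  expect_equal(max(abs(profu$frequencies - 1 / 21)), 0, tolerance = 1e-3)
})

test_that("profile log-likelihood equals the brute-force product of frequencies", {
  prof0 <- fit_column_profile(toy_family(rep("ACD", 4)), alpha = 0)
  expect_equal(profile_loglik(prof0, protein_sequence("q", "ACD")), 0)

  # one column at 0.5, rest at 1 -> ln 0.5
  prof <- fit_column_profile(toy_family(c("ACD", "AWD")), alpha = 0)
  expect_equal(profile_loglik(prof, protein_sequence("q", "ACD")), log(0.5))

  set.seed(31)
  for (i in 1:15) {
    fam <- toy_family(vapply(1:6, function(.)
      random_residues(7, c(CANON, "-")), character(1)))
    p <- fit_column_profile(fam, alpha = 0.7)
    q <- protein_sequence("q", random_residues(7, c(CANON, "-", "X")))
    expect_equal(suppressWarnings(profile_loglik(p, q)),
                 oracle_loglik(p, q$residues), tolerance = 1e-12)
  }

  expect_error(profile_loglik(prof0, protein_sequence("q", "ACDE")),
               class = "protzoo_length_mismatch")
  expect_error(profile_loglik(prof0, protein_sequence("q", "WCD")),
               class = "protzoo_zero_frequency", regexp = "alpha > 0")
  expect_warning(profile_loglik(prof0, protein_sequence("q", "XCD")),
                 class = "protzoo_unknown_residue")
})

test_that("variant delta scores reduce to per-site frequency log-ratios", {
  fam <- toy_family(c("ACWD", "ACWD", "AWWD", "AC-D"))
  prof <- fit_column_profile(fam, alpha = 1)
  wt <- protein_sequence("wt", "ACWD")

  tab <- variant_delta_scores(prof, wt, list("", "C2W", "C2W:D4A"))
  expect_equal(tab$score[1], 0)  # empty variant scores exactly 0

  # reduced formula equals the full-sequence log-likelihood difference
  mut <- apply_mutations(wt, parse_mutation_string("C2W"))
  full_delta <- profile_loglik(prof, mut) - profile_loglik(prof, wt)
  expect_equal(tab$score[2], full_delta, tolerance = 1e-12)

  # mutating toward the more frequent symbol at a column scores positive
  tab2 <- variant_delta_scores(prof, protein_sequence("wt", "AWWD"), list("W2C"))
  expect_gt(tab2$score[1], 0)
  expect_equal(tab2$score[1], -tab$score[2], tolerance = 1e-12)

  expect_error(variant_delta_scores(prof, wt, list("G1C")),
               class = "protzoo_wt_mismatch")
})

test_that("wild types not matching the profile width are aligned, insertions error", {
  fam <- toy_family(rep("ACWDE", 5))
  prof <- fit_column_profile(fam, alpha = 1)
  # shorter wild type: positions map through the profile alignment
  wt <- protein_sequence("wt", "ACDE")        # aligned as AC-DE
  tab <- variant_delta_scores(prof, wt, list("D3W"))
  direct <- log(prof$frequencies[4, "W"]) - log(prof$frequencies[4, "D"])
  expect_equal(tab$score[1], unname(direct), tolerance = 1e-12)

  # longer wild type: the inserted position maps to no column
  wt2 <- protein_sequence("wt", "ACWWDE")
  expect_error(variant_delta_scores(prof, wt2, list("W3A")),
               class = "protzoo_mapping")
})

test_that("masked, wild-type and mutant marginals collapse on a context-free backend", {
  set.seed(41)
  for (i in 1:10) {
    prof <- make_profile(width = 9, concentration = 0.5, seed = 500 + i)
    wt <- profile_consensus(prof)
    backend <- profile_conditional_model(prof)
    lv <- labeled_variants(prof, wt, 5, seed = 600 + i)
    for (muts in lv$variants) {
      ms <- vapply(c("masked", "wildtype", "mutant"), function(mode)
        marginal_score(backend, wt, muts, mode), numeric(1))
      expect_lt(max(ms) - min(ms), 1e-9)
      # equal to the direct profile delta log-likelihood
      direct <- variant_delta_scores(prof, wt, list(muts))$score
      expect_equal(unname(ms["masked"]), direct, tolerance = 1e-9)
    }
  }
})

test_that("masked-mode scores are additive over disjoint mutations when context-free", {
  prof <- make_profile(width = 12, seed = 77)
  wt <- profile_consensus(prof)
  backend <- profile_conditional_model(prof)
  wt_chars <- strsplit(wt$residues, "")[[1]]
  m1 <- mutation_spec(wt_chars[2], 2, setdiff(CANON, wt_chars[2])[1])
  m2 <- mutation_spec(wt_chars[8], 8, setdiff(CANON, wt_chars[8])[3])
  double <- marginal_score(backend, wt, list(m1, m2), "masked")
  singles <- marginal_score(backend, wt, list(m1), "masked") +
    marginal_score(backend, wt, list(m2), "masked")
  expect_equal(double, singles, tolerance = 1e-12)
  expect_equal(marginal_score(backend, wt, list(), "masked"), 0)
  expect_equal(marginal_score(backend, wt, list(), "mutant"), 0)
})

test_that("backends violating the distribution contract are rejected", {
  bad <- structure(list(), class = c("bad_backend", "conditional_sequence_model"))
  registerS3method("residue_distribution", "bad_backend",
                   function(model, context, position, masked = FALSE)
                     rep(0.05, 20),  # unnamed: contract violation
                   envir = asNamespace("protzoo"))
  wt <- protein_sequence("wt", "ACD")
  expect_error(marginal_score(bad, wt, list(mutation_spec("A", 1, "C"))),
               class = "protzoo_model_contract")
})

test_that("profile and marginal scorers run the full lifecycle end to end", {
  prof <- make_profile(width = 10, seed = 13)
  fam <- sample_family(prof, 50, seed = 14)
  wt <- profile_consensus(prof)
  variants <- saturation_mutagenesis(wt, positions = c(2, 5))

  ps <- fit(profile_scorer(alpha = 1), data_bundle(sequences = fam))
  lls <- predict(ps, variants)
  expect_length(lls, 38)
  expect_true(all(is.finite(lls)))
  tab <- score_variants(ps, wt, as.list(paste0(sub("^.*_", "", sequence_ids(variants)))))
  expect_equal(nrow(tab), 38)

  ms <- fit(marginal_scorer(mode = "wildtype", alpha = 1),
            data_bundle(sequences = fam, wild_type = wt))
  preds <- predict(ms, variants)
  expect_length(preds, 38)
  # wild type itself scores 0 under every marginal protocol
  expect_equal(unname(predict(ms, protein_sequence_set(list(wt)))), 0)
})
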
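test_that("fixed one-hot encoding places one indicator per position", {
  mat <- onehot_encode(protein_sequence_set(list(protein_sequence("s", "ACD"))))
  expect_equal(dim(mat), c(1L, 60L))
  expect_equal(sum(mat), 3)
  expect_equal(unname(mat[1, c("pos1_A", "pos2_C", "pos3_D")]), c(1, 1, 1))

  # X yields an all-zero block at its position
  xm <- onehot_encode(protein_sequence_set(list(protein_sequence("s", "AXD"))))
  expect_equal(sum(xm[1, paste0("pos2_", CANON)]), 0)
  expect_equal(sum(xm), 2)

  expect_error(onehot_encode(protein_sequence_set(list(
    protein_sequence("a", "ACD"), protein_sequence("b", "AC")))),
    class = "protzoo_fixed_length")
  expect_error(onehot_encode(protein_sequence_set(list(
    protein_sequence("a", "A-D")))), class = "protzoo_validation",
    regexp = "aligned")
})

test_that("one-hot encode/decode is a bijection on X-free sequences", {
  set.seed(21)
  s <- random_set(40, 15)
  mat <- onehot_encode(s)
  expect_equal(onehot_decode(mat), stats::setNames(sequence_residues(s),
                                                   sequence_ids(s)))
  expect_equal(anyDuplicated(mat), 0L)
})

test_that("aligned one-hot state has 21 channels per column and rows sum to W", {
  fam <- toy_family(c("ACW-", "AC-D", "ACWD"))
  model <- fit(onehot_aligned_embedder(), data_bundle(sequences = fam))
  expect_equal(model$state$width, 4L)

  # refit on the same MSA gives the identical state
  expect_identical(fit(model, data_bundle(sequences = fam))$state, model$state)

  # width-W gapped input is encoded directly
  direct <- transform(model, protein_sequence_set(list(
    protein_sequence("q", "AC-D"))))
  expect_equal(dim(direct), c(1L, 84L))  # 21 * 4
  expect_equal(unname(rowSums(direct)), 4)
  expect_equal(unname(direct[1, "col3_gap"]), 1)

  # gap-free shorter input goes through align-to-profile; row still sums to W
  short <- transform(model, protein_sequence_set(list(
    protein_sequence("q", "ACD"))))
  expect_equal(unname(rowSums(short)), 4)
  expect_equal(sum(short[1, grepl("_gap$", colnames(short))]), 1)
})

test_that("align_to_profile returns the consensus unchanged and fixed width", {
  fam <- toy_family(rep("ACWDE", 4))
  prof <- fit_column_profile(fam, alpha = 1)

  aln <- align_to_profile(protein_sequence("q", "ACWDE"), prof)
  expect_equal(as.character(aln), "ACWDE")
  expect_equal(attr(aln, "mapping"), 1:5)

  # consensus with one residue deleted: exactly one gap appears
  del <- align_to_profile(protein_sequence("q", "ACDE"), prof)
  expect_equal(nchar(as.character(del)), 5L)
  expect_equal(lengths(regmatches(del, gregexpr("-", del))), 1L)

  # query longer than the profile: output width still W
  long <- align_to_profile(protein_sequence("q", "ACWWDE"), prof)
  expect_equal(nchar(as.character(long)), 5L)
  expect_equal(sum(is.na(attr(long, "mapping"))), 1L)

  expect_error(align_to_profile(protein_sequence("q", "A-C"), prof),
               class = "protzoo_validation")
})

test_that("profile alignment DP matches exhaustive enumeration on small instances", {
  set.seed(17)
  for (rep in 1:60) {
    W <- sample(2:6, 1)
    L <- sample(2:6, 1)
    prof <- make_profile(W, concentration = 0.7, seed = 1000 + rep)
    residues <- random_residues(L)
    aln <- align_to_profile(protein_sequence("q", residues), prof)
    best <- oracle_profile_align_score(residues, prof)
    expect_equal(attr(aln, "score"), best, tolerance = 1e-9)
    # and the emitted alignment actually achieves the optimal score
    expect_equal(realized_align_score(aln, residues, prof), best,
                 tolerance = 1e-9)
  }
})

test_that("k-mer counts enumerate windows and respect the dimension cap", {
  s1 <- protein_sequence_set(list(protein_sequence("s", "AAA")))
  m <- kmer_counts(s1, k = 2)
  expect_equal(dim(m), c(1L, 400L))
  expect_equal(unname(m[1, "kmer_AA"]), 2)
  expect_equal(sum(m), 2)

  # row sum is L - k + 1 for X-free sequences
  set.seed(9)
  s <- random_set(10, 12)
  for (k in 1:3) expect_equal(unname(rowSums(kmer_counts(s, k))),
                              rep(12 - k + 1, 10))

  # windows containing X are skipped
  xz <- kmer_counts(protein_sequence_set(list(protein_sequence("s", "AXA"))), k = 2)
  expect_equal(sum(xz), 0)

  # k-mer columns are lexicographic over the canonical alphabet
  expect_equal(colnames(kmer_counts(s1, k = 1))[1:3],
               c("kmer_A", "kmer_C", "kmer_D"))
  expect_equal(colnames(m)[1:2], c("kmer_AA", "kmer_AC"))

  expect_error(kmer_counts(s1, k = 4), class = "protzoo_params")
  expect_error(kmer_counts(protein_sequence_set(list(
    protein_sequence("g", "A-A"))), k = 2), class = "protzoo_validation")
  expect_warning(short <- kmer_counts(protein_sequence_set(list(
    protein_sequence("s", "A"))), k = 2), class = "protzoo_short_sequence")
  expect_equal(sum(short), 0)

  # normalization divides by counted windows
  nm <- kmer_counts(s1, k = 2, normalize = TRUE)
  expect_equal(unname(nm[1, "kmer_AA"]), 1)

  # row-wise permutation invariance of the set order
  perm <- kmer_counts(s[c(3, 1, 2, 10, 4:9)], k = 2)
  full <- kmer_counts(s, k = 2)
  expect_equal(perm["r3", ], full["r3", ])
})
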
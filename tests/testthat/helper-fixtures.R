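# Fixtures and independent oracles. Everything is generated in code; the
# oracles deliberately use brute-force enumeration or direct closed forms so
# they share no code path with the implementation they check.

CANON <- canonical_alphabet()

random_residues <- function(L, alphabet = CANON) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

random_set <- function(n, L, prefix = "r") {
  protein_sequence_set(lapply(seq_len(n), function(i)
    protein_sequence(paste0(prefix, i), random_residues(L))))
}

toy_family <- function(rows, prefix = "t") {
  aligned_family(protein_sequence_set(lapply(seq_along(rows), function(i)
    protein_sequence(paste0(prefix, i), rows[i]))))
}

# fixed-width PDB ATOM line builder for synthetic structure fixtures
pdb_atom_line <- function(serial, name, resname, chain, resno,
                          alt = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, icode,
          1.0, 2.0, 3.0, 1.0, 0.0, substr(name, 1, 1))
}

toy_pdb_text <- function(resnames, chain = "A", resnos = seq_along(resnames),
                         with_n_atoms = TRUE) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resnames)) {
    if (with_n_atoms) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "N", resnames[i], chain, resnos[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, "CA", resnames[i], chain, resnos[i]))
  }
  paste(c(lines, "END"), collapse = "\n")
}

# brute-force optimal profile-alignment score: enumerate every monotone
# assignment of m query residues to m columns (0 <= m <= min(L, W)); unmatched
# columns are deletions, unmatched query residues insertions
oracle_profile_align_score <- function(residues, profile,
                                       d_del = -1.5, d_ins = -1.5,
                                       eps = 1e-9) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars); W <- profile$width
  match_score <- function(i, j) {
    if (chars[i] == "X") return(0)
    unname(log(profile$frequencies[j, chars[i]] + eps) - log(1 / 20))
  }
  best <- -Inf
  for (m in 0:min(L, W)) {
    qsets <- if (m == 0) list(integer(0)) else
      asplit(utils::combn(L, m), 2L)
    csets <- if (m == 0) list(integer(0)) else
      asplit(utils::combn(W, m), 2L)
    for (q in qsets) for (cc in csets) {
      s <- (W - m) * d_del + (L - m) * d_ins
      if (m > 0) s <- s + sum(vapply(seq_len(m), function(t)
        match_score(q[t], cc[t]), numeric(1)))
      if (s > best) best <- s
    }
  }
  best
}

# score of the alignment the DP actually emitted, recomputed from its output
realized_align_score <- function(aln, residues, profile,
                                 d_del = -1.5, d_ins = -1.5, eps = 1e-9) {
  mapping <- attr(aln, "mapping")
  chars <- strsplit(residues, "")[[1]]
  matched <- which(!is.na(mapping))
  s <- (profile$width - length(matched)) * d_del +
    (length(chars) - length(matched)) * d_ins
  for (i in matched) {
    s <- s + if (chars[i] == "X") 0 else
      unname(log(profile$frequencies[mapping[i], chars[i]] + eps) - log(1 / 20))
  }
  s
}

# closed-form sequence log-likelihood: product of column frequencies, logged
oracle_loglik <- function(profile, residues) {
  chars <- strsplit(residues, "")[[1]]
  p <- 1
  for (j in seq_along(chars)) {
    if (chars[j] == "X") next
    p <- p * unname(profile$frequencies[j, chars[j]])
  }
  log(p)
}
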
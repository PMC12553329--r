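# Dependency-free deterministic alignment used for "attempt to align"
# remediation: global pairwise DP and center-star progressive merging.
# Scoring is deliberately simple (match +1, mismatch 0, linear gap -1); this
# is a remediation step, not a competitive aligner.

#' Global pairwise alignment
#'
#' Needleman-Wunsch with match \code{+1}, mismatch \code{0} and linear gap
#' penalty \code{-1}. Traceback is deterministic: ties prefer a
#' match/mismatch step, then a gap placed in the second sequence, then a gap
#' in the first.
#'
#' @param a,b Residue strings (gap-free).
#' @return List with \code{a_aln}, \code{b_aln} (equal-length gapped strings)
#'   and \code{score}.
#' @export
pairwise_align <- function(a, b) {
  ca <- split_chars(a); cb <- split_chars(b)
  n <- length(ca); m <- length(cb)
  gap <- -1
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    match_row <- ifelse(ca[i] == cb, 1, 0)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + match_row[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, preference: diagonal > up (gap in b) > left (gap in a)
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (ca[i] == cb[j]) 1 else 0)) {
      ra <- c(ca[i], ra); rb <- c(cb[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(ca[i], ra); rb <- c(PZ_GAP, rb); i <- i - 1L
    } else {
      ra <- c(PZ_GAP, ra); rb <- c(cb[j], rb); j <- j - 1L
    }
  }
  list(a_aln = paste(ra, collapse = ""), b_aln = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

# insert gap columns (positions given in the *target* coordinate system) into
# an aligned string
insert_gaps <- function(s, at) {
  if (length(at) == 0L) return(s)
  chars <- split_chars(s)
  out <- character(nchar(s) + length(at))
  out[at] <- PZ_GAP
  out[setdiff(seq_along(out), at)] <- chars
  paste(out, collapse = "")
}

#' Center-star multiple alignment
#'
#' Chooses the member maximizing summed pairwise alignment score against all
#' others (ties: lowest index) as the center, then merges the pairwise
#' center-vs-member alignments under the "once a gap, always a gap" rule.
#' Pre-existing gap characters are removed before aligning. Member order is
#' preserved.
#'
#' @param sequences A [protein_sequence_set()] with at least 2 members.
#' @return An [aligned_family()].
#' @export
center_star_align <- function(sequences) {
  stopifnot(inherits(sequences, "protein_sequence_set"))
  n <- length(sequences)
  if (n < 2L)
    pz_stop("validation", "center-star alignment needs at least 2 sequences")
  plain <- vapply(sequences, function(s) gsub(PZ_GAP, "", s$residues, fixed = TRUE),
                  character(1))
  if (any(!nzchar(plain))) pz_stop("validation", "all-gap sequence cannot be aligned")
  # pairwise score sums (symmetric; diagonal excluded)
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sc <- pairwise_align(plain[i], plain[j])$score
    tot[i] <- tot[i] + sc; tot[j] <- tot[j] + sc
  }
  center <- which.max(tot)  # which.max takes the lowest index on ties
  master <- plain[center]
  aligned <- stats::setNames(vector("list", n), NULL)
  aligned[[center]] <- master
  for (k in setdiff(seq_len(n), center)) {
    pw <- pairwise_align(plain[center], plain[k])
    ca <- split_chars(pw$a_aln)   # center within this pair
    ck <- split_chars(pw$b_aln)
    cm <- split_chars(master)
    # reconcile: walk both center renderings, inserting gaps on either side
    out_new <- character(0); ins_master <- integer(0)
    i <- 1L; j <- 1L; col <- 0L
    while (i <= length(cm) || j <= length(ca)) {
      col <- col + 1L
      mi <- if (i <= length(cm)) cm[i] else NULL
      aj <- if (j <= length(ca)) ca[j] else NULL
      if (!is.null(mi) && !is.null(aj) && (mi == aj ||
          (mi != PZ_GAP && aj != PZ_GAP))) {
        out_new <- c(out_new, ck[j]); i <- i + 1L; j <- j + 1L
      } else if (!is.null(mi) && mi == PZ_GAP) {
        out_new <- c(out_new, PZ_GAP); i <- i + 1L       # master gap: pad new
      } else {                                           # new gap: pad master
        out_new <- c(out_new, ck[j]); ins_master <- c(ins_master, col)
        j <- j + 1L
      }
    }
    if (length(ins_master)) {
      master <- insert_gaps(master, ins_master)
      for (idx in seq_len(n)) {
        if (idx != k && !is.null(aligned[[idx]]))
          aligned[[idx]] <- insert_gaps(aligned[[idx]], ins_master)
      }
    }
    aligned[[k]] <- paste(out_new, collapse = "")
  }
  aligned[[center]] <- master
  aligned_family(protein_sequence_set(lapply(seq_len(n), function(i)
    protein_sequence(sequences[[i]]$id, aligned[[i]]))))
}
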
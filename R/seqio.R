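# Protein sequence / alignment data types, FASTA-A2M I/O, mutation notation,
# and mutagenesis library generation.

#' Construct a validated protein sequence
#'
#' A \code{protein_sequence} couples an identifier with a residue string over
#' the canonical 20-letter alphabet plus \code{"X"} (unknown residue) and
#' \code{"-"} (alignment gap). Residues are validated at construction: the
#' string must be non-empty, uppercase, and contain no characters outside the
#' alphabet.
#'
#' @param id Non-empty record identifier.
#' @param residues Residue string (uppercase; \code{A2M} dialect should be
#'   normalized before construction, see [read_fasta()]).
#' @param structure_ref Optional path or identifier of an associated structure.
#' @return An object of class \code{protein_sequence} with fields \code{id},
#'   \code{residues} and \code{structure_ref}.
#' @export
#' @examples
#' protein_sequence("wt", "ACDW")
protein_sequence <- function(id, residues, structure_ref = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    pz_stop("validation", "sequence id must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      !nzchar(residues))
    pz_stop("validation", sprintf("sequence '%s': residues must be non-empty", id))
  chars <- split_chars(residues)
  bad <- which(!(chars %in% PZ_ALPHABET))
  if (length(bad))
    pz_stop("validation", sprintf(
      "sequence '%s': invalid residue '%s' at position %d (alphabet is %s plus 'X' and '-')",
      id, chars[bad[1]], bad[1], paste(PZ_CANONICAL, collapse = "")))
  structure(list(id = id, residues = residues, structure_ref = structure_ref),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d residues)\n", x$id, seq_width(x)))
  cat(" ", x$residues, "\n", sep = "")
  invisible(x)
}

seq_width <- function(seq) nchar(seq$residues)

seq_has_gap <- function(seq) grepl(PZ_GAP, seq$residues, fixed = TRUE)

#' Ordered collection of protein sequences
#'
#' The collection preserves insertion order (iteration is deterministic) and is
#' the common currency passed to models, analogous to the feature matrix of a
#' classical estimator. Duplicate ids are permitted -- alignments frequently
#' repeat ids -- but raise a warning; order disambiguates.
#'
#' @param sequences List of [protein_sequence()] objects (or a single one).
#' @return Object of class \code{protein_sequence_set}.
#' @export
protein_sequence_set <- function(sequences = list()) {
  if (inherits(sequences, "protein_sequence")) sequences <- list(sequences)
  if (!is.list(sequences) || !all(vapply(sequences, inherits, logical(1),
                                         "protein_sequence")))
    pz_stop("validation", "sequences must be a list of protein_sequence objects")
  ids <- vapply(sequences, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    pz_warn("duplicate_ids", sprintf(
      "duplicate sequence ids (%s); order disambiguates",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(unname(sequences), class = "protein_sequence_set")
}

#' @export
print.protein_sequence_set <- function(x, ...) {
  cat(sprintf("<protein_sequence_set> %d sequences%s\n", length(x),
              if (uniform_length(x) && length(x))
                sprintf(", uniform length %d", seq_width(x[[1]])) else ""))
  invisible(x)
}

#' @export
`[.protein_sequence_set` <- function(x, i) {
  structure(unclass(x)[i], class = class(x))
}

#' Sequence set accessors
#'
#' @param x A \code{protein_sequence_set}.
#' @return \code{sequence_ids} and \code{sequence_residues}: character vectors,
#'   one element per member; \code{uniform_length}: \code{TRUE} iff all members
#'   share one length (vacuously true when empty).
#' @export
sequence_ids <- function(x) vapply(x, `[[`, character(1), "id")

#' @rdname sequence_ids
#' @export
sequence_residues <- function(x) vapply(x, `[[`, character(1), "residues")

#' @rdname sequence_ids
#' @export
uniform_length <- function(x) {
  if (length(x) == 0L) return(TRUE)
  length(unique(nchar(sequence_residues(x)))) == 1L
}

#' Fixed-width aligned family (a multiple sequence alignment)
#'
#' An \code{aligned_family} is a \code{protein_sequence_set} whose members all
#' share one width. At least one member is required.
#'
#' @param sequences A \code{protein_sequence_set} or list of sequences, all of
#'   equal length.
#' @return Object of classes \code{aligned_family}, \code{protein_sequence_set}
#'   with attribute \code{width}.
#' @export
aligned_family <- function(sequences) {
  if (!inherits(sequences, "protein_sequence_set"))
    sequences <- protein_sequence_set(sequences)
  if (length(sequences) < 1L)
    pz_stop("validation", "an aligned family needs at least one member")
  widths <- nchar(sequence_residues(sequences))
  if (length(unique(widths)) != 1L)
    pz_stop("validation", sprintf(
      "aligned family members must share one width (found %s)",
      paste(unique(widths), collapse = ", ")))
  structure(unclass(sequences), width = widths[1],
            class = c("aligned_family", "protein_sequence_set"))
}

#' @rdname aligned_family
#' @param x An \code{aligned_family}.
#' @export
family_width <- function(x) attr(x, "width")

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %d sequences x %d columns\n",
              length(x), family_width(x)))
  invisible(x)
}

# ---- FASTA / A2M I/O ---------------------------------------------------------

#' Read FASTA / A2M sequences
#'
#' Accepts a file path or FASTA-formatted text. Records may be line-wrapped.
#' The A2M dialect is tolerated: lowercase residues are uppercased and
#' \code{'.'} is normalized to the gap character \code{'-'} before validation.
#' Record order is preserved.
#'
#' @param x Path to a FASTA file, or a character string of FASTA text (text is
#'   recognized by a leading \code{'>'} or an embedded newline).
#' @return A [protein_sequence_set()].
#' @export
#' @examples
#' read_fasta(">a\nACD\n>b\nWYV\n")
read_fasta <- function(x) {
  if (!is.character(x) || length(x) != 1L)
    pz_stop("format", "input must be a single path or FASTA text string")
  is_text <- startsWith(trimws(x), ">") || grepl("\n", x, fixed = TRUE)
  con <- if (is_text) textConnection(x) else x
  if (is_text) on.exit(try(close(con), silent = TRUE), add = TRUE)
  if (!is_text && !file.exists(x))
    pz_stop("io", sprintf("no such file: %s", x))
  raw <- tryCatch(
    seqinr::read.fasta(con, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE, whole.header = TRUE),
    error = function(e) pz_stop("format", paste("not FASTA:", conditionMessage(e))))
  if (length(raw) == 0L) pz_stop("format", "empty FASTA input")
  seqs <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    id <- trimws(names(raw)[i])
    residues <- chartr(".", PZ_GAP, toupper(raw[[i]]))
    seqs[[i]] <- protein_sequence(id, residues)
  }
  protein_sequence_set(seqs)
}

#' Write sequences as FASTA
#'
#' Residue lines are wrapped at 80 columns. [read_fasta()] of the written file
#' reproduces ids and residues exactly.
#'
#' @param x A \code{protein_sequence_set} (or single \code{protein_sequence}).
#' @param path Destination file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "protein_sequence")) x <- protein_sequence_set(x)
  stopifnot(inherits(x, "protein_sequence_set"))
  ok <- tryCatch({
    seqinr::write.fasta(as.list(sequence_residues(x)), sequence_ids(x),
                        file.out = path, as.string = TRUE, nbchar = 80)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    pz_stop("io", sprintf("cannot write FASTA to '%s'", path))
  invisible(path)
}

# ---- mutation notation -------------------------------------------------------

#' Mutation specification
#'
#' A single substitution \code{(wild-type residue, 1-based position, mutant
#' residue)}, written \code{"A2C"}. Positions are 1-based on the ungapped
#' wild-type sequence -- the universal deep-mutational-scanning convention.
#' Both residues must be canonical and must differ.
#'
#' @param wt_aa,mut_aa Canonical one-letter residue codes.
#' @param position Integer position, \code{>= 1}.
#' @return Object of class \code{mutation_spec}.
#' @export
mutation_spec <- function(wt_aa, position, mut_aa) {
  if (!is_canonical(wt_aa) || !is_canonical(mut_aa))
    pz_stop("parse", sprintf("mutation residues must be canonical (got '%s','%s')",
                             wt_aa, mut_aa))
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    pz_stop("parse", "mutation position must be an integer >= 1")
  if (wt_aa == mut_aa)
    pz_stop("parse", sprintf("wild-type and mutant residue are both '%s' at %d",
                             wt_aa, position))
  structure(list(wt_aa = wt_aa, position = position, mut_aa = mut_aa),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) paste0(x$wt_aa, x$position, x$mut_aa)

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec>", format(x), "\n"); invisible(x)
}

#' Collapse a list of mutations to its string form
#'
#' @param muts List of [mutation_spec()] objects.
#' @return A string such as \code{"A2C:G5W"}; \code{""} for an empty list.
#' @export
mutation_string <- function(muts) {
  paste(vapply(muts, format, character(1)), collapse = ":")
}

#' Parse mutation notation
#'
#' Parses one token or colon-separated tokens of the form
#' \code{<wt><position><mut>}, e.g. \code{"A2C"} or \code{"A2C:G5W"}. Order is
#' preserved.
#'
#' @param s Mutation string.
#' @return List of [mutation_spec()].
#' @export
parse_mutation_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(trimws(s)))
    pz_stop("parse", "mutation string must be a non-empty string")
  tokens <- strsplit(trimws(s), ":", fixed = TRUE)[[1]]
  lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z])$", tok))[[1]]
    if (length(m) != 4L)
      pz_stop("parse", sprintf("malformed mutation token '%s' (expected e.g. 'A2C')", tok))
    mutation_spec(m[2], as.integer(m[3]), m[4])
  })
}

#' Read a mutation list file
#'
#' One mutation string per line; \code{'#'} starts a comment; blank lines are
#' skipped.
#'
#' @param path File path.
#' @return List of mutation lists (one per non-comment line).
#' @export
read_mutation_file <- function(path) {
  if (!file.exists(path)) pz_stop("io", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_mutation_string)
}

#' Apply substitutions to a sequence
#'
#' Each mutation is checked against the sequence: the position must be in
#' range and the residue found there must equal the mutation's wild-type
#' residue. A new sequence is returned (the input is not modified); its id is
#' suffixed with the mutation string unless the list is empty.
#'
#' @param seq A gap-aware [protein_sequence()]; positions index its residues
#'   directly, so variant scoring applies mutations to ungapped wild types.
#' @param muts List of [mutation_spec()].
#' @return A new \code{protein_sequence}.
#' @export
#' @examples
#' apply_mutations(protein_sequence("wt", "ACD"), parse_mutation_string("A1C"))
apply_mutations <- function(seq, muts) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (length(muts) == 0L) return(seq)
  chars <- split_chars(seq$residues)
  for (m in muts) {
    if (m$position > length(chars))
      pz_stop("range", sprintf("mutation %s: position %d beyond sequence length %d",
                               format(m), m$position, length(chars)))
    found <- chars[m$position]
    if (found != m$wt_aa)
      pz_stop("wt_mismatch", sprintf(
        "mutation %s: expected wild-type '%s' at position %d but found '%s'",
        format(m), m$wt_aa, m$position, found))
    chars[m$position] <- m$mut_aa
  }
  protein_sequence(paste0(seq$id, "_", mutation_string(muts)),
                   paste(chars, collapse = ""),
                   structure_ref = seq$structure_ref)
}

#' Differences between two equal-length sequences
#'
#' Returns the minimal substitution list taking \code{a} to \code{b}, sorted by
#' position: \code{apply_mutations(a, diff_sequences(a, b))} reproduces
#' \code{b}'s residues. Both sequences must be gap-free and of equal length;
#' unequal lengths require alignment first.
#'
#' @param a,b [protein_sequence()] objects.
#' @return List of [mutation_spec()] (empty when identical).
#' @export
diff_sequences <- function(a, b) {
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  if (seq_has_gap(a) || seq_has_gap(b))
    pz_stop("validation", "diff_sequences requires gap-free sequences")
  if (seq_width(a) != seq_width(b))
    pz_stop("length_mismatch", sprintf(
      "sequences differ in length (%d vs %d); align them first",
      seq_width(a), seq_width(b)))
  ca <- split_chars(a$residues); cb <- split_chars(b$residues)
  pos <- which(ca != cb)
  lapply(pos, function(i) mutation_spec(ca[i], i, cb[i]))
}

#' Saturation mutagenesis library
#'
#' All single substitutions to the other 19 canonical residues at each selected
#' position, in deterministic position-major, alphabet-minor order. Variant ids
#' are the wild-type id suffixed with the mutation string. Positions holding
#' the unknown residue \code{'X'} cannot be mutated.
#'
#' @param seq Gap-free wild-type [protein_sequence()].
#' @param positions Optional integer vector of 1-based positions (default: all).
#' @return A [protein_sequence_set()] of \code{19 * length(positions)} variants.
#' @export
saturation_mutagenesis <- function(seq, positions = NULL) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (seq_has_gap(seq))
    pz_stop("validation", "saturation mutagenesis requires a gap-free sequence")
  L <- seq_width(seq)
  if (is.null(positions)) positions <- seq_len(L)
  positions <- as.integer(positions)
  if (any(is.na(positions) | positions < 1L | positions > L))
    pz_stop("range", sprintf("positions must lie in 1..%d", L))
  chars <- split_chars(seq$residues)
  variants <- list()
  for (p in positions) {
    wt <- chars[p]
    if (!is_canonical(wt))
      pz_stop("validation", sprintf(
        "position %d holds non-canonical residue '%s'; cannot mutate", p, wt))
    for (aa in PZ_CANONICAL) {
      if (aa == wt) next
      variants[[length(variants) + 1L]] <-
        apply_mutations(seq, list(mutation_spec(wt, p, aa)))
    }
  }
  protein_sequence_set(variants)
}

#' Remove gaps from a sequence
#'
#' @param seq A [protein_sequence()].
#' @return List with \code{sequence} (the ungapped \code{protein_sequence}) and
#'   \code{mapping}, an integer vector giving, for each ungapped position, its
#'   1-based index in the original gapped string.
#' @export
#' @examples
#' ungap(protein_sequence("s", "A-C"))$mapping  # 1 3
ungap <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  chars <- split_chars(seq$residues)
  keep <- which(chars != PZ_GAP)
  if (length(keep) == 0L)
    pz_stop("validation", sprintf("sequence '%s' is all gaps", seq$id))
  list(sequence = protein_sequence(seq$id, paste(chars[keep], collapse = ""),
                                   structure_ref = seq$structure_ref),
       mapping = keep)
}
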
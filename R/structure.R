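# Minimal structure handling: enough PDB awareness to extract a chain's
# residue sequence and to validate sequence/structure consistency for
# structure-requiring models. Coordinates and geometry are out of scope.

#' Extract a chain's residue sequence from a PDB file
#'
#' Parses ATOM records only (HETATM is ignored). A residue is counted once per
#' distinct (residue number, insertion code) that has a CA atom, in file
#' order -- CA presence defines a residue, which is robust to missing side
#' chains. Alternate locations other than blank or \code{'A'} are discarded.
#' Three-letter residue codes are mapped to one-letter codes; unknown codes
#' become \code{'X'}.
#'
#' @param pdb Path to a PDB file, or PDB-formatted text (recognized by an
#'   embedded newline or a leading record keyword).
#' @param chain_id Single chain identifier character.
#' @return A \code{structure_record}: list with \code{source}, \code{chain_id},
#'   \code{residue_sequence} (a [protein_sequence()]) and
#'   \code{residue_numbers} (author numbering, order of appearance).
#' @export
parse_chain_sequence <- function(pdb, chain_id) {
  if (!is.character(chain_id) || length(chain_id) != 1L || nchar(chain_id) != 1L)
    pz_stop("validation", "chain_id must be a single character")
  is_text <- grepl("\n", pdb, fixed = TRUE) ||
    grepl("^(ATOM|HETATM|HEADER|MODEL)", pdb)
  path <- pdb
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
  } else if (!file.exists(pdb)) {
    pz_stop("io", sprintf("no such file: %s", pdb))
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) pz_stop("format", paste("cannot parse PDB:", conditionMessage(e))))
  atoms <- parsed$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) pz_stop("format", "no ATOM records in input")
  have <- sort(unique(atoms$chain))
  if (!chain_id %in% have)
    pz_stop("chain_absent", sprintf("chain '%s' not found; available chains: %s",
                                    chain_id, paste(have, collapse = ", ")))
  atoms <- atoms[atoms$chain == chain_id & atoms$elety == "CA", , drop = FALSE]
  alt <- atoms$alt
  atoms <- atoms[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  if (nrow(atoms) == 0L)
    pz_stop("format", sprintf("chain '%s' has no CA atoms", chain_id))
  ic <- ifelse(is.na(atoms$insert), "", atoms$insert)
  key <- paste(atoms$resno, ic, sep = "|")
  keep <- !duplicated(key)
  resid <- atoms$resid[keep]
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !nzchar(one) | !(one %in% c(PZ_CANONICAL, PZ_UNKNOWN))] <- PZ_UNKNOWN
  src <- if (is_text) "<text>" else pdb
  structure(list(
    source = src,
    chain_id = chain_id,
    residue_sequence = protein_sequence(
      paste0(basename(src), "_", chain_id), paste(one, collapse = "")),
    residue_numbers = as.integer(atoms$resno[keep])
  ), class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s chain %s, %d residues\n",
              x$source, x$chain_id, length(x$residue_numbers)))
  invisible(x)
}

#' Compare a sequence against a structure's residue sequence
#'
#' The sequence is ungapped before comparison. Failure is encoded in the
#' report, never raised.
#'
#' @param seq A [protein_sequence()].
#' @param rec A \code{structure_record} from [parse_chain_sequence()].
#' @return List with \code{exact_match} (logical), \code{mismatches} (integer
#'   positions where residues differ, over the shared prefix length) and
#'   \code{length_difference} (sequence length minus structure length).
#' @export
check_sequence_structure_match <- function(seq, rec) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(rec, "structure_record"))
  s <- ungap(seq)$sequence$residues
  t <- rec$residue_sequence$residues
  n <- min(nchar(s), nchar(t))
  cs <- split_chars(s)[seq_len(n)]
  ct <- split_chars(t)[seq_len(n)]
  mism <- which(cs != ct)
  list(exact_match = nchar(s) == nchar(t) && length(mism) == 0L,
       mismatches = as.integer(mism),
       length_difference = nchar(s) - nchar(t))
}
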
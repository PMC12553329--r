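# Canonical residue alphabet. The ordering here is the single source of truth
# for every channel layout in the package (one-hot columns, k-mer lexicographic
# order, profile rows): changing it would silently re-index every embedding.

#' The canonical amino-acid alphabet
#'
#' Twenty one-letter residue codes in the fixed order
#' \code{"ACDEFGHIKLMNPQRSTVWY"}. All channel indices in the package (one-hot
#' positions, k-mer lexicographic order, profile columns) are derived from this
#' ordering. The gap symbol \code{"-"} is never a member of the canonical set;
#' layouts that include it place it after the 20 canonical channels. The
#' unknown-residue symbol is \code{"X"}.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' canonical_alphabet()
canonical_alphabet <- function() PZ_CANONICAL

PZ_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PZ_GAP <- "-"
PZ_UNKNOWN <- "X"
PZ_ALPHABET <- c(PZ_CANONICAL, PZ_UNKNOWN, PZ_GAP)
# profile alphabet: 20 canonical + gap, gap last
PZ_PROFILE_ALPHABET <- c(PZ_CANONICAL, PZ_GAP)

# index of each canonical residue (1..20); X and '-' deliberately absent
PZ_CANONICAL_INDEX <- stats::setNames(seq_along(PZ_CANONICAL), PZ_CANONICAL)

is_canonical <- function(chars) chars %in% PZ_CANONICAL

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# ---- classed conditions ------------------------------------------------------
# Every error/warning the package raises carries a machine-readable event code
# as a condition class "protzoo_<code>", so callers can handle them by code
# rather than by message text.

pz_stop <- function(code, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("protzoo_", code), "protzoo_error"),
                      call = call))
}

pz_warn <- function(code, msg) {
  warning(warningCondition(msg, class = c(paste0("protzoo_", code),
                                          "protzoo_warning")))
}
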
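#' Validate and normalize an RNA sequence
#'
#' Sequences are plain character strings over the alphabet `A`, `C`, `G`, `U`.
#' Lowercase input is uppercased.  `T` is either rejected (the default) or
#' transliterated to `U` when `transliterate = TRUE`, which is the policy used
#' by the FASTA reader.
#'
#' @param x Character scalar, the candidate sequence.
#' @param transliterate If `TRUE`, convert `T` to `U` instead of failing.
#' @param max_len Maximum allowed length (guards the cubic-time folding
#'   engine); default 400 nt.
#' @return The normalized sequence string.
#' @export
validate_rna <- function(x, transliterate = FALSE, max_len = 400L) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("sequence must be a single character string", class = "ribochain_input_error")
  }
  x <- toupper(x)
  if (transliterate) x <- gsub("T", "U", x, fixed = TRUE)
  if (nchar(x) == 0L) {
    abort("sequence must be non-empty", class = "ribochain_input_error")
  }
  if (nchar(x) > max_len) {
    abort(sprintf("sequence longer than the configured maximum (%d nt)", max_len),
          class = "ribochain_input_error")
  }
  bad <- gsub("[ACGU]", "", x)
  if (nchar(bad) > 0L) {
    abort(sprintf("invalid residues in sequence: %s",
                  paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
          class = "ribochain_input_error")
  }
  x
}

seq_codes <- function(x) {
  # A=0, C=1, G=2, U=3 (the encoding used by the C++ engine)
  match(strsplit(x, "")[[1]], c("A", "C", "G", "U")) - 1L
}

#' Reverse complement of an RNA sequence
#'
#' @param x RNA sequence string.
#' @return The reverse complement, 5' to 3'.
#' @export
revcomp_rna <- function(x) {
  x <- validate_rna(x)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

complement_base <- function(b) c(A = "U", C = "G", G = "C", U = "A")[[b]]

#' Construct an annotated RNA species
#'
#' A light container pairing a sequence with an identifier and a network
#' role.  Most functions accept bare strings; this is mainly used when
#' building [network_spec()] species tables.
#'
#' @param residues Sequence string (may be `NA` for a species that is yet to
#'   be designed, in which case `length` must be given).
#' @param id Identifier.
#' @param role One of `"SR"`, `"SRR"`, `"SRRR"`, `"GENERIC"`.
#' @param length Length in nt, required when `residues` is `NA`.
#' @return A list of class `rna_species`.
#' @export
rna_species <- function(residues, id, role = "GENERIC", length = NULL) {
  role <- match.arg(role, c("SR", "SRR", "SRRR", "GENERIC"))
  if (is.na(residues)) {
    if (is.null(length)) abort("length required for an unassigned species",
                               class = "ribochain_input_error")
    len <- as.integer(length)
  } else {
    residues <- validate_rna(residues)
    len <- nchar(residues)
  }
  structure(list(id = id, residues = residues, role = role, length = len),
            class = "rna_species")
}

# -- windows -----------------------------------------------------------------
# All windows in the package are 0-based, half-open integer pairs [start, end),
# matching their serialized form in network YAML files.

check_window <- function(window, len, what = "window") {
  if (length(window) != 2L || any(is.na(window))) {
    abort(sprintf("%s must be a [start, end) integer pair", what),
          class = "ribochain_input_error")
  }
  window <- as.integer(window)
  if (window[1] < 0L || window[2] > len || window[1] > window[2]) {
    abort(sprintf("%s [%d, %d) out of bounds for length %d",
                  what, window[1], window[2], len),
          class = "ribochain_input_error")
  }
  window
}
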
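#' Parse dot-bracket notation
#'
#' Accepts single- or multi-strand structures; `&` marks a nick between
#' strands (the nick position is recorded in the concatenated 0-based
#' coordinate system).  Matched `()` are base pairs, `.` is unpaired.
#'
#' @param x Dot-bracket string.
#' @return A list with `db` (the string without `&`), `pairs` (two-column
#'   integer matrix of 0-based index pairs, i < j), `cuts` (0-based nick
#'   positions, i.e. the index of the first residue after each nick) and
#'   `length` (number of residues).
#' @export
parse_dotbracket <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("dot-bracket must be a single string", class = "ribochain_parse_error")
  }
  chars <- strsplit(x, "")[[1]]
  cuts <- integer(0)
  clean <- character(0)
  for (ch in chars) {
    if (ch == "&") {
      cuts <- c(cuts, length(clean))
    } else if (ch %in% c("(", ")", ".")) {
      clean <- c(clean, ch)
    } else {
      abort(sprintf("invalid dot-bracket character '%s' at column %d",
                    ch, length(clean) + length(cuts) + 1L),
            class = "ribochain_parse_error")
    }
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(clean)) {
    if (clean[i] == "(") {
      stack <- c(stack, i)
    } else if (clean[i] == ")") {
      if (length(stack) == 0L) {
        abort(sprintf("unbalanced ')' at column %d", i),
              class = "ribochain_parse_error")
      }
      pairs <- rbind(pairs, c(stack[length(stack)] - 1L, i - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    abort(sprintf("unbalanced '(' at column %d", stack[length(stack)]),
          class = "ribochain_parse_error")
  }
  ord <- order(pairs[, 1])
  list(db = paste(clean, collapse = ""),
       pairs = pairs[ord, , drop = FALSE],
       cuts = cuts, length = length(clean))
}

#' Serialize a pair set to dot-bracket
#'
#' @param pairs Two-column matrix of 0-based pairs (i < j).
#' @param length Number of residues.
#' @param cuts Optional 0-based nick positions at which `&` is inserted.
#' @return Dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, length, cuts = integer(0)) {
  chars <- rep(".", length)
  if (nrow(pairs) > 0) {
    chars[pairs[, 1] + 1L] <- "("
    chars[pairs[, 2] + 1L] <- ")"
  }
  for (c in rev(sort(cuts))) {
    if (c > 0 && c < length) chars <- append(chars, "&", after = c)
  }
  paste(chars, collapse = "")
}

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of the two pair sets; symmetric in
#' its arguments.  Used by the structural sub-objective term.
#'
#' @param a,b Dot-bracket strings of equal length.
#' @return Non-negative integer distance.
#' @export
bp_distance <- function(a, b) {
  pa <- parse_dotbracket(a)
  pb <- parse_dotbracket(b)
  if (pa$length != pb$length) {
    abort("structures must have equal length", class = "ribochain_input_error")
  }
  key <- function(p) if (nrow(p$pairs) == 0) character(0) else
    paste(p$pairs[, 1], p$pairs[, 2], sep = ":")
  ka <- key(pa); kb <- key(pb)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

insert_cuts <- function(db, cuts) {
  pairs_to_dotbracket(parse_dotbracket(db)$pairs, nchar(db), cuts)
}
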
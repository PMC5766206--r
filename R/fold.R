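# Core folding API over the pluggable energy backends.
#
# All folds go through fold_raw(), which dispatches to the internal
# dynamic-programming engine (src/fold.cpp) or to the ViennaRNA command-line
# adapter, and which memoises results while a design run is active (the
# annealing loop re-evaluates many unchanged species).

.fold_cache <- new.env(parent = emptyenv())

fold_cache_on  <- function() assign(".enabled", TRUE,  envir = .fold_cache)
fold_cache_off <- function() {
  assign(".enabled", FALSE, envir = .fold_cache)
  rm(list = setdiff(ls(.fold_cache, all.names = TRUE), ".enabled"),
     envir = .fold_cache)
}

fold_raw <- function(model, seq, cuts = integer(0),
                     forced_unpaired = NULL, forced_partner = NULL,
                     want_structure = TRUE) {
  n <- nchar(seq)
  if (is.null(forced_unpaired)) forced_unpaired <- rep(FALSE, n)
  if (is.null(forced_partner)) forced_partner <- rep(-1L, n)
  use_cache <- isTRUE(get0(".enabled", envir = .fold_cache, ifnotfound = FALSE))
  key <- NULL
  if (use_cache) {
    key <- paste(backend_id(model), seq, paste(cuts, collapse = ","),
                 paste(which(forced_unpaired), collapse = ","),
                 paste(forced_partner, collapse = ","),
                 want_structure, sep = "|")
    hit <- get0(key, envir = .fold_cache)
    if (!is.null(hit)) return(hit)
  }
  res <- if (model$backend == "internal_toy") {
    out <- fold_engine_cpp(seq_codes(seq), as.integer(cuts),
                           forced_unpaired, as.integer(forced_partner),
                           model$can_pair, model$stack, model$hairpin_min,
                           want_structure)
    if (!isTRUE(out$feasible)) {
      abort("infeasible fold constraints (conflicting frozen pairs?)",
            class = "ribochain_state_error")
    }
    list(energy = out$energy, db = out$structure)
  } else {
    vienna_fold(model, seq, cuts, forced_unpaired, forced_partner)
  }
  if (use_cache) assign(key, res, envir = .fold_cache)
  res
}

vienna_fold <- function(model, seq, cuts, forced_unpaired, forced_partner) {
  if (length(cuts) > 1L) {
    abort("the ViennaRNA adapter supports at most two strands per fold",
          class = "ribochain_backend_error")
  }
  n <- nchar(seq)
  cons <- rep(".", n)
  cons[forced_unpaired] <- "x"
  idx <- which(forced_partner >= 0)
  for (i in idx) {
    j <- forced_partner[i] + 1L
    if (j > i) { cons[i] <- "("; cons[j] <- ")" }
  }
  has_cons <- any(cons != ".")
  celsius <- model$temperature - 273.15
  if (length(cuts) == 1L) {
    sq <- paste0(substr(seq, 1, cuts), "&", substr(seq, cuts + 1L, n))
    cn <- paste0(paste(cons[seq_len(cuts)], collapse = ""), "&",
                 paste(cons[(cuts + 1L):n], collapse = ""))
    exe <- model$rnacofold
  } else {
    sq <- seq
    cn <- paste(cons, collapse = "")
    exe <- model$rnafold
  }
  args <- c("--noPS", sprintf("-T%g", celsius))
  input <- sq
  if (has_cons) {
    args <- c(args, "-C", "--enforceConstraint")
    input <- c(sq, cn)
  }
  out <- system2(exe, args, stdout = TRUE, input = paste(input, collapse = "\n"))
  line <- out[2]
  m <- regmatches(line, regexec("^([().&]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("could not parse %s output: %s", exe, line),
          class = "ribochain_backend_error")
  }
  list(energy = as.numeric(m[3]), db = gsub("&", "", m[2], fixed = TRUE))
}

normalize_constraint <- function(constraint, n) {
  if (is.null(constraint)) return(rep(FALSE, n))
  if (is.character(constraint) && length(constraint) == 1L) {
    ch <- strsplit(constraint, "")[[1]]
    if (length(ch) != n) {
      abort("constraint length does not match sequence length",
            class = "ribochain_input_error")
    }
    if (!all(ch %in% c(".", "x"))) {
      abort("constraint string may contain only '.' (free) and 'x' (unpaired)",
            class = "ribochain_input_error")
    }
    return(ch == "x")
  }
  if (is.logical(constraint)) {
    if (length(constraint) != n) {
      abort("constraint length does not match sequence length",
            class = "ribochain_input_error")
    }
    return(constraint)
  }
  abort("constraint must be NULL, a '.x' string, or a logical vector",
        class = "ribochain_input_error")
}

new_fold_result <- function(seq, cuts, raw, constraint = NULL) {
  structure(
    list(sequence = seq, cuts = cuts,
         structure = insert_cuts(raw$db, cuts),
         pairs = parse_dotbracket(raw$db)$pairs,
         energy = raw$energy, constraint = constraint),
    class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.2f kcal/mol)\n", x$energy),
      sep = "")
  invisible(x)
}

#' Minimum-free-energy fold of a single strand
#'
#' Returns the pseudoknot-free MFE structure under the active energy model,
#' optionally honoring per-position unpaired constraints.  Deterministic:
#' among co-optimal structures the lexicographically smallest dot-bracket is
#' returned.
#'
#' @param seq RNA sequence string.
#' @param constraint `NULL`, a string of `.`/`x` (x = force unpaired), or a
#'   logical vector (`TRUE` = force unpaired) of the same length.
#' @param model Energy model, see [toy_energy_model()] and
#'   [vienna_energy_model()].
#' @return A `fold_result` with fields `sequence`, `structure` (dot-bracket),
#'   `pairs` (0-based matrix), `energy` (kcal/mol) and `constraint`.
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(seq, constraint = NULL, model = toy_energy_model()) {
  seq <- validate_rna(seq)
  fu <- normalize_constraint(constraint, nchar(seq))
  raw <- fold_raw(model, seq, forced_unpaired = fu)
  new_fold_result(seq, integer(0), raw, constraint)
}

#' Minimum-free-energy cofold of two strands
#'
#' Folds the concatenation of the two strands in a single coordinate system
#' with one recorded nick; intra- and intermolecular pairs are both allowed
#' and the hairpin-loop minimum is not enforced across the nick.
#'
#' @param a,b RNA sequence strings.
#' @param constraint Optional unpaired constraint over the concatenation.
#' @inheritParams fold_mfe
#' @return A `fold_result`; `structure` uses `&` to mark the nick.
#' @examples
#' cofold_mfe("GGGG", "CCCC")
#' @export
cofold_mfe <- function(a, b, model = toy_energy_model(), constraint = NULL) {
  a <- validate_rna(a); b <- validate_rna(b)
  seq <- paste0(a, b)
  fu <- normalize_constraint(constraint, nchar(seq))
  raw <- fold_raw(model, seq, cuts = nchar(a), forced_unpaired = fu)
  new_fold_result(seq, nchar(a), raw, constraint)
}

#' Energy cost of exposing a window
#'
#' The opening energy of a window is the difference between the MFE with all
#' window positions forced unpaired and the unconstrained MFE.  It is always
#' >= 0, and 0 exactly when some MFE-energy structure leaves the window
#' unpaired.  This quantity realizes "toehold exposure" (and RBS occlusion)
#' as an energy.
#'
#' @param x A sequence string or a [assemble_complex()] result; for a complex
#'   the window is located on the strand named by `strand` and the complex's
#'   frozen intermolecular pairs are retained in the constrained refold
#'   (pairs that touch the window itself are released).
#' @param window 0-based half-open `[start, end)` interval.
#' @param model Energy model.
#' @param strand Strand id (complex contexts only).
#' @return Opening energy in kcal/mol.
#' @export
opening_energy <- function(x, window, model = toy_energy_model(), strand = NULL) {
  UseMethod("opening_energy")
}

#' @export
opening_energy.character <- function(x, window,
                                     model = toy_energy_model(), strand = NULL) {
  x <- validate_rna(x)
  window <- check_window(window, nchar(x))
  if (window[1] == window[2]) return(0)
  base <- fold_raw(model, x, want_structure = FALSE)
  fu <- rep(FALSE, nchar(x))
  fu[(window[1] + 1L):window[2]] <- TRUE
  cons <- fold_raw(model, x, forced_unpaired = fu, want_structure = FALSE)
  de <- cons$energy - base$energy
  if (abs(de) < 1e-9) de <- 0
  de
}

#' @export
opening_energy.complex_state <- function(x, window,
                                         model = toy_energy_model(),
                                         strand = NULL) {
  if (is.null(strand)) {
    abort("strand id required for a complex-context opening energy",
          class = "ribochain_input_error")
  }
  off <- strand_offsets(x)
  if (!strand %in% names(off)) {
    abort(sprintf("strand '%s' is not a member of the complex", strand),
          class = "ribochain_input_error")
  }
  len <- nchar(x$seqs[[strand]])
  window <- check_window(window, len)
  if (window[1] == window[2]) return(0)
  gidx <- off[[strand]] + (window[1] + 1L):window[2]  # 1-based global
  n <- sum(nchar(x$seqs))
  fu <- rep(FALSE, n)
  fu[gidx] <- TRUE
  fp <- frozen_partner_vector(x, drop = gidx)
  cons <- fold_raw(model, paste(x$seqs, collapse = ""), cuts = x$cuts,
                   forced_unpaired = fu, forced_partner = fp,
                   want_structure = FALSE)
  de <- cons$energy - x$energy
  if (abs(de) < 1e-9) de <- 0
  max(de, 0)
}

#' Exhaustively enumerate all legal structures of a short strand
#'
#' The test oracle for the folding engine: every nested, loop-legal structure
#' of a short sequence is generated recursively and scored by an independent
#' (plain R) energy routine, so that the minimum over the list can be checked
#' against [fold_mfe()].
#'
#' @param seq RNA sequence string.
#' @param model Energy model (internal backend only).
#' @param max_len Refusal threshold; enumeration is exponential.
#' @param cuts Optional 0-based nick positions (to enumerate cofold states).
#' @return A tibble with columns `structure`, `energy`, `n_pairs`, sorted by
#'   energy.
#' @export
enumerate_structures <- function(seq, model = toy_energy_model(),
                                 max_len = 16L, cuts = integer(0)) {
  seq <- validate_rna(seq)
  n <- nchar(seq)
  if (n > max_len) {
    abort(sprintf("refusing to enumerate %d nt (max_len = %d)", n, max_len),
          class = "ribochain_input_error")
  }
  if (model$backend != "internal_toy") {
    abort("enumeration is only defined for the internal model",
          class = "ribochain_input_error")
  }
  codes <- seq_codes(seq) + 1L
  cut_in <- function(lo, hi) any(cuts >= lo & cuts <= hi)  # nick between c-1,c
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    res <- lapply(enum(i + 1L, j), identity)
    for (k in (i + 1L):j) {
      if (k > j) break
      if (!model$can_pair[codes[i + 1L], codes[k + 1L]]) next
      if ((k - i - 1L) < model$hairpin_min && !cut_in(i + 1L, k)) next
      for (inner in enum(i + 1L, k - 1L)) {
        for (right in enum(k + 1L, j)) {
          res[[length(res) + 1L]] <- rbind(c(i, k), inner, right)
        }
      }
    }
    assign(key, res, envir = memo)
    res
  }
  all_pairs <- enum(0L, n - 1L)
  tibble::tibble(
    structure = vapply(all_pairs, pairs_to_dotbracket, "", length = n, cuts = cuts),
    energy = vapply(all_pairs, structure_energy, 0.0,
                    seq = seq, model = model, cuts = cuts),
    n_pairs = vapply(all_pairs, nrow, 0L)
  ) |> dplyr::arrange(.data$energy, .data$structure)
}

#' Score a given structure under the internal model
#'
#' Sums the stacking contributions of the given pair set; independent of the
#' dynamic-programming engine (used as its oracle).
#'
#' @param pairs Two-column 0-based pair matrix or a dot-bracket string.
#' @param seq RNA sequence string.
#' @param model Internal energy model.
#' @param cuts 0-based nick positions.
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(pairs, seq, model = toy_energy_model(),
                             cuts = integer(0)) {
  if (is.character(pairs)) pairs <- parse_dotbracket(pairs)$pairs
  if (nrow(pairs) == 0) return(0)
  codes <- seq_codes(seq)
  partner <- rep(NA_integer_, nchar(seq))
  partner[pairs[, 1] + 1L] <- pairs[, 2]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    inner <- partner[i + 2L]
    if (!is.na(inner) && inner == j - 1L &&
        !((i + 1L) %in% cuts) && !(j %in% cuts)) {
      e <- e + model$stack[4L * codes[i + 1L] + codes[j + 1L] + 1L,
                           4L * codes[i + 2L] + codes[j] + 1L]
    }
  }
  e
}
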
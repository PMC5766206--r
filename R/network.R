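# Network representation and per-interaction energetics.

strand_offsets <- function(x) {
  lens <- vapply(x$seqs, nchar, 0L)
  off <- cumsum(c(0L, lens[-length(lens)]))
  names(off) <- names(x$seqs)
  off
}

frozen_partner_vector <- function(x, drop = integer(0)) {
  n <- sum(vapply(x$seqs, nchar, 0L))
  fp <- rep(-1L, n)
  fz <- x$frozen
  if (is.null(fz) || nrow(fz) == 0) return(fp)
  for (r in seq_len(nrow(fz))) {
    i <- fz[r, 1]; j <- fz[r, 2]
    if ((i + 1L) %in% drop || (j + 1L) %in% drop) next
    fp[i + 1L] <- j
    fp[j + 1L] <- i
  }
  fp
}

strand_of <- function(pos, cuts) findInterval(pos, cuts) + 1L  # 0-based pos

intermolecular_pairs <- function(pairs, cuts) {
  if (nrow(pairs) == 0) return(pairs)
  keep <- strand_of(pairs[, 1], cuts) != strand_of(pairs[, 2], cuts)
  pairs[keep, , drop = FALSE]
}

new_complex_state <- function(seqs, raw, frozen, assembly, model) {
  lens <- vapply(seqs, nchar, 0L)
  cuts <- cumsum(lens)[-length(lens)]
  pairs <- parse_dotbracket(raw$db)$pairs
  structure(
    list(members = names(seqs), seqs = seqs, cuts = as.integer(cuts),
         structure = insert_cuts(raw$db, cuts), pairs = pairs,
         energy = raw$energy,
         frozen = intermolecular_pairs(pairs, cuts),
         assembly = assembly, backend = backend_id(model)),
    class = "complex_state")
}

#' @export
print.complex_state <- function(x, ...) {
  cat("<complex ", paste(x$members, collapse = "+"), "> ",
      sprintf("%.2f kcal/mol\n", x$energy), sep = "")
  cat(paste(unlist(x$seqs), collapse = "&"), "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Hierarchically assemble a multi-strand complex
#'
#' Hybridization events are applied in the order given by the assembly tree
#' (left-deep over the member order by default).  Intermolecular pairs formed
#' at an earlier event are frozen (constrained to be present) in all later
#' events; intramolecular structure is free to re-equilibrate.  This realizes
#' the assumption that multi-strand RNA assembly is mostly hierarchical
#' without requiring a three-strand partition function.
#'
#' @param members Named character vector or list of member sequences, in
#'   strand (concatenation) order.
#' @param order Assembly tree as nested lists of member names, e.g.
#'   `list(list("SR", "SRR"), "SRRR")`; `NULL` means left-deep in member
#'   order.  Leaves must be exactly the member names, left to right.
#' @param model Energy model.
#' @return A `complex_state` with the final multi-strand structure (nicks as
#'   `&`), its energy, the frozen intermolecular pair set and the assembly
#'   order.
#' @export
assemble_complex <- function(members, order = NULL, model = toy_energy_model()) {
  seqs <- lapply(as.list(members), validate_rna)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("strand", seq_along(seqs))
  }
  if (length(seqs) < 2L) {
    abort("a complex needs at least two members", class = "ribochain_input_error")
  }
  if (is.null(order)) {
    order <- names(seqs)[1]
    for (k in 2:length(seqs)) order <- list(order, names(seqs)[k])
  }
  leaves <- function(node) if (is.character(node)) node
    else c(leaves(node[[1]]), leaves(node[[2]]))
  lv <- tryCatch(leaves(order), error = function(e) NULL)
  if (is.null(lv) || !identical(lv, names(seqs))) {
    abort("assembly order must be a binary tree whose leaves are the member names in order",
          class = "ribochain_input_error")
  }
  build <- function(node) {
    if (is.character(node)) {
      sq <- seqs[node]
      return(list(seqs = sq, frozen = matrix(integer(0), ncol = 2)))
    }
    if (length(node) != 2L) {
      abort("assembly tree nodes must be binary", class = "ribochain_input_error")
    }
    left <- build(node[[1]])
    right <- build(node[[2]])
    off <- sum(vapply(left$seqs, nchar, 0L))
    frozen <- rbind(left$frozen,
                    if (nrow(right$frozen)) right$frozen + off else right$frozen)
    sq <- c(left$seqs, right$seqs)
    lens <- vapply(sq, nchar, 0L)
    cuts <- as.integer(cumsum(lens)[-length(lens)])
    fp <- frozen_partner_vector(list(seqs = sq, frozen = frozen))
    raw <- fold_raw(model, paste(unlist(sq), collapse = ""), cuts = cuts,
                    forced_partner = fp)
    st <- new_complex_state(sq, raw, frozen, node, model)
    st
  }
  build(order)
}

#' Detect toehold candidates between two molecules
#'
#' Scans the maximal unpaired runs (length >= `min_len`, within one strand)
#' of the MFE structure of `mol` and reports those whose reverse complement
#' matches a window on `partner`.  With `match = "unpaired"` the partner
#' window must itself be unpaired in the partner's MFE structure; with
#' `"anywhere"` (default) any window qualifies.
#'
#' @param mol A sequence string or `complex_state`.
#' @param partner A sequence string.
#' @param min_len Minimum toehold length.
#' @param model Energy model.
#' @param match Partner matching policy.
#' @param min_complementarity Minimum fraction of complementary positions
#'   (G-U counts as complementary only when the model allows wobble pairs).
#' @return A tibble with columns `start`, `end` (0-based half-open window on
#'   `mol`, global coordinates for a complex), `strand`, `exposed`,
#'   `partner_start`, `partner_end`, `complementarity`.
#' @export
detect_toeholds <- function(mol, partner, min_len = 4L,
                            model = toy_energy_model(),
                            match = c("anywhere", "unpaired"),
                            min_complementarity = 1.0) {
  match <- match.arg(match)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), exposed = logical(0),
                          partner_start = integer(0), partner_end = integer(0),
                          complementarity = numeric(0))
  if (is.character(mol)) {
    mol <- validate_rna(mol)
    fr <- fold_mfe(mol, model = model)
    seq_all <- mol
    db <- fr$structure
    cuts <- integer(0)
    strands <- "strand1"
  } else if (inherits(mol, "complex_state")) {
    seq_all <- paste(unlist(mol$seqs), collapse = "")
    db <- gsub("&", "", mol$structure, fixed = TRUE)
    cuts <- mol$cuts
    strands <- mol$members
  } else {
    abort("mol must be a sequence or a complex_state", class = "ribochain_input_error")
  }
  partner <- validate_rna(partner)
  n <- nchar(seq_all)
  if (min_len > n || min_len > nchar(partner)) return(empty)
  unpaired <- strsplit(db, "")[[1]] == "."
  # break runs at strand boundaries
  boundary <- rep(FALSE, n)
  boundary[cuts + 1L] <- TRUE
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (unpaired[i]) {
      j <- i
      while (j < n && unpaired[j + 1L] && !boundary[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0) return(empty)

  p_unpaired <- strsplit(fold_mfe(partner, model = model)$structure, "")[[1]] == "."
  pchars <- strsplit(partner, "")[[1]]
  rows <- list()
  for (run in runs) {
    w <- substr(seq_all, run[1], run[2])
    target <- revcomp_rna(w)
    tlen <- nchar(target)
    best <- NULL
    for (s in seq_len(nchar(partner) - tlen + 1L)) {
      win <- pchars[s:(s + tlen - 1L)]
      if (match == "unpaired" && !all(p_unpaired[s:(s + tlen - 1L)])) next
      tw <- strsplit(target, "")[[1]]
      ok <- tw == win
      if (isTRUE(model$allow_gu)) {
        rw <- rev(strsplit(w, "")[[1]])
        ok <- ok | (rw == "G" & win == "U") | (rw == "U" & win == "G")
      }
      frac <- mean(ok)
      if (is.null(best) || frac > best$frac) best <- list(s = s, frac = frac)
    }
    if (!is.null(best) && best$frac >= min_complementarity) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = run[1] - 1L, end = run[2],
        strand = strands[strand_of(run[1] - 1L, cuts)],
        exposed = TRUE,
        partner_start = best$s - 1L, partner_end = best$s + tlen - 1L,
        complementarity = best$frac)
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Hybridization and activation free energies of one interaction
#'
#' The hybridization free energy is the cofold (or assembly-event) energy
#' minus the two partners' unhybridized energies; the activation free energy
#' is the sum of the two partners' toehold opening energies, i.e. the energy
#' needed to expose the nucleating regions to the solvent.  The landmark
#' energies trace the reaction coordinate (number of intermolecular base
#' pairs): unbound reference 0, nucleation barrier `dG_act`, full
#' hybridization `dG_hyb`.
#'
#' @param upstream Sequence string or `complex_state`.
#' @param downstream Sequence string.
#' @param up_window,down_window Toehold windows (0-based half-open) on the
#'   upstream and downstream partner.
#' @param up_strand Strand carrying `up_window` when `upstream` is a complex.
#' @param model Energy model.
#' @return An `interaction_energetics` object: `dG_hyb`, `dG_act`,
#'   `landmarks`, `backend`.
#' @export
interaction_energetics <- function(upstream, downstream,
                                   up_window, down_window,
                                   up_strand = NULL,
                                   model = toy_energy_model()) {
  downstream <- validate_rna(downstream)
  e_down <- fold_raw(model, downstream, want_structure = FALSE)$energy
  if (is.character(upstream)) {
    upstream <- validate_rna(upstream)
    e_up <- fold_raw(model, upstream, want_structure = FALSE)$energy
    joint <- fold_raw(model, paste0(upstream, downstream),
                      cuts = nchar(upstream), want_structure = FALSE)$energy
    act_up <- opening_energy(upstream, up_window, model)
  } else if (inherits(upstream, "complex_state")) {
    e_up <- upstream$energy
    sq <- c(upstream$seqs, list(.down = downstream))
    lens <- vapply(sq, nchar, 0L)
    cuts <- as.integer(cumsum(lens)[-length(lens)])
    fp <- frozen_partner_vector(list(seqs = sq, frozen = upstream$frozen))
    joint <- fold_raw(model, paste(unlist(sq), collapse = ""), cuts = cuts,
                      forced_partner = fp, want_structure = FALSE)$energy
    if (is.null(up_strand)) {
      abort("up_strand required when upstream is a complex",
            class = "ribochain_input_error")
    }
    act_up <- opening_energy(upstream, up_window, model, strand = up_strand)
  } else {
    abort("upstream must be a sequence or a complex_state",
          class = "ribochain_input_error")
  }
  act_down <- opening_energy(downstream, down_window, model)
  dG_hyb <- joint - e_up - e_down
  if (abs(dG_hyb) < 1e-9) dG_hyb <- 0
  dG_act <- act_up + act_down
  structure(
    list(dG_hyb = dG_hyb, dG_act = dG_act,
         landmarks = c(unbound = 0, nucleation = dG_act, hybridized = dG_hyb),
         backend = backend_id(model)),
    class = "interaction_energetics")
}

#' @export
print.interaction_energetics <- function(x, ...) {
  cat(sprintf("<interaction> dG_hyb = %.2f, dG_act = %.2f kcal/mol [%s]\n",
              x$dG_hyb, x$dG_act, x$backend))
  invisible(x)
}

#' @export
tidy.interaction_energetics <- function(x, ...) {
  tibble::tibble(dG_hyb = x$dG_hyb, dG_act = x$dG_act,
                 objective_energy = x$dG_hyb + x$dG_act, backend = x$backend)
}

#' Plot the reaction-coordinate energy landscape of an interaction
#'
#' @param object An `interaction_energetics` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.interaction_energetics <- function(object, ...) {
  df <- tibble::tibble(
    state = factor(c("unbound", "nucleation", "hybridized"),
                   levels = c("unbound", "nucleation", "hybridized")),
    energy = unname(object$landmarks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$energy, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "reaction coordinate (intermolecular base pairs)",
                  y = "free energy (kcal/mol)") +
    ggplot2::theme_minimal()
}
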
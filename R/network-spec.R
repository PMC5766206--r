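# The NetworkSpec container: species, interactions, sub-objectives, windows.

#' Construct a network specification
#'
#' A network specification declares the species of an RNA hybridization
#' network (with roles and optional fixed regions / mutability masks), the
#' desired interactions with their toehold windows, optional structural
#' sub-objectives, and the expression-platform windows (RBS, start codon).
#' Any ordered pair of distinct nodes not related by a declared desired
#' interaction (and not a complex/member pair) is implicitly undesired.
#'
#' Complexes are referred to by joining member ids with `+`, e.g.
#' `"SR+SRR"`; member order is strand (concatenation) order.
#'
#' @param species Data frame with columns `id`, `role` (`SR`/`SRR`/`SRRR`/
#'   `GENERIC`), `seq` (string or `NA` before design) and optionally
#'   `length` (needed when `seq` is `NA`), `fixed` (list column of
#'   `list(window =, seq =)` fixed regions) and `mutable` (list column of
#'   logical masks; default everything outside fixed regions).
#' @param interactions Data frame with columns `upstream`, `downstream`,
#'   `desired` (logical), `up_window`, `down_window` (list columns of
#'   0-based half-open pairs) and optionally `up_strand` (strand carrying
#'   the upstream window when upstream is a complex).
#' @param rbs_window,start_codon_window 0-based half-open windows on the
#'   SRRR species.
#' @param subobjectives Named list mapping a species or complex id to a
#'   target dot-bracket (scored as a sub-objective, not enforced).
#' @param weights [objective_weights()].
#' @param schedule [anneal_schedule()].
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(species, interactions,
                         rbs_window = NULL, start_codon_window = NULL,
                         subobjectives = NULL,
                         weights = objective_weights(),
                         schedule = anneal_schedule()) {
  species <- tibble::as_tibble(species)
  interactions <- tibble::as_tibble(interactions)
  stopifnot(all(c("id", "role", "seq") %in% names(species)),
            all(c("upstream", "downstream", "desired",
                  "up_window", "down_window") %in% names(interactions)))
  if (!"length" %in% names(species)) {
    species$length <- NA_integer_
  }
  species$length <- ifelse(is.na(species$seq),
                           as.integer(species$length),
                           nchar(species$seq))
  if (any(is.na(species$length))) {
    abort("species without a sequence need an explicit length",
          class = "ribochain_spec_error")
  }
  if (!"fixed" %in% names(species)) species$fixed <- rep(list(list()), nrow(species))
  if (!"mutable" %in% names(species)) species$mutable <- rep(list(NULL), nrow(species))
  species$mutable <- lapply(seq_len(nrow(species)), function(i) {
    m <- species$mutable[[i]]
    len <- species$length[i]
    if (is.null(m)) m <- rep(TRUE, len)
    if (length(m) != len) abort("mutability mask length mismatch",
                                class = "ribochain_spec_error")
    for (fx in species$fixed[[i]]) {
      w <- check_window(fx$window, len, "fixed region")
      if (w[2] > w[1]) m[(w[1] + 1L):w[2]] <- FALSE
    }
    m
  })
  if (!"up_strand" %in% names(interactions)) {
    interactions$up_strand <- NA_character_
  }
  if (sum(species$role == "SRRR") > 1L) {
    abort("at most one species may carry the SRRR role",
          class = "ribochain_spec_error")
  }
  net <- structure(
    list(species = species, interactions = interactions,
         rbs_window = if (!is.null(rbs_window)) as.integer(rbs_window),
         start_codon_window = if (!is.null(start_codon_window))
           as.integer(start_codon_window),
         subobjectives = subobjectives %||% list(),
         weights = weights, schedule = schedule,
         schema_version = 1L),
    class = "network_spec")
  validate_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a network specification
#'
#' Checks species/interaction referential integrity, window bounds and
#' toehold lengths.  Called by [network_spec()] and after YAML input.
#'
#' @param net A `network_spec`.
#' @return `net`, invisibly; errors with class `ribochain_spec_error`.
#' @export
validate_network <- function(net) {
  sp <- net$species
  lens <- setNames(sp$length, sp$id)
  node_len <- function(id) {
    members <- strsplit(id, "+", fixed = TRUE)[[1]]
    if (!all(members %in% sp$id)) {
      abort(sprintf("unknown species in node '%s'", id),
            class = "ribochain_spec_error")
    }
    sum(lens[members])
  }
  for (r in seq_len(nrow(net$interactions))) {
    row <- net$interactions[r, ]
    if (identical(row$upstream, row$downstream)) {
      abort("upstream and downstream of an interaction must differ",
            class = "ribochain_spec_error")
    }
    uw <- row$up_window[[1]]; dw <- row$down_window[[1]]
    up_len <- if (!is.na(row$up_strand)) lens[[row$up_strand]] else
      node_len(row$upstream)
    check_window(uw, up_len, "up_window")
    check_window(dw, node_len(row$downstream), "down_window")
    if (uw[2] - uw[1] < 1L || dw[2] - dw[1] < 1L) {
      abort("toehold windows must have length >= 1",
            class = "ribochain_spec_error")
    }
  }
  if (!is.null(net$rbs_window)) {
    plat <- platform_id(net)
    check_window(net$rbs_window, lens[[plat]], "rbs_window")
  }
  invisible(net)
}

platform_id <- function(net) {
  id <- net$species$id[net$species$role == "SRRR"]
  if (length(id) != 1L) {
    abort("network has no (or no unique) SRRR species",
          class = "ribochain_spec_error")
  }
  id
}

node_members <- function(id) strsplit(id, "+", fixed = TRUE)[[1]]

is_complex_id <- function(id) grepl("+", id, fixed = TRUE)

network_sequences <- function(net) {
  setNames(as.list(net$species$seq), net$species$id)
}

assigned <- function(net) !any(is.na(net$species$seq))

#' Replace the sequences of a network
#'
#' @param net A `network_spec`.
#' @param seqs Named list/vector of sequences (names = species ids).
#' @return The updated `network_spec`.
#' @export
set_sequences <- function(net, seqs) {
  for (id in names(seqs)) {
    i <- match(id, net$species$id)
    if (is.na(i)) abort(sprintf("unknown species '%s'", id),
                        class = "ribochain_spec_error")
    s <- validate_rna(seqs[[id]])
    if (nchar(s) != net$species$length[i]) {
      abort(sprintf("sequence length %d does not match declared length %d for '%s'",
                    nchar(s), net$species$length[i], id),
            class = "ribochain_spec_error")
    }
    net$species$seq[i] <- s
  }
  net
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d species, %d declared interaction(s)\n",
              nrow(x$species), nrow(x$interactions)))
  print(x$species[, c("id", "role", "seq", "length")])
  invisible(x)
}

# Build the upstream node (species sequence or assembled complex) named `id`.
resolve_node <- function(net, id, model) {
  seqs <- network_sequences(net)
  members <- node_members(id)
  if (length(members) == 1L) {
    s <- seqs[[id]]
    if (is.null(s) || is.na(s)) abort(sprintf("species '%s' has no sequence", id),
                                      class = "ribochain_state_error")
    return(s)
  }
  ms <- seqs[members]
  if (any(vapply(ms, function(x) is.null(x) || is.na(x), TRUE))) {
    abort(sprintf("complex '%s' has unassigned members", id),
          class = "ribochain_state_error")
  }
  assemble_complex(setNames(lapply(ms, identity), members), model = model)
}

# Energetics of one declared interaction row.
interaction_row_energetics <- function(net, row, model) {
  up <- resolve_node(net, row$upstream, model)
  down_id <- row$downstream
  if (is_complex_id(down_id)) {
    abort("complex downstream nodes are not supported",
          class = "ribochain_spec_error")
  }
  down <- resolve_node(net, down_id, model)
  up_strand <- if (!is.na(row$up_strand)) row$up_strand else NULL
  interaction_energetics(up, down, row$up_window[[1]], row$down_window[[1]],
                         up_strand = up_strand, model = model)
}

# Implicitly undesired ordered pairs: every (node, species) combination among
# the declared nodes that is not a declared desired interaction in either
# order and not a complex/member relation.  Homodimers are excluded here and
# reported separately by evaluate().
implicit_undesired_pairs <- function(net) {
  nodes <- unique(c(net$species$id, net$interactions$upstream,
                    net$interactions$downstream))
  declared <- paste(net$interactions$upstream, net$interactions$downstream)
  declared <- c(declared, paste(net$interactions$downstream,
                                net$interactions$upstream))
  out <- list()
  for (a in nodes) for (b in nodes) {
    if (a >= b) next  # unordered enumeration; toy energies are symmetric
    if (is_complex_id(b)) next
    if (paste(a, b) %in% declared || paste(b, a) %in% declared) next
    if (is_complex_id(a) && b %in% node_members(a)) next
    out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

# dG_hyb of an undeclared pair (no toehold windows -> dG_act term omitted).
undesired_energetics <- function(net, a, b, model) {
  up <- resolve_node(net, a, model)
  down <- resolve_node(net, b, model)
  if (is.character(up)) {
    e_up <- fold_raw(model, up, want_structure = FALSE)$energy
    joint <- fold_raw(model, paste0(up, down), cuts = nchar(up),
                      want_structure = FALSE)$energy
  } else {
    e_up <- up$energy
    sq <- c(up$seqs, list(.down = down))
    lens <- vapply(sq, nchar, 0L)
    cuts <- as.integer(cumsum(lens)[-length(lens)])
    fp <- frozen_partner_vector(list(seqs = sq, frozen = up$frozen))
    joint <- fold_raw(model, paste(unlist(sq), collapse = ""), cuts = cuts,
                      forced_partner = fp, want_structure = FALSE)$energy
  }
  e_down <- fold_raw(model, down, want_structure = FALSE)$energy
  d <- joint - e_up - e_down
  if (abs(d) < 1e-9) d <- 0
  d
}

#' Cross-talk matrix between networks
#'
#' For every ordered pair of networks, the upstream complex of the first
#' (all species up to the expression platform, hierarchically assembled) is
#' confronted with the expression platform (5' UTR) of the second, exactly as
#' the cognate (diagonal) interactions are computed.  The report includes the
#' free-energy gap `dG_hyb(cognate) - dG_hyb(pair)` for each row; cognate
#' pairs should show a clearly negative `dG_hyb` and non-cognate pairs no
#' significant gap.
#'
#' @param networks Named list of `network_spec` objects (all sequences
#'   assigned).
#' @param model Energy model.
#' @return A tibble with columns `up_network`, `down_network`, `dG_hyb`,
#'   `dG_act`, `cognate`, `gap`.
#' @export
crosstalk_matrix <- function(networks, model = toy_energy_model()) {
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("net", seq_along(networks))
  }
  plat_row <- function(net) {
    plat <- platform_id(net)
    r <- which(net$interactions$desired & net$interactions$downstream == plat)
    if (length(r) != 1L) abort("network must declare exactly one platform interaction",
                               class = "ribochain_spec_error")
    net$interactions[r, ]
  }
  rows <- list()
  for (i in names(networks)) {
    ni <- networks[[i]]
    ri <- plat_row(ni)
    up <- resolve_node(ni, ri$upstream, model)
    up_strand <- if (!is.na(ri$up_strand)) ri$up_strand else NULL
    for (j in names(networks)) {
      nj <- networks[[j]]
      rj <- plat_row(nj)
      down <- resolve_node(nj, rj$downstream, model)
      e <- interaction_energetics(up, down, ri$up_window[[1]],
                                  rj$down_window[[1]],
                                  up_strand = up_strand, model = model)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        up_network = i, down_network = j,
        dG_hyb = e$dG_hyb, dG_act = e$dG_act, cognate = identical(i, j))
    }
  }
  out <- dplyr::bind_rows(rows)
  diag_val <- setNames(out$dG_hyb[out$cognate], out$up_network[out$cognate])
  out$gap <- unname(diag_val[out$up_network]) - out$dG_hyb
  out
}
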
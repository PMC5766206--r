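# Deterministic synthetic chain networks with planted solutions.
#
# The generator is structure-templated: stems, loops and toeholds are placed
# first and sequences are filled from disjoint complementarity classes, so
# the planted properties hold by construction under the internal model:
#   * every desired interaction has dG_hyb < 0 and dG_act = 0,
#   * every implicitly undesired pair has dG_hyb = 0 (off-target duplexes
#     are shorter than the intramolecular stems that protect them),
#   * the RBS is occluded in the unhybridized 5' UTR and exposed in the
#     fully assembled ON complex.
#
# Layout of a chain S1 -> S2 -> ... -> Sn (Sn = expression platform):
#   S1       = D1                              (the signal riboregulator)
#   Sk (mid) = revcomp(head of Dk) | comp(D(k-1)) | Dk
#              with the first segment pairing the head of Dk into a stem
#              that encloses the loop, so that binding of the upstream
#              molecule to the loop (a pseudoknot-forbidden crossing)
#              forces the stem open and activates Dk; placing Dk at the 3'
#              end keeps it outside the upstream duplex in the concatenated
#              coordinate system, free to invade the next species
#   Sn       = revcomp(RBS unit) | comp(D(n-1)) | RBS unit
#              an RBS-occluding hairpin whose loop is the toehold; invasion
#              by the upstream complex opens the stem and exposes the RBS.
# Domain letters alternate between the A/U and C/G complementarity classes
# along the chain so that non-adjacent species cannot form stacks.

#' Generate a planted chain-network fixture
#'
#' @param n_species Number of species in the chain; only 3 (signal,
#'   intermediate, cis-repressed 5' UTR) admits a planted solution with
#'   exact off-target zeros under a four-letter alphabet: with two
#'   complementarity classes, any two middle species of a longer chain can
#'   trade both of their domain pairings in a double invasion, so longer
#'   recipes are rejected as infeasible.
#' @param toehold_len Length of the first toehold (SR and the SRR loop);
#'   must exceed `stem_len` so the signal can open the stem.
#' @param stem_len Length of the stems hiding downstream domains (>= 3).
#' @param loop_len Length of the downstream interaction domains (and of the
#'   platform loop); must exceed the RBS-unit length so that invasion opens
#'   the RBS stem, and `loop_len - stem_len` must stay below it so the OFF
#'   state does not leak.
#' @param alphabet Complementarity class of the platform-invading domain:
#'   `"AU"` or `"GC"`.  Two fixtures with different classes are orthogonal.
#' @param rbs,spacer,start_codon Fixed-content regions of the platform.
#' @param seed Integer, recorded in the spec (the template itself is fully
#'   deterministic).
#' @return A list with `network` (a [network_spec()] carrying the planted
#'   sequences), `sequences` (named character), and `expected` (tibble of
#'   planted interaction energetics under the default internal model).
#' @export
generate_chain <- function(n_species = 3L, toehold_len = 10L, stem_len = 8L,
                           loop_len = 14L, alphabet = c("AU", "GC"),
                           rbs = "AGGAGG", spacer = "", start_codon = "AUG",
                           seed = 1L) {
  alphabet <- match.arg(alphabet)
  n <- as.integer(n_species)
  unit <- paste0(rbs, spacer, start_codon)
  unit_len <- nchar(unit)
  if (n != 3L) {
    abort(paste("infeasible recipe: planted chains are only constructible",
                "for 3 species (two complementarity classes cannot keep",
                "longer chains orthogonal)"),
          class = "ribochain_input_error")
  }
  if (toehold_len < 4L || stem_len < 3L) {
    abort("toehold_len >= 4 and stem_len >= 3 required",
          class = "ribochain_input_error")
  }
  if (toehold_len <= stem_len) {
    abort("infeasible recipe: the toehold must be longer than the stem it opens",
          class = "ribochain_input_error")
  }
  if (loop_len <= unit_len) {
    abort("infeasible recipe: the invading domain must be longer than the RBS stem",
          class = "ribochain_input_error")
  }
  if (loop_len - stem_len >= unit_len - 2L) {
    abort("infeasible recipe: the exposed part of a hidden domain would open the RBS stem",
          class = "ribochain_input_error")
  }

  # domain letter of species k (k = 1..n-1), alternating classes backwards
  # from the platform-invading domain
  lead <- if (alphabet == "AU") c("A", "C") else c("C", "U")
  x <- vapply(seq_len(n - 1L), function(k) {
    lead[((n - 1L - k) %% 2L) + 1L]
  }, "")
  d_len <- c(toehold_len, rep(loop_len, n - 2L))

  ids <- if (n == 3L) c("SR", "SRR", "SRRR") else
    c("SR", "SRR", paste0("R", seq(3L, n - 1L)), "SRRR")
  roles <- c("SR", "SRR", rep("GENERIC", max(0L, n - 3L)), "SRRR")

  seqs <- character(n)
  seqs[1] <- strrep(x[1], toehold_len)
  if (n > 2L) for (k in 2:(n - 1L)) {
    seqs[k] <- paste0(strrep(complement_base(x[k]), stem_len),
                      strrep(complement_base(x[k - 1L]), d_len[k - 1L]),
                      strrep(x[k], loop_len))
  }
  seqs[n] <- paste0(revcomp_rna(unit),
                    strrep(complement_base(x[n - 1L]), d_len[n - 1L]),
                    unit)
  names(seqs) <- ids

  # declared desired interactions with their toehold windows
  inter <- lapply(seq_len(n - 1L), function(k) {
    upstream <- if (k == 1L) ids[1] else paste(ids[seq_len(k)], collapse = "+")
    up_strand <- if (k == 1L) NA_character_ else ids[k]
    # the active domain of a middle species occupies its 3' end
    up_off <- if (k == 1L) 0L else stem_len + d_len[k - 1L]
    down_off <- if (k == n - 1L) unit_len else stem_len
    tibble::tibble(
      upstream = upstream, downstream = ids[k + 1L], desired = TRUE,
      up_window = list(c(up_off, up_off + d_len[k])),
      down_window = list(c(down_off, down_off + d_len[k])),
      up_strand = up_strand)
  })
  inter <- dplyr::bind_rows(inter)

  rbs_window <- c(unit_len + loop_len, unit_len + loop_len + nchar(rbs))
  start_off <- unit_len + loop_len + nchar(rbs) + nchar(spacer)
  start_codon_window <- c(start_off, start_off + nchar(start_codon))
  fixed_platform <- list(
    list(window = rbs_window, seq = rbs),
    list(window = start_codon_window, seq = start_codon))

  species <- tibble::tibble(
    id = ids, role = roles, seq = unname(seqs),
    fixed = c(rep(list(list()), n - 1L), list(fixed_platform)))

  net <- network_spec(species, inter, rbs_window = rbs_window,
                      start_codon_window = start_codon_window)
  net$seed <- as.integer(seed)

  s <- 2.0  # default Watson-Crick stack magnitude of the internal model
  expected <- dplyr::bind_rows(lapply(seq_len(n - 1L), function(k) {
    dg <- if (k == 1L) -s * (toehold_len - stem_len)
          else -s * (loop_len - unit_len)
    tibble::tibble(upstream = inter$upstream[k], downstream = inter$downstream[k],
                   desired = TRUE, dG_hyb = dg, dG_act = 0)
  }))

  list(network = net, sequences = seqs, expected = expected)
}

#' Generate two orthogonal chain-network fixtures
#'
#' The two networks draw their platform-invading domains from disjoint
#' complementarity classes, so their cross (non-cognate) complex/UTR pairs
#' share no complementary runs and have `dG_hyb = 0` under the internal
#' model, while each cognate pair stays strongly negative.
#'
#' @param n_species,toehold_len,stem_len,loop_len,seed As in
#'   [generate_chain()] (applied to both networks).
#' @param alphabets Character vector of two distinct complementarity
#'   classes, one per network.
#' @return Named list of two fixtures (`netA`, `netB`).
#' @export
generate_orthogonal_pair <- function(n_species = 3L, toehold_len = 10L,
                                     stem_len = 8L, loop_len = 14L,
                                     alphabets = c("AU", "GC"), seed = 1L) {
  if (length(alphabets) != 2L || alphabets[1] == alphabets[2]) {
    abort("orthogonal fixtures need two disjoint alphabet partitions",
          class = "ribochain_input_error")
  }
  list(
    netA = generate_chain(n_species, toehold_len, stem_len, loop_len,
                          alphabet = alphabets[1], seed = seed),
    netB = generate_chain(n_species, toehold_len, stem_len, loop_len,
                          alphabet = alphabets[2], seed = seed + 1L))
}
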
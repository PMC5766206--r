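# Mass-action equilibrium of network species and complexes; thermodynamic
# and apparent (gel-derived) dissociation constants.

#' Thermodynamic Kd from a hybridization free energy
#'
#' `Kd = C0 * exp(dG / (R * T))` with standard concentration `C0 = 1` M and
#' `R = 1.987e-3` kcal/(mol K).  `log(Kd)` is therefore exactly linear in
#' the hybridization free energy with slope `1 / (R * T)` - the model-side
#' mechanism behind correlating measured log-Kd with predicted energies.
#'
#' @param dG_hyb Free energy of hybridization, kcal/mol.
#' @param temperature Temperature in Kelvin.
#' @return Dissociation constant in M (vectorized over `dG_hyb`).
#' @export
kd_from_energy <- function(dG_hyb, temperature = 310.15) {
  if (temperature <= 0) abort("temperature must be > 0 K",
                              class = "ribochain_input_error")
  exp(dG_hyb / (gas_constant_kcal() * temperature))
}

gas_constant_kcal <- function() 1.987e-3

#' Define a mass-action binding system
#'
#' Elementary species with total concentrations plus a list of binary
#' binding reactions, each forming a complex from two reactants (species or
#' previously formed complexes - the reaction list must be ordered so that a
#' complex is defined before it is consumed, i.e. complex formation is
#' acyclic and hierarchical).
#'
#' @param totals Named numeric vector of total strand concentrations (M).
#' @param reactions Data frame with columns `complex`, `r1`, `r2`, `kd`
#'   (M, > 0).
#' @return An `equilibrium_system`.
#' @export
equilibrium_system <- function(totals, reactions) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("complex", "r1", "r2", "kd") %in% names(reactions)))
  if (any(reactions$kd <= 0)) abort("Kd must be > 0",
                                    class = "ribochain_input_error")
  if (any(totals < 0)) abort("totals must be >= 0",
                             class = "ribochain_input_error")
  known <- names(totals)
  for (r in seq_len(nrow(reactions))) {
    for (rr in c(reactions$r1[r], reactions$r2[r])) {
      if (!rr %in% known) {
        abort(sprintf("reactant '%s' undefined at reaction %d (acyclic order required)",
                      rr, r), class = "ribochain_input_error")
      }
    }
    known <- c(known, reactions$complex[r])
  }
  structure(list(totals = totals, reactions = reactions),
            class = "equilibrium_system")
}

# Composition of every complex in elementary species (recursive expansion).
complex_composition <- function(sys) {
  comp <- lapply(names(sys$totals), function(s) setNames(1, s))
  names(comp) <- names(sys$totals)
  for (r in seq_len(nrow(sys$reactions))) {
    a <- comp[[sys$reactions$r1[r]]]
    b <- comp[[sys$reactions$r2[r]]]
    all_names <- union(names(a), names(b))
    v <- setNames(numeric(length(all_names)), all_names)
    v[names(a)] <- v[names(a)] + a
    v[names(b)] <- v[names(b)] + b
    comp[[sys$reactions$complex[r]]] <- v
  }
  comp
}

#' Solve a binding system for its equilibrium state
#'
#' Damped multiplicative fixed-point iteration on the free concentrations of
#' the elementary species; complex concentrations follow from the mass-action
#' law `[complex] = [r1][r2] / Kd` applied along the (acyclic) reaction
#' order.  Single-reaction two-species systems are solved by the closed-form
#' quadratic.  Per-strand conservation is verified to the requested
#' tolerance.
#'
#' @param sys An [equilibrium_system()].
#' @param tol Relative conservation tolerance.
#' @param max_iter Iteration cap; exceeded means a solver error.
#' @return An `equilibrium_state`: tibble with columns `species`, `type`
#'   (`free`/`complex`), `concentration` (M); attributes `residual`
#'   (max relative conservation violation) and `iterations`.
#' @export
solve_equilibrium <- function(sys, tol = 1e-12, max_iter = 100000L) {
  species <- names(sys$totals)
  rx <- sys$reactions
  comp <- complex_composition(sys)

  complex_concs <- function(free) {
    conc <- as.list(free)
    if (nrow(rx)) for (r in seq_len(nrow(rx))) {
      conc[[rx$complex[r]]] <- conc[[rx$r1[r]]] * conc[[rx$r2[r]]] / rx$kd[r]
    }
    conc
  }
  bound_per_species <- function(conc) {
    bound <- setNames(numeric(length(species)), species)
    if (nrow(rx)) for (r in seq_len(nrow(rx))) {
      cc <- comp[[rx$complex[r]]]
      bound[names(cc)] <- bound[names(cc)] + cc * conc[[rx$complex[r]]]
    }
    bound
  }

  if (nrow(rx) == 1L && all(comp[[rx$complex[1]]] == 1) &&
      length(comp[[rx$complex[1]]]) == 2L) {
    a0 <- sys$totals[rx$r1[1]]; b0 <- sys$totals[rx$r2[1]]; kd <- rx$kd[1]
    s <- a0 + b0 + kd
    ab <- as.numeric((s - sqrt(s^2 - 4 * a0 * b0)) / 2)
    free <- sys$totals
    free[rx$r1[1]] <- a0 - ab
    free[rx$r2[1]] <- b0 - ab
    conc <- as.list(free)
    conc[[rx$complex[1]]] <- ab
    iters <- 0L
  } else {
    free <- pmax(sys$totals, 0)
    free[free == 0] <- 0
    iters <- 0L
    repeat {
      iters <- iters + 1L
      conc <- complex_concs(free)
      bound <- bound_per_species(conc)
      denom <- free + bound
      rel <- abs(denom - sys$totals) / pmax(sys$totals, .Machine$double.xmin)
      rel[sys$totals == 0] <- abs(denom[sys$totals == 0])
      if (max(rel) < tol) break
      if (iters >= max_iter) {
        abort(sprintf("equilibrium solver did not converge (residual %.3g after %d iterations)",
                      max(rel), iters),
              class = "ribochain_solver_error")
      }
      ratio <- ifelse(sys$totals == 0, 0,
                      ifelse(denom > 0, sys$totals / denom, 1))
      free <- free * ratio^0.5
      free[sys$totals == 0] <- 0
    }
    conc <- complex_concs(free)
  }

  bound <- bound_per_species(conc)
  resid <- abs(unlist(conc[species]) + bound - sys$totals) /
    pmax(sys$totals, .Machine$double.xmin)
  resid[sys$totals == 0] <- 0
  out <- tibble::tibble(
    species = names(conc),
    type = ifelse(names(conc) %in% species, "free", "complex"),
    concentration = unname(unlist(conc)))
  structure(out, residual = max(resid), iterations = iters,
            class = c("equilibrium_state", class(out)))
}

#' Molecular weight of an RNA strand
#'
#' Sum of ribonucleotide-monophosphate residue masses plus one water
#' (5'-OH / 3'-OH convention); used to translate gel band masses into molar
#' amounts when no explicit molecular weight is supplied.
#'
#' @param seq RNA sequence string.
#' @return Molecular weight in g/mol.
#' @export
mw_rna <- function(seq) {
  seq <- validate_rna(seq)
  masses <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
  sum(masses[strsplit(seq, "")[[1]]]) + 18.02
}

#' Apparent Kd from a gel band mass fraction
#'
#' Gel bands are assumed proportional to mass.  The complex band's mass
#' fraction (complex mass over total loaded mass) is translated into molar
#' concentrations via the strands' molecular weights and the reaction
#' volume, and the apparent dissociation constant is `[A][B]/[AB]`.
#'
#' @param fraction Complex mass fraction in `[0, 1]`.
#' @param mass_a,mass_b Loaded strand masses (ng).
#' @param volume Reaction volume (L).
#' @param mw_a,mw_b Molecular weights (g/mol); computed from `seq_a`/`seq_b`
#'   when omitted.
#' @param seq_a,seq_b Optional sequences used to compute molecular weights.
#' @return Apparent Kd in M.  `fraction = 1` returns 0 and `fraction = 0`
#'   returns `Inf`, both with attribute `flag`; a complex mass exceeding the
#'   stoichiometrically available partner mass is an error.
#' @export
mass_fraction_to_kd <- function(fraction, mass_a, mass_b, volume,
                                mw_a = NULL, mw_b = NULL,
                                seq_a = NULL, seq_b = NULL) {
  if (mass_a <= 0 || mass_b <= 0 || volume <= 0) {
    abort("masses and volume must be > 0", class = "ribochain_input_error")
  }
  if (fraction < 0 || fraction > 1) {
    abort("mass fraction must lie in [0, 1]", class = "ribochain_input_error")
  }
  mw_a <- mw_a %||% (if (!is.null(seq_a)) mw_rna(seq_a) else
    abort("mw_a or seq_a required", class = "ribochain_input_error"))
  mw_b <- mw_b %||% (if (!is.null(seq_b)) mw_rna(seq_b) else
    abort("mw_b or seq_b required", class = "ribochain_input_error"))
  if (fraction == 1) return(structure(0, flag = "saturated"))
  if (fraction == 0) return(structure(Inf, flag = "no_complex"))
  ng <- 1e-9  # masses in ng, MW in g/mol
  total_mass <- mass_a + mass_b
  complex_mass <- fraction * total_mass
  mol_ab <- complex_mass * ng / (mw_a + mw_b)
  mol_a_free <- mass_a * ng / mw_a - mol_ab
  mol_b_free <- mass_b * ng / mw_b - mol_ab
  if (mol_a_free < 0 || mol_b_free < 0) {
    abort("complex mass exceeds the stoichiometrically available partner mass",
          class = "ribochain_input_error")
  }
  (mol_a_free / volume) * (mol_b_free / volume) / (mol_ab / volume)
}

#' Predict a gel band mass fraction from a Kd
#'
#' Forward model of [mass_fraction_to_kd()]: solves the two-species binding
#' equilibrium at the loaded amounts and converts the complex concentration
#' back to a mass fraction of the total loaded mass.  Exact inverse of the
#' backward conversion on their common domain.
#'
#' @inheritParams mass_fraction_to_kd
#' @param kd Dissociation constant in M (>= 0; 0 means complete binding).
#' @return Mass fraction in `[0, 1]`.
#' @export
predict_mass_fraction <- function(kd, mass_a, mass_b, volume,
                                  mw_a = NULL, mw_b = NULL,
                                  seq_a = NULL, seq_b = NULL) {
  if (mass_a <= 0 || mass_b <= 0 || volume <= 0) {
    abort("masses and volume must be > 0", class = "ribochain_input_error")
  }
  if (kd < 0) abort("Kd must be >= 0", class = "ribochain_input_error")
  mw_a <- mw_a %||% (if (!is.null(seq_a)) mw_rna(seq_a) else
    abort("mw_a or seq_a required", class = "ribochain_input_error"))
  mw_b <- mw_b %||% (if (!is.null(seq_b)) mw_rna(seq_b) else
    abort("mw_b or seq_b required", class = "ribochain_input_error"))
  ng <- 1e-9
  a0 <- mass_a * ng / mw_a / volume
  b0 <- mass_b * ng / mw_b / volume
  ab <- if (kd == 0) {
    min(a0, b0)
  } else {
    s <- a0 + b0 + kd
    (s - sqrt(s^2 - 4 * a0 * b0)) / 2
  }
  complex_mass <- ab * volume * (mw_a + mw_b) / ng
  complex_mass / (mass_a + mass_b)
}

#' Mass fractions of an equilibrium state
#'
#' Converts the molar concentrations of a solved system into per-band mass
#' fractions of the total loaded mass (bands proportional to mass).
#'
#' @param state An `equilibrium_state`.
#' @param sys The [equilibrium_system()] it solves.
#' @param mws Named molecular weights (g/mol) of the elementary species.
#' @return The state tibble with extra columns `mw` and `mass_fraction`.
#' @export
mass_fractions <- function(state, sys, mws) {
  comp <- complex_composition(sys)
  mw_of <- function(id) sum(mws[names(comp[[id]])] * comp[[id]])
  mw <- vapply(state$species, mw_of, 0.0)
  mass <- state$concentration * mw
  out <- state
  out$mw <- unname(mw)
  out$mass_fraction <- mass / sum(sys$totals * mws[names(sys$totals)])
  out
}
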
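#' Internal stacking-only nearest-neighbour energy model
#'
#' A deliberately simple, fully self-contained 2D energy model: every stack of
#' two adjacent Watson-Crick base pairs contributes `stack_wc` kcal/mol, a
#' stack involving at least one G-U wobble pair contributes `stack_wobble`
#' (only when `allow_gu = TRUE`), and there are no loop penalties.  Hairpin
#' loops must enclose at least three unpaired nucleotides unless a strand
#' nick lies inside them.  Isolated pairs cost nothing, so the empty
#' structure always has energy exactly 0 and any structure has energy <= 0
#' under the defaults.
#'
#' The model is crude on purpose: it makes minimum-free-energy structures
#' exhaustively verifiable at small lengths while preserving the qualitative
#' features the design framework relies on (duplex stability growing with
#' helix length, constrained refolding, strand-displacement competition).
#' For realistic runs swap in [vienna_energy_model()].
#'
#' @param stack_wc Stacking energy (kcal/mol) for two adjacent Watson-Crick
#'   pairs; must be <= 0.
#' @param stack_wobble Stacking energy when a G-U pair is involved.
#' @param allow_gu Allow G-U wobble pairs.
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#' @return An object of class `ribochain_model`.
#' @export
toy_energy_model <- function(stack_wc = -2.0, stack_wobble = -1.0,
                             allow_gu = FALSE, temperature = 310.15) {
  if (stack_wc > 0) abort("Watson-Crick stacking energies must be <= 0",
                          class = "ribochain_input_error")
  if (temperature <= 0) abort("temperature must be > 0 K",
                              class = "ribochain_input_error")
  can_pair <- matrix(FALSE, 4, 4)  # A C G U
  wc <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))  # AU UA CG GC (1-based codes)
  for (k in seq_len(nrow(wc))) can_pair[wc[k, 1], wc[k, 2]] <- TRUE
  gu <- rbind(c(3, 4), c(4, 3))
  if (allow_gu) for (k in 1:2) can_pair[gu[k, 1], gu[k, 2]] <- TRUE

  is_wobble <- function(a, b) (a == 3 && b == 4) || (a == 4 && b == 3)
  stack <- matrix(0, 16, 16)
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4) {
    if (can_pair[a, b] && can_pair[c, d]) {
      val <- if (is_wobble(a, b) || is_wobble(c, d)) stack_wobble else stack_wc
      stack[4L * (a - 1L) + b, 4L * (c - 1L) + d] <- val
    }
  }
  structure(
    list(backend = "internal_toy", can_pair = can_pair, stack = stack,
         hairpin_min = 3L, allow_gu = allow_gu, temperature = temperature,
         stack_wc = stack_wc, stack_wobble = stack_wobble),
    class = "ribochain_model")
}

#' ViennaRNA command-line backend
#'
#' Adapter around the `RNAfold` / `RNAcofold` executables (full Turner
#' parameters).  Constrained folds use ViennaRNA hard constraints (`-C`).
#' The exact ViennaRNA version is recorded in the backend identifier so that
#' every report names the parameter source.
#'
#' @param temperature Temperature in Kelvin; converted to Celsius for the
#'   `-T` option.
#' @param rnafold,rnacofold Executable names or paths.
#' @return An object of class `ribochain_model`.
#' @export
vienna_energy_model <- function(temperature = 310.15,
                                rnafold = "RNAfold", rnacofold = "RNAcofold") {
  if (temperature <= 0) abort("temperature must be > 0 K",
                              class = "ribochain_input_error")
  ver <- tryCatch(
    system2(rnafold, "--version", stdout = TRUE, stderr = TRUE)[1],
    error = function(e) NA_character_, warning = function(w) NA_character_)
  if (is.na(ver)) abort("RNAfold executable not found on PATH",
                        class = "ribochain_backend_error")
  structure(
    list(backend = "vienna", rnafold = rnafold, rnacofold = rnacofold,
         temperature = temperature, version = ver, hairpin_min = 3L,
         allow_gu = TRUE),
    class = "ribochain_model")
}

#' Backend identifier with parameter digest
#'
#' @param model A `ribochain_model`.
#' @return A single string identifying the backend and its parameters;
#'   written into every energetics report.
#' @export
backend_id <- function(model) {
  stopifnot(inherits(model, "ribochain_model"))
  if (model$backend == "internal_toy") {
    sprintf("internal_toy/wc=%g;wobble=%g;gu=%s;hairpin=%d;T=%gK",
            model$stack_wc, model$stack_wobble,
            if (model$allow_gu) "on" else "off",
            model$hairpin_min, model$temperature)
  } else {
    sprintf("vienna/%s;T=%gK", model$version, model$temperature)
  }
}

#' @export
print.ribochain_model <- function(x, ...) {
  cat("<ribochain energy model> ", backend_id(x), "\n", sep = "")
  invisible(x)
}
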
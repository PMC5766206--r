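# Monte Carlo simulated-annealing sequence design over the mutable positions
# of a network specification.

#' Annealing schedule
#'
#' Geometric cooling: the temperature starts at `t_initial` (objective
#' units, not Kelvin) and is multiplied by `cooling` after every block of
#' `steps_per_temperature` proposals.  The defaults are sized so that the
#' bundled three-species fixture chains converge in well under a minute on
#' one CPU.
#'
#' @param t_initial Initial annealing temperature (> 0).
#' @param cooling Multiplicative cooling factor in (0, 1).
#' @param steps_per_temperature Proposals per temperature block.
#' @param n_temperatures Number of temperature blocks (0 = evaluate only).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(t_initial = 5, cooling = 0.9,
                            steps_per_temperature = 100L,
                            n_temperatures = 40L) {
  if (t_initial <= 0 || cooling <= 0 || cooling >= 1 ||
      steps_per_temperature < 1 || n_temperatures < 0) {
    abort("invalid annealing schedule", class = "ribochain_input_error")
  }
  structure(list(t_initial = t_initial, cooling = cooling,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 n_temperatures = as.integer(n_temperatures)),
            class = "anneal_schedule")
}

#' Propose a single-point mutation
#'
#' Chooses one mutable position uniformly over all species' mutability masks
#' and substitutes a uniformly chosen different base.  Fixed regions are
#' never touched.  Uses (and advances) R's global RNG.
#'
#' @param seqs Named list of sequence strings.
#' @param masks Named list of logical mutability masks (same lengths).
#' @return A list with the mutated `seqs` plus `species`, `pos` (0-based),
#'   `from`, `to`.
#' @export
propose_mutation <- function(seqs, masks) {
  ids <- names(seqs)
  counts <- vapply(ids, function(id) sum(masks[[id]]), 0L)
  total <- sum(counts)
  if (total == 0L) {
    abort("no mutable positions in the network", class = "ribochain_config_error")
  }
  k <- sample.int(total, 1L)
  cum <- cumsum(counts)
  si <- which(k <= cum)[1]
  id <- ids[si]
  pos <- which(masks[[id]])[k - c(0L, cum)[si]]
  old <- substr(seqs[[id]], pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
  substr(seqs[[id]], pos, pos) <- new
  list(seqs = seqs, species = id, pos = pos - 1L, from = old, to = new)
}

#' Metropolis acceptance
#'
#' Accepts a proposal with probability `min(1, exp(-delta / temperature))`.
#'
#' @param delta Objective change (proposal minus current).
#' @param temperature Annealing temperature (> 0).
#' @return Logical.
#' @export
metropolis_accept <- function(delta, temperature) {
  if (temperature <= 0) {
    abort("annealing temperature must be > 0", class = "ribochain_input_error")
  }
  if (delta <= 0) return(TRUE)
  runif(1) < exp(-delta / temperature)
}

#' Design the sequences of a network by simulated annealing
#'
#' Runs the Metropolis/annealing loop over the mutable positions of `net`,
#' minimizing [total_objective()].  Species with all-`FALSE` masks are frozen
#' (sequential design); unassigned mutable positions are initialized
#' uniformly at random.  The full run is reproducible from the seed.
#'
#' @param net A `network_spec`.
#' @param schedule [anneal_schedule()]; overrides `net$schedule` when given.
#' @param weights [objective_weights()]; overrides `net$weights` when given.
#' @param seed Integer seed (mandatory: design runs are stochastic).
#' @param model Energy model.
#' @return A `design_result`: `best_sequences`, `best_objective`,
#'   `best_breakdown`, `trace` (tibble: step, temperature, objective,
#'   proposal, accepted, best), `seed`, `schedule`, `backend`.
#' @export
design <- function(net, schedule = NULL, weights = NULL, seed,
                   model = toy_energy_model()) {
  schedule <- schedule %||% net$schedule
  w <- weights %||% net$weights
  if (missing(seed)) abort("a seed is required for design runs",
                           class = "ribochain_input_error")
  set.seed(as.integer(seed))
  masks <- setNames(net$species$mutable, net$species$id)
  seqs <- network_sequences(net)
  # initialize: fixed-region content, then random bases elsewhere if missing
  for (i in seq_len(nrow(net$species))) {
    id <- net$species$id[i]
    len <- net$species$length[i]
    if (is.na(seqs[[id]])) {
      chars <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      for (fx in net$species$fixed[[i]]) {
        wnd <- check_window(fx$window, len, "fixed region")
        if (wnd[2] > wnd[1]) chars[(wnd[1] + 1L):wnd[2]] <- strsplit(fx$seq, "")[[1]]
      }
      seqs[[id]] <- paste(chars, collapse = "")
    }
  }
  has_mutable <- any(vapply(masks, any, TRUE))
  fold_cache_on()
  on.exit(fold_cache_off(), add = TRUE)
  plan <- objective_plan(net, w)
  score <- function(sq) sum(eval_objective_plan(plan, sq, model)$value)
  cur <- score(seqs)
  best <- cur; best_seqs <- seqs
  trace <- list()
  step <- 0L
  if (has_mutable && schedule$n_temperatures > 0L) {
    # flatten the mutability masks once; proposals index into this table
    temp <- schedule$t_initial
    for (b in seq_len(schedule$n_temperatures)) {
      for (s in seq_len(schedule$steps_per_temperature)) {
        step <- step + 1L
        prop <- propose_mutation(seqs, masks)
        prop_obj <- score(prop$seqs)
        acc <- metropolis_accept(prop_obj - cur, temp)
        if (acc) {
          seqs <- prop$seqs; cur <- prop_obj
          if (cur < best) { best <- cur; best_seqs <- seqs }
        }
        trace[[step]] <- c(step = step, temperature = temp,
                           objective = cur, proposal = prop_obj,
                           accepted = as.numeric(acc), best = best)
      }
      temp <- temp * schedule$cooling
    }
  }
  best_bd <- total_objective(set_sequences(net, best_seqs), model, w)
  trace <- if (length(trace)) {
    tibble::as_tibble(as.data.frame(do.call(rbind, trace)))
  } else {
    tibble::tibble(step = integer(0), temperature = numeric(0),
                   objective = numeric(0), proposal = numeric(0),
                   accepted = numeric(0), best = numeric(0))
  }
  if (nrow(trace)) trace$accepted <- trace$accepted == 1
  structure(
    list(best_sequences = best_seqs, best_objective = best,
         best_breakdown = best_bd, trace = trace, seed = as.integer(seed),
         schedule = schedule, backend = backend_id(model)),
    class = "design_result")
}

#' Evaluate a fully specified network
#'
#' Rational-design mode: no mutation, just the objective breakdown and a full
#' per-interaction energetics report (declared desired interactions with
#' their activation energies, implicit undesired pairs, and homodimers
#' reported separately).
#'
#' @param net A `network_spec` with all sequences assigned.
#' @param model Energy model.
#' @param weights Overrides `net$weights`.
#' @return A list of class `evaluation_result` with `breakdown`
#'   (an `objective_breakdown`), `objective` (its total), `energetics`
#'   (tibble: upstream, downstream, desired, dG_hyb, dG_act, backend_id) and
#'   `homodimers` (tibble: id, dG_hyb).
#' @export
evaluate <- function(net, model = toy_energy_model(), weights = NULL) {
  if (!assigned(net)) {
    abort("all species must carry sequences", class = "ribochain_state_error")
  }
  bd <- total_objective(net, model, weights)
  rows <- list()
  for (r in seq_len(nrow(net$interactions))) {
    row <- net$interactions[r, ]
    e <- interaction_row_energetics(net, row, model)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      upstream = row$upstream, downstream = row$downstream,
      desired = row$desired, dG_hyb = e$dG_hyb, dG_act = e$dG_act,
      backend_id = e$backend)
  }
  for (pr in implicit_undesired_pairs(net)) {
    d <- undesired_energetics(net, pr[1], pr[2], model)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      upstream = pr[1], downstream = pr[2], desired = FALSE,
      dG_hyb = d, dG_act = NA_real_, backend_id = backend_id(model))
  }
  homo <- lapply(net$species$id, function(id) {
    s <- network_sequences(net)[[id]]
    tibble::tibble(id = id,
                   dG_hyb = undesired_energetics(net, id, id, model))
  })
  structure(list(breakdown = bd, objective = objective_total(bd),
                 energetics = dplyr::bind_rows(rows),
                 homodimers = dplyr::bind_rows(homo)),
            class = "evaluation_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> best objective %.3f after %d steps (seed %d)\n",
              x$best_objective, nrow(x$trace), x$seed))
  invisible(x)
}

#' @export
tidy.design_result <- function(x, ...) x$trace

#' @export
glance.design_result <- function(x, ...) {
  tibble::tibble(best_objective = x$best_objective, steps = nrow(x$trace),
                 accept_rate = if (nrow(x$trace)) mean(x$trace$accepted) else NA_real_,
                 seed = x$seed, backend = x$backend)
}

#' Plot an annealing trace
#'
#' Current and best-so-far objective against the proposal step.
#'
#' @param object A `design_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.design_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("objective", "best"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "annealing step", y = "objective",
                  color = NULL) +
    ggplot2::theme_minimal()
}
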
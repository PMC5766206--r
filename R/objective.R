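# The empirical linear design objective: a weighted sum of interaction
# energetics (desired favored, undesired penalized), RBS occlusion/exposure
# terms, and structural sub-objectives.  Lower is better; the designer
# minimizes it.

#' Objective weights
#'
#' All terms enter an additive, linear objective.  `alpha_act` sets the
#' relative weight of the activation energy versus the hybridization energy
#' inside an interaction term; the default 1.0 scores the plain sum
#' `dG_hyb + dG_act`.  With `undesired_hinge = TRUE` undesired interactions
#' are penalized only when their aggregate energy is favorable (< 0),
#' instead of being maximized outright.
#'
#' @param w_desired,w_undesired,w_rbs_off,w_rbs_on,w_struct Non-negative
#'   term weights, default 1.
#' @param alpha_act Non-negative weight of `dG_act` within a term.
#' @param undesired_hinge Use the hinge variant for undesired terms.
#' @return An `objective_weights` list.
#' @export
objective_weights <- function(w_desired = 1, w_undesired = 1,
                              w_rbs_off = 1, w_rbs_on = 1, w_struct = 1,
                              alpha_act = 1, undesired_hinge = FALSE) {
  w <- list(w_desired = w_desired, w_undesired = w_undesired,
            w_rbs_off = w_rbs_off, w_rbs_on = w_rbs_on, w_struct = w_struct,
            alpha_act = alpha_act, undesired_hinge = undesired_hinge)
  nums <- unlist(w[1:6])
  if (any(!is.finite(nums)) || any(nums < 0)) {
    abort("objective weights must be finite and >= 0",
          class = "ribochain_input_error")
  }
  structure(w, class = "objective_weights")
}

#' Score one interaction
#'
#' Desired interactions contribute `+w_desired * (dG_hyb + alpha_act *
#' dG_act)` (more negative is better); undesired interactions contribute the
#' negated aggregate, so that favorable off-target energies raise the
#' objective.
#'
#' @param e An `interaction_energetics` object (or a list with `dG_hyb`,
#'   `dG_act`).
#' @param desired Logical flag.
#' @param w [objective_weights()].
#' @return Scalar score.
#' @export
interaction_term <- function(e, desired, w = objective_weights()) {
  agg <- e$dG_hyb + w$alpha_act * e$dG_act
  if (desired) {
    w$w_desired * agg
  } else if (isTRUE(w$undesired_hinge)) {
    -w$w_undesired * min(agg, 0)
  } else {
    -w$w_undesired * agg
  }
}

#' Score RBS occlusion (OFF) and exposure (ON)
#'
#' Rewards a high opening energy of the ribosome-binding site in the
#' unhybridized 5' UTR (cis-repression, OFF) and penalizes residual
#' occlusion in the ON complex:
#' `-w_rbs_off * opening(RBS | OFF) + w_rbs_on * opening(RBS | ON)`.
#'
#' @param utr 5' UTR (SRRR) sequence.
#' @param on_complex `complex_state` containing the UTR in its ON state.
#' @param rbs_window 0-based half-open RBS window on the UTR.
#' @param utr_id Strand id of the UTR within `on_complex`.
#' @param w [objective_weights()].
#' @param model Energy model.
#' @return Scalar score (list attribute-free); use [total_objective()] for a
#'   per-term breakdown.
#' @export
rbs_term <- function(utr, on_complex, rbs_window, utr_id,
                     w = objective_weights(), model = toy_energy_model()) {
  if (is.null(rbs_window)) {
    abort("the SRRR species carries no rbs_window", class = "ribochain_spec_error")
  }
  off_open <- opening_energy(utr, rbs_window, model)
  on_open <- opening_energy(on_complex, rbs_window, model, strand = utr_id)
  -w$w_rbs_off * off_open + w$w_rbs_on * on_open
}

#' Score a structural sub-objective
#'
#' `w_struct` times the base-pair distance between the realized and the
#' target structure.  Sub-objectives bias the design toward specified
#' structures without enforcing them as constraints.
#'
#' @param actual,target Dot-bracket strings of equal length.
#' @param w [objective_weights()].
#' @return Scalar score >= 0.
#' @export
structure_term <- function(actual, target, w = objective_weights()) {
  w$w_struct * bp_distance(actual, target)
}

# -- precompiled evaluation plan ---------------------------------------------
# The annealing loop re-scores thousands of proposals; extracting the spec
# into plain lists once avoids per-step tibble subsetting.

objective_plan <- function(net, weights = NULL) {
  w <- weights %||% net$weights
  inter <- lapply(seq_len(nrow(net$interactions)), function(r) {
    row <- net$interactions[r, ]
    list(name = paste(row$upstream, "->", row$downstream),
         up_members = node_members(row$upstream),
         downstream = row$downstream,
         desired = row$desired,
         up_window = as.integer(row$up_window[[1]]),
         down_window = as.integer(row$down_window[[1]]),
         up_strand = if (!is.na(row$up_strand)) row$up_strand else NULL)
  })
  list(inter = inter,
       undesired = implicit_undesired_pairs(net),
       rbs_window = net$rbs_window,
       platform = if (!is.null(net$rbs_window)) platform_id(net) else NULL,
       on_members = net$species$id,
       subobjectives = net$subobjectives,
       weights = w)
}

# Left-deep hierarchical assembly in a minimal container (energies plus the
# frozen intermolecular pair set; no S3 wrapping).
assemble_fast <- function(seqs, model) {
  cur_seq <- seqs[[1]]
  cuts <- integer(0)
  frozen <- matrix(integer(0), ncol = 2)
  if (length(seqs) == 1L) {
    return(list(seq = cur_seq, cuts = cuts, frozen = frozen,
                offsets = setNames(0L, names(seqs)),
                energy = fold_raw(model, cur_seq, want_structure = FALSE)$energy))
  }
  energy <- NA_real_
  for (k in seq_along(seqs)[-1]) {
    cuts <- c(cuts, nchar(cur_seq))
    cur_seq <- paste0(cur_seq, seqs[[k]])
    fp <- rep(-1L, nchar(cur_seq))
    if (nrow(frozen)) {
      fp[frozen[, 1] + 1L] <- frozen[, 2]
      fp[frozen[, 2] + 1L] <- frozen[, 1]
    }
    raw <- fold_raw(model, cur_seq, cuts = cuts, forced_partner = fp)
    frozen <- intermolecular_pairs(parse_dotbracket(raw$db)$pairs, cuts)
    energy <- raw$energy
  }
  lens <- vapply(seqs, nchar, 0L)
  list(seq = cur_seq, cuts = as.integer(cuts), frozen = frozen,
       offsets = setNames(cumsum(c(0L, lens[-length(lens)])), names(seqs)),
       energy = energy)
}

# Opening energy of a window inside an assemble_fast() state (frozen pairs
# retained except those touching the window).
opening_fast <- function(fc, strand, window, model) {
  if (window[1] == window[2]) return(0)
  gidx <- fc$offsets[[strand]] + (window[1] + 1L):window[2]
  n <- nchar(fc$seq)
  fu <- rep(FALSE, n)
  fu[gidx] <- TRUE
  fp <- rep(-1L, n)
  if (nrow(fc$frozen)) for (r in seq_len(nrow(fc$frozen))) {
    i <- fc$frozen[r, 1]; j <- fc$frozen[r, 2]
    if ((i + 1L) %in% gidx || (j + 1L) %in% gidx) next
    fp[i + 1L] <- j; fp[j + 1L] <- i
  }
  e <- fold_raw(model, fc$seq, cuts = fc$cuts, forced_unpaired = fu,
                forced_partner = fp, want_structure = FALSE)$energy - fc$energy
  if (abs(e) < 1e-9) 0 else max(e, 0)
}

opening_mono <- function(seq, window, model) {
  if (window[1] == window[2]) return(0)
  fu <- rep(FALSE, nchar(seq))
  fu[(window[1] + 1L):window[2]] <- TRUE
  e <- fold_raw(model, seq, forced_unpaired = fu,
                want_structure = FALSE)$energy -
    fold_raw(model, seq, want_structure = FALSE)$energy
  if (abs(e) < 1e-9) 0 else max(e, 0)
}

# dG_hyb of (possibly multi-strand) upstream node vs a downstream strand.
hyb_fast <- function(up_seqs, down, model) {
  if (length(up_seqs) == 1L) {
    e_up <- fold_raw(model, up_seqs[[1]], want_structure = FALSE)$energy
    joint <- fold_raw(model, paste0(up_seqs[[1]], down),
                      cuts = nchar(up_seqs[[1]]),
                      want_structure = FALSE)$energy
    fc <- NULL
  } else {
    fc <- assemble_fast(up_seqs, model)
    e_up <- fc$energy
    n_up <- nchar(fc$seq)
    fp <- rep(-1L, n_up + nchar(down))
    if (nrow(fc$frozen)) {
      fp[fc$frozen[, 1] + 1L] <- fc$frozen[, 2]
      fp[fc$frozen[, 2] + 1L] <- fc$frozen[, 1]
    }
    joint <- fold_raw(model, paste0(fc$seq, down),
                      cuts = c(fc$cuts, n_up), forced_partner = fp,
                      want_structure = FALSE)$energy
  }
  e_down <- fold_raw(model, down, want_structure = FALSE)$energy
  d <- joint - e_up - e_down
  list(dG_hyb = if (abs(d) < 1e-9) 0 else d, fc = fc)
}

# Evaluate all objective terms for a sequence assignment; returns parallel
# vectors (term, type, value).
eval_objective_plan <- function(plan, seqs, model) {
  w <- plan$weights
  nm <- character(0); ty <- character(0); val <- numeric(0)
  add <- function(term, type, value) {
    nm[length(nm) + 1L] <<- term
    ty[length(ty) + 1L] <<- type
    val[length(val) + 1L] <<- value
  }
  for (it in plan$inter) {
    up_seqs <- unlist(seqs[it$up_members])
    down <- seqs[[it$downstream]]
    h <- hyb_fast(up_seqs, down, model)
    act <- if (is.null(h$fc)) {
      opening_mono(up_seqs[[1]], it$up_window, model)
    } else {
      opening_fast(h$fc, it$up_strand, it$up_window, model)
    }
    act <- act + opening_mono(down, it$down_window, model)
    add(it$name, if (it$desired) "desired" else "undesired",
        interaction_term(list(dG_hyb = h$dG_hyb, dG_act = act), it$desired, w))
  }
  for (pr in plan$undesired) {
    a <- node_members(pr[1]); b <- pr[2]
    h <- hyb_fast(unlist(seqs[a]), seqs[[b]], model)
    add(paste(pr[1], "->", pr[2]), "undesired",
        interaction_term(list(dG_hyb = h$dG_hyb, dG_act = 0), FALSE, w))
  }
  if (!is.null(plan$rbs_window)) {
    off_open <- opening_mono(seqs[[plan$platform]], plan$rbs_window, model)
    fc <- assemble_fast(unlist(seqs[plan$on_members]), model)
    on_open <- opening_fast(fc, plan$platform, plan$rbs_window, model)
    add("rbs", "rbs", -w$w_rbs_off * off_open + w$w_rbs_on * on_open)
  }
  for (id in names(plan$subobjectives)) {
    members <- node_members(id)
    actual <- if (length(members) == 1L) {
      fold_raw(model, seqs[[id]])$db
    } else {
      fc <- assemble_fast(unlist(seqs[members]), model)
      fold_raw(model, fc$seq, cuts = fc$cuts)$db
    }
    add(paste0("structure:", id), "structure",
        structure_term(actual,
                       gsub("&", "", plan$subobjectives[[id]], fixed = TRUE), w))
  }
  list(term = nm, type = ty, value = val)
}

#' Full objective of a network
#'
#' Sums interaction terms over all declared desired and implicitly undesired
#' pairs, the RBS occlusion/exposure term (when an `rbs_window` is declared)
#' and all structural sub-objectives.  Returns a per-term breakdown whose
#' values add up to the total.
#'
#' @param net A `network_spec` with all sequences assigned.
#' @param model Energy model.
#' @param weights Overrides `net$weights` when given.
#' @return An `objective_breakdown`: a tibble with columns `term`, `type`,
#'   `value` and attributes `total` and `backend`; see also
#'   [glance.objective_breakdown()].
#' @export
total_objective <- function(net, model = toy_energy_model(), weights = NULL) {
  if (!assigned(net)) {
    abort("all species must carry sequences", class = "ribochain_state_error")
  }
  plan <- objective_plan(net, weights)
  ev <- eval_objective_plan(plan, network_sequences(net), model)
  out <- tibble::tibble(term = ev$term, type = ev$type, value = ev$value)
  structure(out, total = sum(out$value), backend = backend_id(model),
            class = c("objective_breakdown", class(out)))
}

# The ON-state complex: all species joined along the desired chain, platform
# last (chain order = species table order).
on_complex_id <- function(net) paste(net$species$id, collapse = "+")

#' @export
glance.objective_breakdown <- function(x, ...) {
  tibble::tibble(total = attr(x, "total"), n_terms = nrow(x),
                 backend = attr(x, "backend"))
}

#' Total of an objective breakdown
#'
#' @param x An `objective_breakdown`.
#' @return Scalar total (sum of the per-term values).
#' @export
objective_total <- function(x) attr(x, "total")
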
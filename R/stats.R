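# Model-validation statistics: induction-state objective energies, Pearson
# correlation with a two-tailed Student t-based test, and the energy/activity
# regression.

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper: requires equal lengths >= 3 and non-degenerate
#' variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with n >= 3", class = "ribochain_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "ribochain_input_error")
  }
  cor(x, y)
}

#' Two-tailed Student t-based correlation test
#'
#' For a Pearson coefficient `r` on `n` observations the statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` follows a Student t distribution with
#' `n - 2` degrees of freedom under the null of no correlation; the reported
#' p-value is two-tailed.
#'
#' @param r Pearson correlation coefficient.
#' @param n Sample size (>= 3).
#' @return A `correlation_result`: `r`, `n`, `df`, `t`, `p`, `degenerate`
#'   (`TRUE` when `|r| = 1`, in which case `p = 0` exactly).
#' @examples
#' correlation_test(0.758, 12)   # t ~ 3.67, p ~ 0.004
#' correlation_test(-0.735, 15)  # p ~ 0.002
#' @export
correlation_test <- function(r, n) {
  if (n < 3) abort("n must be >= 3", class = "ribochain_input_error")
  if (abs(r) > 1) abort("|r| must be <= 1", class = "ribochain_input_error")
  df <- n - 2
  if (abs(r) == 1) {
    res <- list(r = r, n = as.integer(n), df = df, t = sign(r) * Inf, p = 0,
                degenerate = TRUE)
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t), df)
    res <- list(r = r, n = as.integer(n), df = df, t = t, p = p,
                degenerate = FALSE)
  }
  structure(res, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, t = %.3f, df = %d, two-tailed P = %.4g)\n",
              x$r, x$n, x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n, t = x$t, df = x$df, p.value = x$p,
                 degenerate = x$degenerate)
}

#' @export
glance.correlation_result <- function(x, ...) tidy(x)

#' Objective free energy of an induced state
#'
#' For a chain network read out by gene expression, each induced state is
#' scored by the free energies of hybridization and activation between the
#' active upstream node and the 5' UTR, plus the energy required to
#' de-repress the RBS within the resulting intermolecular complex:
#' * `"both"`: upstream node = the assembled sRNA complex (SRR*),
#' * `"aTc"`: SRR alone, `"IPTG"`: SR alone,
#' * `"uninduced"`: reference state, energy 0.
#'
#' @param net A `network_spec` (3-species chain with `rbs_window`).
#' @param state One of `"uninduced"`, `"aTc"`, `"IPTG"`, `"both"`.
#' @param model Energy model.
#' @return Energy in kcal/mol.
#' @export
induction_objective_energy <- function(net, state = c("uninduced", "aTc",
                                                      "IPTG", "both"),
                                       model = toy_energy_model()) {
  state <- match.arg(state)
  if (state == "uninduced") return(0)
  if (is.null(net$rbs_window)) {
    abort("network has no rbs_window", class = "ribochain_spec_error")
  }
  plat <- platform_id(net)
  seqs <- network_sequences(net)
  plat_int <- which(net$interactions$desired &
                      net$interactions$downstream == plat)
  if (length(plat_int) != 1L) {
    abort("network must declare exactly one platform interaction",
          class = "ribochain_spec_error")
  }
  prow <- net$interactions[plat_int, ]
  down_window <- prow$down_window[[1]]
  sr_id <- net$species$id[net$species$role == "SR"][1]
  srr_id <- net$species$id[net$species$role == "SRR"][1]

  if (state == "both") {
    up <- resolve_node(net, prow$upstream, model)
    up_strand <- if (!is.na(prow$up_strand)) prow$up_strand else NULL
    e <- interaction_energetics(up, seqs[[plat]], prow$up_window[[1]],
                                down_window, up_strand = up_strand,
                                model = model)
    members <- c(node_members(prow$upstream), plat)
  } else {
    up_id <- if (state == "aTc") srr_id else sr_id
    # the window on the single sRNA: reuse its declared window (the platform
    # interaction's window when it lives on this strand, else its own
    # desired-interaction window)
    if (!is.na(prow$up_strand) && identical(prow$up_strand, up_id)) {
      upw <- prow$up_window[[1]]
    } else {
      own <- which(net$interactions$desired &
                     net$interactions$upstream == up_id)
      upw <- if (length(own)) net$interactions$up_window[[own[1]]] else
        c(0L, nchar(seqs[[up_id]]))
    }
    e <- interaction_energetics(seqs[[up_id]], seqs[[plat]], upw,
                                down_window, model = model)
    members <- c(up_id, plat)
  }
  cplx <- assemble_complex(setNames(seqs[members], members), model = model)
  derepression <- opening_energy(cplx, net$rbs_window, model, strand = plat)
  e$dG_hyb + e$dG_act + derepression
}

#' Regress measured activity (log scale) on predicted energy
#'
#' Ordinary least squares of `log(measured)` on `energy` (natural log), with
#' the associated two-tailed correlation test.  Used both for apparent-Kd
#' versus hybridization-energy comparisons and for activation-fold versus
#' objective-energy comparisons.
#'
#' @param records Data frame with the predictor and response columns.
#' @param energy,measured Column names (strings) of the predictor (kcal/mol)
#'   and the strictly positive measured quantity.
#' @return An `energy_activity_fit`: `slope`, `intercept`, `cor`
#'   (a [correlation_test()] result), `fit` (the `lm`), `data`.
#' @export
energy_activity_regression <- function(records, energy = "energy",
                                       measured = "measured") {
  df <- as.data.frame(records)
  if (nrow(df) < 3) abort("need at least 3 records",
                          class = "ribochain_input_error")
  x <- df[[energy]]
  y <- df[[measured]]
  if (any(y <= 0)) abort("measured values must be > 0 for the log transform",
                         class = "ribochain_input_error")
  ly <- log(y)
  r <- pearson_r(x, ly)
  fit <- lm(ly ~ x)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         cor = correlation_test(r, length(x)), fit = fit,
         data = tibble::tibble(energy = x, log_measured = ly)),
    class = "energy_activity_fit")
}

#' @export
print.energy_activity_fit <- function(x, ...) {
  cat(sprintf("log(measured) = %.4g + %.4g * energy\n", x$intercept, x$slope))
  print(x$cor)
  invisible(x)
}

#' @export
tidy.energy_activity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "energy"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.energy_activity_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$cor$r,
                 n = x$cor$n, t = x$cor$t, df = x$cor$df, p.value = x$cor$p)
}

#' Plot an energy/activity regression
#'
#' Scatter of log-measured values against predicted energies with the fitted
#' line.
#'
#' @param object An `energy_activity_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.energy_activity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$energy, y = .data$log_measured)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(x = "predicted energy (kcal/mol)", y = "log(measured)") +
    ggplot2::theme_minimal()
}
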
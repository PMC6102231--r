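#' Plot a per-residue perturbation profile
#'
#' Bar plot of the chosen statistic (CSP or intensity change) against
#' residue number in the style of a titration figure panel: the black
#' horizontal line is the mean-plus-one-SD threshold, the orange line
#' the replicate-variability threshold, significant residues are filled
#' red, and residues broadened beyond detection are marked by arrows
#' coloured by region at the top of the panel.
#'
#' @param profile Output of [perturbation_profile()].
#' @param statistic `"csp"` (ppm) or `"intensity"` (percent).
#' @return A ggplot object.
#' @export
plot_perturbation <- function(profile, statistic = c("csp", "intensity")) {
  statistic <- match.arg(statistic)
  thr <- attr(profile, "thresholds")[[statistic]]
  col <- if (statistic == "csp") "csp" else "intensity_change_pct"
  sig <- if (statistic == "csp") "significant_csp" else "significant_intensity"
  ylab <- if (statistic == "csp") {
    expression(Delta * delta[NH] ~ "(ppm)")
  } else {
    "Intensity change (%)"
  }
  d <- dplyr::mutate(tibble::as_tibble(profile),
                     .value = .data[[col]],
                     .sig = .data[[sig]])
  broadened <- dplyr::filter(d, .data$status == "broadened")
  arrow_y <- max(d$.value, thr$black_line, na.rm = TRUE) * 1.08
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$residue,
                                       y = .data$.value)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$.sig),
                      show.legend = FALSE, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red3",
                                          `FALSE` = "grey40")) +
    ggplot2::geom_hline(yintercept = thr$black_line, colour = "black") +
    ggplot2::geom_hline(yintercept = thr$orange_line, colour = "orange") +
    ggplot2::labs(x = "Residue", y = ylab) +
    ggplot2::theme_classic()
  if (nrow(broadened) > 0) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(broadened, .value = arrow_y),
      ggplot2::aes(colour = .data$region), shape = 25, size = 2,
      na.rm = TRUE) +
      ggplot2::scale_colour_manual(
        values = c("N-terminal" = "pink2", "NAC" = "green4",
                   "C-terminal" = "purple3"),
        name = "Broadened")
  }
  p
}

#' Plot a line-width difference profile
#'
#' \eqn{\Delta LW} (condition minus reference, Hz) against residue
#' number, narrowing below zero and broadening above.
#'
#' @param lw Output of [compute_linewidth_diff()].
#' @param map Optional [region_map] used to colour the bars by region.
#' @return A ggplot object.
#' @export
plot_linewidth <- function(lw, map = NULL) {
  d <- tibble::as_tibble(lw)
  if (!is.null(map)) d$region <- classify_region(d$residue, map)
  aes <- if (!is.null(map)) {
    ggplot2::aes(x = .data$residue, y = .data$delta_lw,
                 fill = .data$region)
  } else {
    ggplot2::aes(x = .data$residue, y = .data$delta_lw)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Residue", y = expression(Delta * "LW (Hz)")) +
    ggplot2::theme_classic()
}

#' Plot a binding fit with its data
#'
#' Observed response against ligand concentration with the fitted curve
#' evaluated on a fine grid; error bars are drawn when the data carry a
#' `sem` column.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot binding_fit
autoplot.binding_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  d <- object$data
  grid <- tibble::tibble(
    ligand_conc = seq(min(d$L), max(d$L), length.out = 200))
  grid$fitted <- predict(object, grid)
  ylab <- if (object$model == "hill") {
    expression(delta[N] ~ "(ppm)")
  } else {
    "Mean intensity difference"
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$L, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$ligand_conc,
                                    y = .data$fitted),
                       colour = "blue3") +
    ggplot2::labs(x = expression("Ligand (" * mu * "M)"), y = ylab) +
    ggplot2::theme_classic()
  if (all(is.finite(d$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sem,
                   ymax = .data$y + .data$sem),
      width = 0)
  }
  p
}
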
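# ggplot2 views of the result objects.

#' Plot orthant probabilities
#'
#' Bar chart of the sampled direction-pattern probabilities, optionally
#' against a reference table (e.g. the rejection oracle).
#'
#' @param samples a `pta_samples` object or an orthant tibble.
#' @param reference optional second orthant tibble for comparison.
#' @param top show at most this many orthants.
#' @return a ggplot object.
#' @export
plot_orthants <- function(samples, reference = NULL, top = 20) {
  tab <- if (inherits(samples, "pta_samples")) samples$orthants else samples
  tab <- dplyr::slice_max(tab, .data$probability, n = top)
  tab$source <- "sampled"
  if (!is.null(reference)) {
    ref <- dplyr::semi_join(reference, tab, by = "signature")
    ref$source <- "reference"
    tab <- dplyr::bind_rows(tab[c("signature", "probability", "source")],
                            ref[c("signature", "probability", "source")])
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$signature,
                                                       -.data$probability),
                                    y = .data$probability,
                                    fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "direction pattern", y = "probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Marginal densities of sampled reaction energies
#'
#' @param object a `pta_samples` object.
#' @param ... unused.
#' @return a ggplot object (one facet per reaction, colored by chain).
#' @export
autoplot.pta_samples <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$dg,
                               color = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "reaction energy (kJ/mol)", color = "chain") +
    ggplot2::theme_minimal()
}

#' Flux sample histograms
#'
#' @param object a `pta_flux_samples` object.
#' @param reactions subset of reactions to show (default: all sampled).
#' @param ... unused.
#' @return a ggplot object, colored by source orthant.
#' @export
autoplot.pta_flux_samples <- function(object, reactions = NULL, ...) {
  df <- tidy(object)
  if (!is.null(reactions)) df <- df[df$reaction %in% reactions, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux, fill = .data$orthant)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", fill = "direction pattern") +
    ggplot2::theme_minimal()
}

#' Z-score overview of a PMO fit
#'
#' Lollipop plot of per-variable z-scores with the anomaly threshold.
#'
#' @param object a `pta_pmo` object.
#' @param theta threshold drawn as reference lines.
#' @param kind which variable block to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pta_pmo <- function(object, theta = 1,
                             kind = c("ln_c", "dg0", "dg"), ...) {
  kind <- match.arg(kind)
  df <- object$z[object$z$kind == kind, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$id, .data$z),
                                   y = .data$z)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$id, y = 0,
                                       yend = .data$z)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-theta, theta), linetype = 2,
                        color = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "z-score at the mode") +
    ggplot2::theme_minimal()
}
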
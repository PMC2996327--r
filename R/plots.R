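# ggplot2 graphics for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sectoring calibration curve
#'
#' Median visible sectors per colony against the per-division loss rate,
#' coloured by semi-quantitative class, with the class boundaries drawn.
#'
#' @param object An `ofm_calibration` from [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ofm_calibration
#' @export
autoplot.ofm_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mu, .data$median_sectors)) +
    ggplot2::geom_hline(yintercept = c(3.5, 9.5), linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "loss rate per division",
      y = "median visible sectors per colony",
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fluctuation assay against its fitted count distribution
#'
#' Overlays the Luria-Delbruck pmf implied by an estimate on the observed
#' per-culture count histogram (counts above `r_show` pooled).
#'
#' @param assay Assay tibble (one row per culture).
#' @param estimate A `loss_rate_est` for the same assay.
#' @param r_show Largest count shown individually.
#' @return A ggplot.
#' @export
plot_assay_fit <- function(assay, estimate, r_show = 20L) {
  v <- validate_assay(assay)
  counts <- pmin(v$counts, r_show)
  obs <- tibble::tibble(count = counts) |>
    dplyr::count(.data$count, name = "n") |>
    dplyr::mutate(freq = .data$n / sum(.data$n))
  p <- ld_pmf(estimate$m_hat, r_show)
  fit <- tibble::tibble(
    count = 0:r_show,
    freq = replace(p[seq_len(r_show + 1L)], r_show + 1L, attr(p, "truncation_mass") + p[r_show + 1L])
  )
  ggplot2::ggplot(obs, ggplot2::aes(.data$count, .data$freq)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_point(data = fit, colour = "firebrick") +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("loss-derived cells per culture (>= %d pooled)", r_show),
      y = "frequency",
      title = sprintf("m = %.3g (%s)", estimate$m_hat, estimate$method)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-origin firing fractions from a replication simulation
#'
#' @param object A `replication_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot replication_sim
#' @export
autoplot.replication_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$firing,
    ggplot2::aes(.data$origin, .data$firing_fraction)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "fraction of cells in which the origin fired",
      title = sprintf(
        "%s under %s: incomplete %.3g ± %.2g",
        object$construct, object$regime,
        object$incomplete_fraction, object$se
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot true versus estimated Ofm index for a virtual screen
#'
#' Strains called in the sectoring stage are shown with their verdicts;
#' the dashed line is identity.
#'
#' @param object A `virtual_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot virtual_screen
#' @export
autoplot.virtual_screen <- function(object, ...) {
  df <- dplyr::filter(object$per_strain, !is.na(.data$index_est))
  ggplot2::ggplot(df, ggplot2::aes(.data$index_true, .data$index_est)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$verdict, shape = .data$archetype)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "true Ofm index", y = "estimated Ofm index",
      colour = "verdict", shape = "truth"
    ) +
    ggplot2::theme_minimal()
}
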
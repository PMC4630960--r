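#' Plot a pyrogram
#'
#' Vertical peak-height lines, one per dispensation, labelled with the
#' dispensed base.
#'
#' @param signal A [pyro_signal()].
#' @return A ggplot object.
#' @export
plot_pyrogram <- function(signal) {
  df <- as_tibble(signal)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dispensation, y = .data$height)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$dispensation, yend = 0),
      linewidth = 1
    ) +
    ggplot2::scale_x_continuous(
      breaks = df$dispensation, labels = df$base,
      minor_breaks = NULL
    ) +
    ggplot2::labs(x = "dispensed nucleotide", y = "peak height") +
    ggplot2::theme_minimal()
}

#' Stacked-contribution plot of a decomposition
#'
#' Shows the observed multiplex pyro-signal as vertical lines and the fitted
#' sparse model as per-atom contributions stacked per dispensation, coloured
#' by SNP — the standard way to inspect how each uniplex atom explains the
#' multiplex signal.
#'
#' @param object A [decompose_pyrosignal()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pyro_decomposition
#' @export
autoplot.pyro_decomposition <- function(object, ...) {
  atoms <- object$atoms
  keep <- which(object$coefficients > 0)
  contrib <- purrr::map(keep, function(k) {
    tibble(
      dispensation = seq_along(atoms$signal[[k]]),
      height = object$coefficients[k] * atoms$signal[[k]],
      atom = atoms$atom_id[k],
      snp_id = atoms$snp_id[k]
    )
  }) |> bind_rows()
  obs <- tibble(
    dispensation = seq_along(object$observed),
    height = object$observed,
    base = strsplit(object$dispensations, "")[[1]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = contrib,
      ggplot2::aes(
        x = .data$dispensation, y = .data$height,
        fill = .data$snp_id, group = .data$atom
      ),
      width = 0.8
    ) +
    ggplot2::geom_segment(
      data = obs,
      ggplot2::aes(
        x = .data$dispensation, xend = .data$dispensation,
        y = 0, yend = .data$height
      ),
      linewidth = 0.6
    ) +
    ggplot2::scale_x_continuous(
      breaks = obs$dispensation, labels = obs$base,
      minor_breaks = NULL
    ) +
    ggplot2::labs(
      x = "dispensed nucleotide", y = "peak height", fill = "SNP",
      subtitle = sprintf("confidence R = %.4f", object$confidence_r)
    ) +
    ggplot2::theme_minimal()
}
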
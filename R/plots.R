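# Light ggplot2 helpers for the main result types.

#' Plot a contact matrix heat map
#'
#' @param m A [contact_matrix()].
#' @param trans Value transform for display: `"log1p"` (default) or
#'   `"identity"`.
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(m, trans = c("log1p", "identity")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plotting needs the ggplot2 package")
  }
  trans <- match.arg(trans)
  stopifnot(inherits(m, "contact_matrix"))
  nb <- n_bins(m)
  df <- expand.grid(i = seq_len(nb) - 1L, j = seq_len(nb) - 1L)
  df$value <- as.vector(m$values)
  if (trans == "log1p") df$value <- log1p(df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = j, y = i, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred", na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "bin", y = "bin", fill = if (trans == "log1p") "log1p(contacts)" else "contacts",
      title = sprintf("%s @ %d bp", m$chrom, m$resolution)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an insulation track with called boundaries
#'
#' @param track Tibble from [insulation()].
#' @param boundaries Optional 0-based boundary bins to mark (e.g. from
#'   [call_strong_boundaries()]).
#' @return A ggplot object.
#' @export
plot_insulation <- function(track, boundaries = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plotting needs the ggplot2 package")
  }
  p <- ggplot2::ggplot(
    track[track$valid, ],
    ggplot2::aes(x = bin, y = score)
  ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "bin", y = "insulation (log2)") +
    ggplot2::theme_minimal()
  if (length(boundaries)) {
    p <- p + ggplot2::geom_vline(
      xintercept = boundaries,
      linetype = "dashed", color = "firebrick", alpha = 0.6
    )
  }
  p
}

#' Plot a training-loss history
#'
#' @param history Tibble from [train()] (`$history`).
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plotting needs the ggplot2 package")
  }
  p <- ggplot2::ggplot(history, ggplot2::aes(x = epoch, y = train_loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
  if (any(is.finite(history$val_loss))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = val_loss), color = "firebrick")
  }
  p
}
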
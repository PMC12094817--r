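# ggplot2 companions for the two standard diagnostic figures; ggplot2 is an
# optional dependency

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot mean generation entropy against the number of sampling steps
#'
#' @param df Data frame with columns `steps`, `entropy` and optionally `se`
#'   (standard error, drawn as a ribbon).
#' @return A ggplot object.
#' @export
plot_entropy_vs_steps <- function(df) {
  .need_ggplot()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = steps, y = entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sampling steps", y = "generation entropy (nats/residue)") +
    ggplot2::theme_minimal()
  if ("se" %in% names(df))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = entropy - se,
                   ymax = entropy + se),
      alpha = 0.2, colour = NA)
  p
}

#' Plot masked-token prediction accuracy against interpolation time
#'
#' @param df Output of [unmasking_accuracy()].
#' @return A ggplot object.
#' @export
plot_accuracy_vs_time <- function(df) {
  .need_ggplot()
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = accuracy,
                                   colour = track)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "interpolation time t", y = "masked-token accuracy") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("steps", "entropy", "se", "t", "accuracy", "track"))
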
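#' Plot per-chromosome inversion evidence
#'
#' Diverging bar chart of transfer counts per chromosome (short-to-long
#' upward, long-to-short downward), coloured by evidence class.
#'
#' @param object An `inversion_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inversion_calls <- function(object, ...) {
  df <- tidy.inversion_calls(object) |>
    tidyr::pivot_longer(c("n_short_to_long", "n_long_to_short"),
                        names_to = "direction", values_to = "n") |>
    mutate(
      n_signed = ifelse(.data$direction == "n_long_to_short",
                        -.data$n, .data$n),
      direction = ifelse(.data$direction == "n_long_to_short",
                         "long to short arm", "short to long arm")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome,
                                   y = .data$n_signed,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_continuous(labels = abs) +
    ggplot2::labs(
      x = NULL,
      y = "genes transferred (long-to-short | short-to-long)",
      fill = "evidence",
      title = "Genes with nonstandard homoeologous arm locations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot classification outcomes of a run
#'
#' Bar chart of per-gene status counts from [classify_arm_patterns()].
#'
#' @param object An `arm_patterns` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arm_patterns <- function(object, ...) {
  df <- object |>
    as_tibble() |>
    count(.data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$status, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Arm-pattern classification outcomes") +
    ggplot2::theme_minimal()
}
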
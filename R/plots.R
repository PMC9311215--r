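#' Scree plot for scan-axis choice
#'
#' @param ck A [choose_k()] result.
#' @return A ggplot object; the chosen k is marked with a dashed line.
#' @export
plot_scree <- function(ck) {
  ggplot2::ggplot(ck$scree, ggplot2::aes(.data$axis, .data$prop_var)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = ck$k, linetype = 2) +
    ggplot2::labs(x = "principal component", y = "proportion of variance") +
    ggplot2::theme_minimal()
}

#' Candidate-set plot for a classified GEA table
#'
#' One point per locus x variable pair, -log10 combined q against locus
#' index, coloured by confidence class.
#'
#' @param gea A [classify_gea()] table.
#' @return A ggplot object.
#' @export
plot_gea_classes <- function(gea) {
  tab <- gea %>%
    group_by(.data$variable) %>%
    mutate(index = dplyr::row_number()) %>%
    ungroup()
  ggplot2::ggplot(
    tab,
    ggplot2::aes(.data$index, -log10(pmax(.data$q_combined, 1e-300)),
                 colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.7, size = 0.8) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "locus index", y = expression(-log[10](q[combined]))) +
    ggplot2::theme_minimal()
}
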
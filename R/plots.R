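#' Marey-map plot
#'
#' Cumulative genetic position against physical position, one facet
#' per chromosome; the local slope is the recombination rate.
#'
#' @param markers Canonical marker tibble.
#' @return A ggplot.
#' @export
plot_marey <- function(markers) {
  ggplot2::ggplot(markers,
                  ggplot2::aes(x = .data$phys_bp / 1e6, y = .data$gen_cm,
                               colour = .data$population)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom_id), scales = "free") +
    ggplot2::labs(x = "physical position (Mb)", y = "genetic position (cM)") +
    ggplot2::theme_minimal()
}

#' Folded recombination-rate profile plot
#'
#' Window rates against folded position (0 = chromosome center,
#' 0.5 = end), split by chromosome size class, with a LOESS curve per
#' class.
#'
#' @param profile [folded_profile()] output.
#' @param span LOESS span.
#' @return A ggplot.
#' @export
plot_folded_profile <- function(profile, span = 0.75) {
  df <- dplyr::filter(profile, !is.na(.data$rate_cm_per_mb))
  smooth <- df |>
    dplyr::group_by(.data$size_class) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(d) {
      if (nrow(d) < 5L) return(NULL)
      dplyr::mutate(
        loess_smooth(d, "folded_pos", "rate_cm_per_mb", span = span),
        size_class = d$size_class[[1]])
    })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$folded_pos,
                                   y = .data$rate_cm_per_mb,
                                   colour = .data$size_class)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = smooth,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$size_class),
                       linewidth = 1) +
    ggplot2::labs(x = "folded position (0 = center, 0.5 = end)",
                  y = "recombination rate (cM/Mb)", colour = "chromosome size") +
    ggplot2::theme_minimal()
}

#' Diversity against recombination rate
#'
#' Binned diversity as a function of binned recombination rate, with
#' the saturating relationship visible as a LOESS curve.
#'
#' @param joined [join_to_recombination()] output.
#' @return A ggplot.
#' @export
plot_diversity_recombination <- function(joined) {
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$rate_cm_per_mb, y = .data$pi)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "recombination rate (cM/Mb)",
                  y = expression(pi)) +
    ggplot2::theme_minimal()
}
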
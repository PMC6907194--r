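#' Plot an eigenvalue profile
#'
#' Number of eigenvalues needed to explain each variance fraction, by
#' population size, on a log or linear count scale.
#'
#' @param profile Output of [eigen_profile_study()] (or the `profile` tibble
#'   of a [run_study()] result).
#' @param log_scale Plot counts on a log10 axis?
#' @return A ggplot object.
#' @export
plot_eigen_profile <- function(profile, log_scale = TRUE) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = 100 * .data$threshold,
                                    y = .data$n_eigenvalues,
                                    colour = factor(.data$n_genotyped),
                                    group = interaction(.data$n_genotyped,
                                                        .data$replicate))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "% of explained GRM variance",
                  y = "number of eigenvalues",
                  colour = "genotyped animals") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the cumulative variance curve of a GRM
#'
#' @param object A `grm_bundle` with eigenvalues.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grm_bundle <- function(object, ...) {
  cv <- cumulative_variance(object)
  ggplot2::ggplot(cv, ggplot2::aes(.data$index,
                                   .data$cumulative_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "eigenvalue rank", y = "cumulative variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot study accuracies against explained variance
#'
#' Mean realized accuracy (across replicates) of the eigen-truncated and APY
#' fits as a function of the explained-variance threshold, with the
#' standard-GRM accuracy as a horizontal reference, faceted by heritability
#' and population size.
#'
#' @param object A `grm_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grm_study <- function(object, ...) {
  s <- summarise_study(object)
  swept <- dplyr::filter(s, !is.na(.data$threshold))
  std <- dplyr::filter(s, .data$option == "standard")
  p <- ggplot2::ggplot(swept,
                       ggplot2::aes(100 * .data$threshold,
                                    .data$mean_accuracy,
                                    colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(h2 ~ n_genotyped,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "% of explained GRM variance",
                  y = "realized accuracy (cor(GEBV, TBV))") +
    ggplot2::theme_minimal()
  if (nrow(std) > 0)
    p <- p + ggplot2::geom_hline(data = std,
                                 ggplot2::aes(yintercept = .data$mean_accuracy),
                                 linetype = "dashed", colour = "grey40")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
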
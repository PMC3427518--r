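#' Tidy the particles of a fitted ABC-SMC run
#'
#' @param x An `abc_smc_fit`.
#' @param generation Which population to return (default: the final one).
#' @param ... Unused.
#' @return A tibble with one row per particle: model, the five parameter
#'   columns (`NA` where a parameter is inactive for the particle's model),
#'   normalized weight, acceptance count and realized distance.
#' @export
tidy.abc_smc_fit <- function(x, generation = NULL, ...) {
  gen <- generation %||% max(x$trace$generation)
  dplyr::filter(x$trace, .data$generation == gen)
}

#' One-row summary of a fitted ABC-SMC run
#'
#' @param x An `abc_smc_fit`.
#' @param ... Unused.
#' @return A tibble with particle/population counts, the final tolerance,
#'   the final generation's acceptance rate and its effective sample size
#'   (`1 / sum(w^2)`).
#' @export
glance.abc_smc_fit <- function(x, ...) {
  final <- tidy(x)
  tibble::tibble(
    n_particles = x$config$n_particles,
    n_populations = x$config$n_populations,
    n_models = length(x$models),
    final_epsilon = x$epsilons[length(x$epsilons)],
    acceptance_rate = nrow(final) / final$attempts[1L],
    ess = 1 / sum(final$weight^2)
  )
}

#' @export
print.abc_smc_fit <- function(x, ...) {
  cat("<abc_smc_fit> ", paste(x$models, collapse = "+"), ": ",
      x$config$n_particles, " particles x ", x$config$n_populations,
      " populations; final epsilon ",
      signif(x$epsilons[length(x$epsilons)], 4), "\n", sep = "")
  if (!is.null(x$model_posterior)) {
    cat("model posterior:\n")
    print(round(x$model_posterior, 3))
  }
  invisible(x)
}

#' Plot posterior parameter marginals of an ABC-SMC fit
#'
#' Weighted density of each active parameter in the chosen population,
#' faceted by parameter (and coloured by model for model-selection fits).
#'
#' @param object An `abc_smc_fit`.
#' @param generation Population to plot (default: final).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_smc_fit <- function(object, generation = NULL, ...) {
  final <- tidy(object, generation = generation)
  long <- tidyr::pivot_longer(final, cols = dplyr::any_of(.param_names),
                              names_to = "parameter", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, weight = .data$weight,
                                     colour = .data$model)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "posterior density",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot a marginal model posterior
#'
#' @param posterior Named probabilities, e.g. from
#'   [marginal_model_posterior()], or an `abc_smc_model_fit`.
#' @return A ggplot bar chart.
#' @export
plot_model_posterior <- function(posterior) {
  if (inherits(posterior, "abc_smc_fit")) posterior <- posterior$model_posterior
  df <- tibble::tibble(model = factor(names(posterior), levels = names(posterior)),
                       probability = as.numeric(posterior))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "posterior model probability") +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution on log-log axes
#'
#' @param dd A tibble from [degree_distribution()] or
#'   [posterior_predictive_degree_distribution()], or a list of such tibbles
#'   (named, plotted as separate series).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(dd) {
  if (is.data.frame(dd)) dd <- list(observed = dd)
  df <- dplyr::bind_rows(dd, .id = "series")
  df <- dplyr::filter(df, .data$degree > 0, .data$probability > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$probability,
                                   colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)", colour = NULL) +
    ggplot2::theme_minimal()
}
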
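#' Posterior-model-probability-weighted average of a statistic
#'
#' Pools a statistic computed under each candidate model into a single
#' estimate, weighting by the marginal model posterior.  Statistics may be
#' scalars or vectors (e.g. degree distributions); vectors of unequal length
#' are aligned by right-padding with zeros, so pooled probability vectors
#' remain probability vectors.
#'
#' @param posterior Named model-posterior probabilities (summing to 1), as
#'   from [marginal_model_posterior()].
#' @param values Named list of per-model statistic values.  Every model with
#'   positive posterior probability must be present; models with zero
#'   posterior may be omitted.
#' @return The pooled statistic (scalar or vector).
#' @examples
#' model_averaged_statistic(c(A = 0.5, B = 0.5), list(A = 2, B = 4))
#' @export
model_averaged_statistic <- function(posterior, values) {
  if (abs(sum(posterior) - 1) > 1e-8) {
    stop("model posterior probabilities must sum to 1", call. = FALSE)
  }
  need <- names(posterior)[posterior > 0]
  missing <- setdiff(need, names(values))
  if (length(missing) > 0L) {
    stop("no statistic supplied for model(s) with positive posterior: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  len <- max(vapply(values[need], length, integer(1)))
  pooled <- numeric(len)
  for (mm in need) {
    v <- values[[mm]]
    pooled <- pooled + posterior[[mm]] * c(v, numeric(len - length(v)))
  }
  pooled
}

#' Posterior-predictive degree distribution with degree-zero correction
#'
#' Reconstructs the degree distribution implied by a fitted posterior:
#' particles are resampled from the final population by weight (which
#' averages over models in proportion to their marginal posterior), each
#' draw is simulated through the sampling scheme, and the per-draw degree
#' distributions are averaged.  Because observed interactome data never
#' contain degree-zero proteins, the pooled distribution is truncated to
#' degrees `k >= 1` and renormalized.
#'
#' @param fit An `abc_smc_fit` (or `abc_smc_model_fit`), or a data frame
#'   holding one population (model, parameter and normalized weight
#'   columns), in which case `sampling` must be supplied.
#' @param sampling [sampling_config()] describing the networks to predict:
#'   use `n_sampled = n_total` to predict the full network, or the fit's own
#'   sampling configuration to predict at the observed size.  Defaults to
#'   the configuration stored in the fit, or to plain growth at the data's
#'   size when the fit used none.
#' @param n_draws Number of posterior-predictive simulations (defaults to
#'   the particle count).
#' @return A tibble with columns `degree` (`>= 1`) and `probability`
#'   (summing to 1).
#' @export
posterior_predictive_degree_distribution <- function(fit, sampling = NULL,
                                                     n_draws = NULL) {
  if (is.data.frame(fit)) {
    final <- fit
    if (is.null(sampling)) {
      stop("`sampling` must be supplied when predicting from a bare population",
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(fit, "abc_smc_fit"))
    final <- tidy(fit)
    if (is.null(sampling)) {
      sampling <- fit$sampling %||%
        sampling_config(fit$data_summary$n_nodes, fit$data_summary$n_nodes)
    }
  }
  if (is.null(n_draws)) n_draws <- nrow(final)
  if (n_draws < 1L) stop("`n_draws` must be at least 1", call. = FALSE)
  idx <- sample.int(nrow(final), n_draws, replace = TRUE, prob = final$weight)
  max_k <- 0L
  dists <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    row <- final[idx[i], ]
    params <- unlist(row[active_parameters(row$model)])
    g <- simulate_with_sampling(row$model, params, sampling)
    dd <- degree_distribution(g)
    dists[[i]] <- dd
    max_k <- max(max_k, max(dd$degree))
  }
  pooled <- numeric(max_k + 1L)
  for (dd in dists) pooled[dd$degree + 1L] <- pooled[dd$degree + 1L] + dd$probability
  pooled <- pooled / n_draws
  pooled <- pooled[-1L]                       # degree-zero correction
  if (sum(pooled) <= 0) {
    stop("every posterior-predictive draw was edgeless; nothing remains ",
         "after restricting to degrees >= 1", call. = FALSE)
  }
  tibble::tibble(degree = seq_len(max_k), probability = pooled / sum(pooled))
}

#' Total variation distance between two degree distributions
#'
#' Convenience metric for comparing predictive and observed degree
#' distributions: half the L1 distance after aligning the supports.
#'
#' @param p,q Data frames with `degree` and `probability` columns (as
#'   returned by [degree_distribution()]), or bare probability vectors
#'   indexed from their first element.
#' @return Number in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      v <- numeric(max(x$degree) + 1L)
      v[x$degree + 1L] <- x$probability
      v
    } else as.numeric(x)
  }
  pv <- as_vec(p)
  qv <- as_vec(q)
  len <- max(length(pv), length(qv))
  sum(abs(c(pv, numeric(len - length(pv))) - c(qv, numeric(len - length(qv))))) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
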
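#' Model-perturbation kernel
#'
#' Discrete analogue of the Gaussian parameter kernel used when the model
#' identity is itself a particle coordinate: with probability `switch_prob`
#' the particle moves to a different model chosen uniformly at random, else
#' it stays put.
#'
#' @param current Current model code.
#' @param model_set Character vector of candidate models containing
#'   `current`.
#' @param switch_prob Probability of proposing a switch, in `[0, 1]`.
#' @param warn_singleton Emit the one-off note when a switch is requested
#'   but no alternative model exists.
#' @return A model code from `model_set`.
#' @export
perturb_model <- function(current, model_set, switch_prob,
                          warn_singleton = TRUE) {
  if (length(model_set) == 0L || !current %in% model_set) {
    stop("`current` must be a member of a nonempty `model_set`", call. = FALSE)
  }
  if (length(model_set) == 1L) {
    if (switch_prob > 0 && warn_singleton) {
      message("model kernel: only one model configured, switches are no-ops")
    }
    return(current)
  }
  if (runif(1L) < switch_prob) {
    others <- setdiff(model_set, current)
    if (length(others) == 1L) others else sample(others, 1L)
  } else {
    current
  }
}

#' Marginal posterior probability of each model
#'
#' The posterior probability of a model is the summed weight of the
#' particles carrying it, taken from a normalized population.
#'
#' @param population A data frame with `model` and `weight` columns whose
#'   weights sum to 1, or an `abc_smc_fit` (its final population is used).
#' @param model_set Optional character vector of all configured models, so
#'   models that lost every particle still appear with probability 0.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
marginal_model_posterior <- function(population, model_set = NULL) {
  if (inherits(population, "abc_smc_fit")) {
    if (is.null(model_set)) model_set <- population$models
    population <- tidy(population)
  }
  w <- population$weight
  if (abs(sum(w) - 1) > 1e-8) {
    stop("population weights are not normalized (sum = ", sum(w), ")",
         call. = FALSE)
  }
  if (is.null(model_set)) model_set <- unique(population$model)
  post <- vapply(setNames(model_set, model_set),
                 function(mm) sum(w[population$model == mm]), numeric(1))
  post
}

#' Importance weight of a joint (model, parameter) particle
#'
#' Extends [compute_weight()] to the joint space used by the model-selection
#' sampler: the numerator is model prior x parameter prior x acceptance
#' count, the denominator the proposal mass — the previous marginal model
#' probabilities pushed through the model kernel, times the within-model
#' Gaussian kernel mixture over the previous population's particles of the
#' proposed model (or the parameter prior density, if that model currently
#' has no particles).  With a single configured model it reduces exactly to
#' [compute_weight()].
#'
#' @param model Proposed model code.
#' @param params Proposed parameter vector (named, active parameters of
#'   `model`).
#' @param s Acceptance count (`> 0`).
#' @param prev_population Previous population: data frame with `model`,
#'   parameter and normalized `weight` columns, or `NULL` at the first
#'   generation (then the weight is `s`).
#' @param bandwidths Named list of per-model kernel bandwidth vectors.
#' @param priors Named list of per-model [prior_spec()]s.
#' @param switch_prob Model-switch probability of the kernel.
#' @param model_prior Named prior model probabilities (uniform by default).
#' @return Unnormalized nonnegative weight.
#' @export
compute_weight_joint <- function(model, params, s, prev_population = NULL,
                                 bandwidths = NULL, priors = NULL,
                                 switch_prob = 0.2, model_prior = NULL) {
  if (s <= 0) stop("zero-acceptance particles are rejected, not weighted", call. = FALSE)
  if (is.null(prev_population)) return(as.numeric(s))
  if (nrow(prev_population) == 0L) stop("previous population is empty", call. = FALSE)
  models <- names(priors)
  if (is.null(model_prior)) {
    model_prior <- setNames(rep(1 / length(models), length(models)), models)
  }
  marg <- vapply(setNames(models, models), function(mm) {
    sum(prev_population$weight[prev_population$model == mm])
  }, numeric(1))
  if (!model %in% models) stop("unknown model ", model, call. = FALSE)
  if (marg[[model]] == 0 && switch_prob == 0 && length(models) > 1L) {
    stop("model ", model, " cannot be proposed: no previous particles and ",
         "a zero switch probability", call. = FALSE)
  }
  prev <- list(model = prev_population$model,
               pmat = as.matrix(prev_population[, .param_names[
                 .param_names %in% names(prev_population)], drop = FALSE]),
               weight = prev_population$weight)
  .joint_weight(model, unlist(params), s, prev, bandwidths, priors, models,
                switch_prob, model_prior, marg)
}

#' Joint model and parameter inference by ABC-SMC
#'
#' Treats the model identity as a discrete particle coordinate alongside the
#' parameters: each proposal resamples a model by its current marginal
#' probability, perturbs it with [perturb_model()], resamples and perturbs a
#' parameter particle *of the perturbed model* (parameters of different
#' models are not commensurable, so they are never carried across a switch;
#' a model with no surviving particles restarts from its prior), and is
#' accepted and weighted as in [run_abc_smc()].  The final population's
#' summed weights per model estimate the marginal model posterior.
#'
#' @param data Observed network ([pin_graph]).
#' @param models Character vector of at least two model codes, or a named
#'   list of [prior_spec()]s keyed by model code.
#' @param config An [abc_config()].
#' @param sampling Optional [sampling_config()].
#' @param switch_prob Model-switch probability of the model kernel
#'   (default 0.2).
#' @param model_prior Named prior model probabilities (uniform by default).
#' @param seed Optional integer seed.
#' @return An `abc_smc_model_fit` (inherits `abc_smc_fit`) whose
#'   `model_posterior` element is the final marginal model posterior; the
#'   full particle trace carries the model of every particle.
#' @examples
#' set.seed(5)
#' obs <- grow_lpa(60, m = 2)
#' fit <- run_abc_smc_model_selection(
#'   obs, c("LPA", "DA"),
#'   config = abc_config(n_particles = 40, n_populations = 2), seed = 9)
#' fit$model_posterior
#' @export
run_abc_smc_model_selection <- function(data, models, config = abc_config(),
                                        sampling = NULL, switch_prob = 0.2,
                                        model_prior = NULL, seed = NULL) {
  if (is.list(models) && !is.null(names(models))) {
    priors <- models
    models <- names(models)
  } else {
    models <- vapply(models, .check_model, character(1))
    priors <- lapply(setNames(models, models), default_prior)
  }
  if (length(models) < 2L) {
    stop("model selection needs at least two candidate models; use ",
         "`run_abc_smc()` for a single model", call. = FALSE)
  }
  if (switch_prob < 0 || switch_prob > 1) {
    stop("`switch_prob` must be a probability", call. = FALSE)
  }
  fit <- .abc_engine(data, models = models, priors = priors, config = config,
                     sampling = sampling, switch_prob = switch_prob,
                     seed = seed, model_prior = model_prior)
  fit$model_posterior <- marginal_model_posterior(
    fit$trace[fit$trace$generation == config$n_populations, ], models)
  class(fit) <- c("abc_smc_model_fit", "abc_smc_fit")
  fit
}
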
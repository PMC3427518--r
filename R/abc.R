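#' Configuration of the ABC-SMC sampler
#'
#' @param n_particles Particles per population (`N >= 2`).
#' @param n_populations Number of tolerance levels (`T >= 1`).
#' @param n_repeats Repeated simulations per proposal (`R >= 1`); the count
#'   of repeats landing within tolerance approximates the likelihood.
#' @param epsilon Optional explicit, strictly decreasing tolerance schedule
#'   of length `n_populations`.  The default `NULL` uses the adaptive rule:
#'   the first population accepts everything (`epsilon[1] = Inf`) and each
#'   later tolerance is the `quantile` of the previous population's realized
#'   distances (see [adaptive_epsilon()]).
#' @param quantile Quantile for the adaptive schedule (default median).
#' @param min_acceptance Abort threshold: a generation that accepts fewer
#'   than this fraction of its proposals stops with a diagnostic rather than
#'   looping forever.
#' @param max_perturb_retry Redraws of an out-of-prior perturbation before a
#'   new source particle is resampled.
#' @return A list with class `abc_config`.
#' @export
abc_config <- function(n_particles = 1000L, n_populations = 8L, n_repeats = 1L,
                       epsilon = NULL, quantile = 0.5,
                       min_acceptance = 1e-3, max_perturb_retry = 50L) {
  n_particles <- as.integer(n_particles)
  n_populations <- as.integer(n_populations)
  n_repeats <- as.integer(n_repeats)
  if (n_particles < 2L) stop("`n_particles` must be at least 2", call. = FALSE)
  if (n_populations < 1L) stop("`n_populations` must be at least 1", call. = FALSE)
  if (n_repeats < 1L) stop("`n_repeats` must be at least 1", call. = FALSE)
  if (!is.null(epsilon)) {
    epsilon <- as.numeric(epsilon)
    if (length(epsilon) != n_populations) {
      stop("explicit `epsilon` schedule must have length `n_populations`",
           call. = FALSE)
    }
    if (any(diff(epsilon) >= 0)) {
      stop("explicit `epsilon` schedule must be strictly decreasing",
           call. = FALSE)
    }
    if (any(epsilon[-1L] < 0)) stop("tolerances must be nonnegative", call. = FALSE)
  }
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(n_particles = n_particles, n_populations = n_populations,
                 n_repeats = n_repeats, epsilon = epsilon, quantile = quantile,
                 min_acceptance = min_acceptance,
                 max_perturb_retry = as.integer(max_perturb_retry)),
            class = "abc_config")
}

#' Repeated-simulation likelihood approximation
#'
#' Simulates the model `n_repeats` times at the proposed parameters (through
#' [simulate_with_sampling()] when a [sampling_config()] is given) and counts
#' how many simulations fall within spectral distance `epsilon` of the data.
#' That count, `s`, is the ABC stand-in for the likelihood: a proposal with
#' `s = 0` is rejected outright, and `s` enters the particle weight.
#'
#' @param model,params Model code and named parameter vector.
#' @param data Observed network ([pin_graph]) or its precomputed descending
#'   spectrum (avoids re-decomposing the data when scoring many proposals).
#' @param epsilon Distance tolerance.
#' @param n_repeats Number of simulations `R`.
#' @param sampling Optional [sampling_config()]; its `n_sampled` must match
#'   the data's node count.
#' @return Integer `s` in `0..n_repeats`, with the realized distances
#'   attached as attribute `"distances"`.
#' @export
approximate_likelihood <- function(model, params, data, epsilon,
                                   n_repeats = 1L, sampling = NULL) {
  data_spec <- if (inherits(data, "pin_graph")) graph_spectrum(data) else as.numeric(data)
  n_data <- length(data_spec)
  if (!is.null(sampling) && sampling$n_sampled != n_data) {
    stop("sampling config n_sampled (", sampling$n_sampled,
         ") does not match the data size (", n_data, ")", call. = FALSE)
  }
  dists <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    g <- tryCatch(
      if (is.null(sampling)) simulate_network(model, params, n_data)
      else simulate_with_sampling(model, params, sampling),
      error = function(e) {
        stop("simulation failed for model ", model, " at parameters (",
             paste(names(params), unlist(params), sep = "=", collapse = ", "),
             "): ", conditionMessage(e), call. = FALSE)
      }
    )
    dists[r] <- spectral_distance(graph_spectrum(g), data_spec)
  }
  s <- sum(dists <= epsilon)
  attr(s, "distances") <- dists
  s
}

#' Gaussian perturbation of a parameter particle
#'
#' Displaces each parameter named in `bandwidth` by independent zero-mean
#' Gaussian noise with the given per-parameter standard deviation (a
#' diagonal-covariance kernel).  The ABC sampler redraws perturbations that
#' leave the prior box; this function itself does not constrain the output.
#'
#' @param params Named numeric parameter vector.
#' @param bandwidth Named positive standard deviations (a subset of
#'   `names(params)`).
#' @return The perturbed parameter vector.
#' @export
perturb_parameters <- function(params, bandwidth) {
  if (any(bandwidth < 0)) stop("bandwidths must be nonnegative", call. = FALSE)
  nm <- names(bandwidth)
  params[nm] <- params[nm] + rnorm(length(nm), 0, bandwidth)
  params
}

#' Importance weight of an accepted particle
#'
#' In the first population the (unnormalized) weight is simply the
#' acceptance count `s`.  Later populations use the sequential importance
#' weight: prior density times `s`, divided by the mixture density of the
#' proposal under the previous population's weighted particles and the
#' Gaussian kernel.
#'
#' @param params Accepted parameter proposal (named vector).
#' @param s Acceptance count from [approximate_likelihood()] (`> 0`).
#' @param prev_population Previous population as a data frame with one
#'   column per active parameter and a normalized `weight` column, or `NULL`
#'   for the first population.
#' @param bandwidth Named kernel standard deviations used for this
#'   generation.
#' @param prior The [prior_spec()] (uniform box).
#' @return Unnormalized nonnegative weight.
#' @export
compute_weight <- function(params, s, prev_population = NULL,
                           bandwidth = NULL, prior = NULL) {
  if (s <= 0) stop("zero-acceptance particles are rejected, not weighted", call. = FALSE)
  if (is.null(prev_population)) return(as.numeric(s))
  if (nrow(prev_population) == 0L) {
    stop("previous population is empty", call. = FALSE)
  }
  nm <- names(bandwidth)
  pmat <- as.matrix(prev_population[, nm, drop = FALSE])
  mix <- .kernel_mixture(unlist(params)[nm], pmat, prev_population$weight, bandwidth)
  pd <- if (is.null(prior)) 1 else .prior_density(prior, unlist(params))
  pd * s / mix
}

# sum_j w_j prod_k dnorm(th[k] - pmat[j,k], 0, bw[k])
.kernel_mixture <- function(th, pmat, w, bw) {
  dens <- rep(1, nrow(pmat))
  for (k in seq_along(bw)) {
    dens <- dens * dnorm(th[k] - pmat[, k], 0, bw[k])
  }
  sum(w * dens)
}

#' Adaptive tolerance from a previous population
#'
#' The next tolerance is a quantile (default the median) of the distances
#' realized by the previous population's accepted particles, so the schedule
#' tightens at a rate the data themselves set.
#'
#' @param prev Previous population: a data frame with a `distance` column,
#'   or a numeric vector of accepted distances.
#' @param quantile Quantile in `(0, 1)`.
#' @param epsilon_prev Optional previous tolerance; the result never exceeds
#'   it.
#' @return The new tolerance.
#' @export
adaptive_epsilon <- function(prev, quantile = 0.5, epsilon_prev = NULL) {
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must lie strictly between 0 and 1", call. = FALSE)
  }
  d <- if (is.data.frame(prev)) prev$distance else as.numeric(prev)
  if (length(d) == 0L || anyNA(d)) {
    stop("previous population carries no realized distances", call. = FALSE)
  }
  eps <- unname(quantile(d, probs = quantile))
  if (!is.null(epsilon_prev)) eps <- min(eps, epsilon_prev)
  eps
}

#' ABC-SMC posterior estimation for one growth model
#'
#' Runs the sequential ABC sampler: the first population is drawn from the
#' prior, each later population is built by resampling the previous one by
#' weight, perturbing with a Gaussian kernel, re-simulating, accepting
#' proposals whose simulations come within the current spectral-distance
#' tolerance, and importance-weighting the survivors.  The kernel bandwidth
#' for each parameter is `sqrt(2 * weighted variance)` of the previous
#' population, recomputed every generation.
#'
#' @param data Observed network ([pin_graph]).
#' @param model Model code (see [network_models()]).
#' @param prior A [prior_spec()]; defaults to [default_prior()] for the
#'   model.
#' @param config An [abc_config()].
#' @param sampling Optional [sampling_config()] with `n_sampled` equal to
#'   the data's node count; simulations then grow to `n_total` and are
#'   subsampled before comparison.
#' @param seed Optional integer seed for exact reproducibility.
#' @return An `abc_smc_fit` object: list with the particle `trace` (tibble
#'   with columns generation, particle, model, the five parameters, weight,
#'   accepted_count, distance), the realized `epsilons`, and the call
#'   configuration.  Use [tidy()], [glance()], [autoplot()] on it.
#' @examples
#' set.seed(1)
#' obs <- grow_da(60, delta = 0.3, alpha = 0.2)
#' fit <- run_abc_smc(obs, "DA",
#'                    config = abc_config(n_particles = 50, n_populations = 2),
#'                    seed = 2)
#' tidy(fit)
#' @export
run_abc_smc <- function(data, model, prior = default_prior(model),
                        config = abc_config(), sampling = NULL, seed = NULL) {
  model <- .check_model(model)
  fit <- .abc_engine(data, models = model,
                     priors = setNames(list(prior), model),
                     config = config, sampling = sampling,
                     switch_prob = 0, seed = seed)
  class(fit) <- "abc_smc_fit"
  fit
}

# ---------------------------------------------------------------------------
# shared engine: single-model inference is the singleton case of the joint
# model/parameter sampler, so both entry points share one code path (and one
# rng stream).
.abc_engine <- function(data, models, priors, config, sampling, switch_prob,
                        seed = NULL, model_prior = NULL) {
  stopifnot(inherits(data, "pin_graph"), inherits(config, "abc_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model_prior)) {
    model_prior <- setNames(rep(1 / length(models), length(models)), models)
  }
  for (mm in models) {
    bad <- setdiff(names(priors[[mm]]), active_parameters(mm))
    if (length(bad) > 0L || !setequal(names(priors[[mm]]), active_parameters(mm))) {
      stop("prior for model ", mm, " must cover exactly its active parameters (",
           paste(active_parameters(mm), collapse = ", "), ")", call. = FALSE)
    }
  }
  if (!is.null(sampling) && sampling$n_sampled != data$n) {
    stop("sampling config n_sampled (", sampling$n_sampled,
         ") must equal the data's node count (", data$n, ")", call. = FALSE)
  }
  data_spec <- graph_spectrum(data)
  N <- config$n_particles
  n_gen <- config$n_populations
  R <- config$n_repeats
  eps_out <- numeric(n_gen)
  singleton_logged <- FALSE
  prev <- NULL
  trace <- vector("list", n_gen)

  for (t in seq_len(n_gen)) {
    eps <- if (!is.null(config$epsilon)) {
      config$epsilon[t]
    } else if (t == 1L) {
      Inf
    } else {
      adaptive_epsilon(prev$distance, config$quantile, eps_out[t - 1L])
    }
    eps_out[t] <- eps

    if (t > 1L) {
      marg <- vapply(models, function(mm) sum(prev$weight[prev$model == mm]), 0)
      bw <- lapply(setNames(models, models), function(mm) {
        .model_bandwidth(prev, mm, priors[[mm]])
      })
    }

    part_model <- character(N)
    part_pmat <- matrix(NA_real_, N, length(.param_names),
                        dimnames = list(NULL, .param_names))
    part_w <- numeric(N)
    part_s <- integer(N)
    part_d <- numeric(N)
    acc <- 0L
    attempts <- 0L
    max_attempts <- ceiling(N / config$min_acceptance)

    while (acc < N) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("ABC-SMC aborted in population ", t, ": only ", acc, " of ", N,
             " particles accepted after ", attempts - 1L,
             " attempts at tolerance ", signif(eps, 6),
             " (acceptance rate below ", config$min_acceptance, ")",
             call. = FALSE)
      }
      if (t == 1L) {
        m2 <- if (length(models) == 1L) models else {
          sample(models, 1L, prob = model_prior[models])
        }
        th2 <- .prior_draw(priors[[m2]])
      } else {
        m1 <- if (length(models) == 1L) models else sample(models, 1L, prob = marg)
        m2 <- perturb_model(m1, models, switch_prob,
                            warn_singleton = !singleton_logged)
        if (length(models) == 1L && switch_prob > 0) singleton_logged <- TRUE
        sel <- which(prev$model == m2)
        if (length(sel) == 0L) {
          th2 <- .prior_draw(priors[[m2]])
        } else {
          wsel <- prev$weight[sel] / sum(prev$weight[sel])
          active <- names(priors[[m2]])
          th2 <- NULL
          for (resample in seq_len(1000L)) {
            j <- sel[sample.int(length(sel), 1L, prob = wsel)]
            th1 <- prev$pmat[j, active]
            for (r in seq_len(config$max_perturb_retry)) {
              cand <- perturb_parameters(th1, bw[[m2]])
              if (.in_prior(priors[[m2]], cand)) { th2 <- cand; break }
            }
            if (!is.null(th2)) break
          }
          if (is.null(th2)) {
            stop("could not draw an in-prior perturbation for model ", m2,
                 " in population ", t, call. = FALSE)
          }
        }
      }
      s <- approximate_likelihood(m2, th2, data_spec, eps,
                                  n_repeats = R, sampling = sampling)
      if (s > 0L) {
        acc <- acc + 1L
        part_model[acc] <- m2
        part_pmat[acc, names(th2)] <- th2
        part_s[acc] <- as.integer(s)
        part_d[acc] <- min(attr(s, "distances"))
        part_w[acc] <- if (t == 1L) {
          as.numeric(s)
        } else {
          .joint_weight(m2, th2, s, prev, bw, priors, models,
                        switch_prob, model_prior, marg)
        }
      }
    }

    part_w <- part_w / sum(part_w)
    prev <- list(model = part_model, pmat = part_pmat, weight = part_w,
                 distance = part_d)
    trace[[t]] <- tibble::tibble(
      generation = t, particle = seq_len(N), model = part_model,
      delta = part_pmat[, "delta"], alpha = part_pmat[, "alpha"],
      p = part_pmat[, "p"], m = part_pmat[, "m"], omega = part_pmat[, "omega"],
      weight = part_w, accepted_count = part_s, distance = part_d,
      epsilon = eps, attempts = attempts
    )
  }

  structure(list(
    trace = dplyr::bind_rows(trace),
    epsilons = eps_out,
    models = models,
    priors = priors,
    config = config,
    sampling = sampling,
    switch_prob = switch_prob,
    data_summary = list(n_nodes = data$n, n_edges = n_edges(data))
  ), class = "abc_smc_fit")
}

# kernel bandwidth for one model: sqrt(2 x weighted variance) per parameter
# from the previous population's particles of that model; prior-scale
# fallback when the model is (nearly) unrepresented, floored away from zero.
.model_bandwidth <- function(prev, model, prior) {
  active <- names(prior)
  sel <- which(prev$model == model)
  bw <- numeric(length(active))
  names(bw) <- active
  for (k in seq_along(active)) {
    range_k <- prior[[active[k]]][2L] - prior[[active[k]]][1L]
    if (length(sel) >= 2L) {
      x <- prev$pmat[sel, active[k]]
      w <- prev$weight[sel] / sum(prev$weight[sel])
      mu <- sum(w * x)
      v <- sum(w * (x - mu)^2)
      bw[k] <- sqrt(2 * v)
    } else {
      bw[k] <- sqrt(2) * range_k / sqrt(12)   # sqrt(2) x prior sd
    }
    bw[k] <- max(bw[k], 1e-6 * range_k)
  }
  bw
}

# joint importance weight (model + parameters); reduces to compute_weight()
# when a single model is configured.
.joint_weight <- function(m2, th2, s, prev, bw, priors, models,
                          switch_prob, model_prior, marg) {
  pd <- .prior_density(priors[[m2]], th2)
  if (length(models) == 1L) {
    km_mix <- 1
  } else {
    km <- vapply(models, function(m1) {
      if (m1 == m2) 1 - switch_prob else switch_prob / (length(models) - 1L)
    }, numeric(1))
    km_mix <- sum(marg * km)
  }
  sel <- which(prev$model == m2)
  qtheta <- if (length(sel) == 0L) {
    pd
  } else {
    wsel <- prev$weight[sel] / sum(prev$weight[sel])
    .kernel_mixture(th2[names(bw[[m2]])],
                    prev$pmat[sel, names(bw[[m2]]), drop = FALSE],
                    wsel, bw[[m2]])
  }
  model_prior[[m2]] * pd * s / (km_mix * qtheta)
}
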
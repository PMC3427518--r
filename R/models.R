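#' Network growth models and their parameters
#'
#' Six stochastic growth models are available, identified by short uppercase
#' codes:
#'
#' * `DA` — duplication–divergence with heterodimerisation: a uniformly
#'   chosen node is copied, each inherited edge survives divergence with
#'   probability `1 - delta` (the original's edges are never touched), and an
#'   original–copy edge is added with probability `alpha`.
#' * `DAC` — as `DA` but preserving complementarity: on divergence one of the
#'   original/copy edge pair is deleted uniformly at random, so at least one
#'   of the pair always survives.
#' * `LPA` — linear preferential attachment: each new node attaches
#'   `Poisson(m)` edges to existing nodes with probability proportional to
#'   degree (`k / 2M`).
#' * `GSF` — generalized scale-free growth: each of the `Poisson(m)` new
#'   edges picks an existing edge with probability proportional to its
#'   weight, attaches to a uniformly chosen endpoint of it, and increments
#'   the picked edge's weight by `omega`; the limiting degree exponent is
#'   `2 + 1 / (1 + 2 * omega)`.
#' * `DACR` — mixture: with probability `p` a `DAC` duplication step,
#'   otherwise a new node plus `Poisson(m)` edges between uniformly chosen
#'   node pairs.
#' * `DACL` — as `DACR`, but the edge-addition step attaches the new node's
#'   `Poisson(m)` edges preferentially by degree.
#'
#' `network_models()` lists the codes; `active_parameters()` gives the
#' parameters each model actually uses (`delta`, `alpha`, `p` are
#' probabilities, `m > 0` is a Poisson mean, `omega >= 0` a weight
#' increment).
#'
#' @param model One of the model codes.
#' @return `network_models()`: character vector of codes;
#'   `active_parameters()`: character vector of parameter names.
#' @examples
#' network_models()
#' active_parameters("DACR")
#' @export
network_models <- function() .model_ids

#' @rdname network_models
#' @export
active_parameters <- function(model) {
  model <- .check_model(model)
  switch(model,
    DA   = c("delta", "alpha"),
    DAC  = c("delta", "alpha"),
    LPA  = "m",
    GSF  = c("m", "omega"),
    DACR = c("delta", "alpha", "p", "m"),
    DACL = c("delta", "alpha", "p", "m")
  )
}

.check_model <- function(model) {
  model <- toupper(as.character(model))
  if (length(model) != 1L || !model %in% .model_ids) {
    stop("unknown model '", paste(model, collapse = ","),
         "'; available models: ", paste(.model_ids, collapse = ", "),
         call. = FALSE)
  }
  model
}

# validate a named parameter vector for a model; returns the active
# parameters in canonical order
.check_params <- function(model, params) {
  model <- .check_model(model)
  active <- active_parameters(model)
  params <- unlist(params)
  if (is.null(names(params)) || any(names(params) == "")) {
    stop("parameters must be a named vector, e.g. c(delta = 0.4, alpha = 0.25)",
         call. = FALSE)
  }
  missing <- setdiff(active, names(params))
  if (length(missing) > 0L) {
    stop("model ", model, " requires parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(params), active)
  if (length(extra) > 0L) {
    warning("parameter(s) ", paste(extra, collapse = ", "),
            " are not used by model ", model, call. = FALSE)
  }
  th <- params[active]
  for (nm in intersect(active, c("delta", "alpha", "p"))) {
    if (is.na(th[nm]) || th[nm] < 0 || th[nm] > 1) {
      stop("parameter ", nm, " must be a probability in [0, 1], got ",
           th[nm], call. = FALSE)
    }
  }
  if ("m" %in% active && (is.na(th["m"]) || th["m"] <= 0)) {
    stop("parameter m must be positive, got ", th["m"], call. = FALSE)
  }
  if ("omega" %in% active && (is.na(th["omega"]) || th["omega"] < 0)) {
    stop("parameter omega must be nonnegative, got ", th["omega"], call. = FALSE)
  }
  th
}

#' Uniform prior boxes for model parameters
#'
#' Priors are independent uniforms, one `(lower, upper)` interval per active
#' parameter.  `prior_spec()` builds one from named length-2 vectors;
#' `default_prior()` returns the package defaults: the full `[0, 1]` range
#' for the probabilities `delta`, `alpha`, `p`, `[0.1, 8]` for the Poisson
#' mean `m` and `[0, 5]` for `omega`.
#'
#' @param ... Named `c(lower, upper)` pairs, e.g.
#'   `prior_spec(delta = c(0, 1), alpha = c(0, 0.5))`.
#' @return A named list of range vectors with class `prior_spec`.
#' @examples
#' default_prior("DA")
#' prior_spec(m = c(0.5, 4))
#' @export
prior_spec <- function(...) {
  ranges <- list(...)
  if (length(ranges) == 0L) stop("empty prior", call. = FALSE)
  bad <- setdiff(names(ranges), .param_names)
  if (is.null(names(ranges)) || length(bad) > 0L) {
    stop("prior parameters must be named among: ",
         paste(.param_names, collapse = ", "), call. = FALSE)
  }
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2L || anyNA(r) || r[1L] >= r[2L]) {
      stop("prior range for ", nm, " must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
    dom <- switch(nm,
      delta = , alpha = , p = c(0, 1),
      m = c(0, Inf), omega = c(0, Inf)
    )
    if (r[1L] < dom[1L] || r[2L] > dom[2L]) {
      stop("prior range for ", nm, " lies outside its legal domain [",
           dom[1L], ", ", dom[2L], "]", call. = FALSE)
    }
    if (nm == "m" && r[1L] <= 0) {
      stop("prior lower bound for m must be > 0", call. = FALSE)
    }
    ranges[[nm]] <- r
  }
  # canonical ordering keeps rng draw order well-defined
  ranges <- ranges[intersect(.param_names, names(ranges))]
  structure(ranges, class = "prior_spec")
}

#' @rdname prior_spec
#' @param model A model code (see [network_models()]).
#' @export
default_prior <- function(model) {
  active <- active_parameters(model)
  full <- list(delta = c(0, 1), alpha = c(0, 1), p = c(0, 1),
               m = c(0.1, 8), omega = c(0, 5))
  do.call(prior_spec, full[active])
}

# one draw from a uniform prior box, named numeric in canonical order
.prior_draw <- function(prior) {
  vapply(prior, function(r) runif(1L, r[1L], r[2L]), numeric(1))
}

# constant density inside the box, 0 outside
.prior_density <- function(prior, params) {
  inside <- all(vapply(names(prior), function(nm) {
    params[nm] >= prior[[nm]][1L] && params[nm] <= prior[[nm]][2L]
  }, logical(1)))
  if (!inside) return(0)
  prod(vapply(prior, function(r) 1 / (r[2L] - r[1L]), numeric(1)))
}

.in_prior <- function(prior, params) .prior_density(prior, params) > 0
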
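#' Uniform node-sampling model for incomplete interactomes
#'
#' Interaction datasets cover only part of an organism's proteome.  The
#' sampling model assumes each protein is included uniformly at random:
#' simulated networks are grown to the organism's full protein count
#' `n_total` and then reduced to the data's size `n_sampled` by taking the
#' subgraph induced by a uniform node subset.  `sampling_config()` bundles
#' the two sizes.
#'
#' @param n_total Number of proteins in the organism (`N_T`).
#' @param n_sampled Number of proteins in the interaction data (`N_S`),
#'   `1 <= n_sampled <= n_total`.
#' @return A list with class `sampling_config`.
#' @examples
#' sampling_config(n_total = 6532, n_sampled = 5035)
#' @export
sampling_config <- function(n_total, n_sampled) {
  n_total <- as.integer(n_total)
  n_sampled <- as.integer(n_sampled)
  if (is.na(n_total) || n_total < 1L) {
    stop("`n_total` must be a positive integer", call. = FALSE)
  }
  if (is.na(n_sampled) || n_sampled < 1L || n_sampled > n_total) {
    stop("`n_sampled` must satisfy 1 <= n_sampled <= n_total (got ",
         n_sampled, " of ", n_total, ")", call. = FALSE)
  }
  structure(list(n_total = n_total, n_sampled = n_sampled),
            class = "sampling_config")
}

#' @export
print.sampling_config <- function(x, ...) {
  cat("<sampling_config> N_T = ", x$n_total, ", N_S = ", x$n_sampled,
      " (fraction ", sprintf("%.2f", x$n_sampled / x$n_total), ")\n", sep = "")
  invisible(x)
}

#' Induced subgraph on a uniform node sample
#'
#' Chooses `n_sampled` distinct nodes uniformly without replacement and
#' returns the induced subgraph: an edge survives iff both endpoints were
#' chosen.  Nodes isolated by the sampling are retained — real interactome
#' data contain no degree-zero proteins, so downstream inference of degree
#' distributions corrects for them (see
#' [posterior_predictive_degree_distribution()]), but the graph itself keeps
#' them.
#'
#' @param g A [pin_graph].
#' @param n_sampled Number of nodes to keep (`<= n_nodes(g)`).
#' @return A [pin_graph] with `n_sampled` nodes.
#' @export
induced_subsample <- function(g, n_sampled) {
  stopifnot(inherits(g, "pin_graph"))
  n_sampled <- as.integer(n_sampled)
  if (n_sampled < 1L || n_sampled > g$n) {
    stop("cannot sample ", n_sampled, " nodes from a graph of ", g$n, " nodes",
         call. = FALSE)
  }
  keep <- sort(sample.int(g$n, n_sampled))
  relabel <- integer(g$n)
  relabel[keep] <- seq_len(n_sampled)
  e <- g$edges
  sel <- e[, 1L] %in% keep & e[, 2L] %in% keep
  e <- e[sel, , drop = FALSE]
  e[] <- relabel[e]
  pin_graph(n_sampled, e)
}

#' Simulate a growth model through the sampling scheme
#'
#' Grows a network to the organism size `n_total` and reduces it to the data
#' size `n_sampled` with [induced_subsample()].  This is the simulation path
#' used inside the ABC sampler whenever a [sampling_config()] is supplied:
#' parameters are thereby inferred for the full network while comparison
#' happens at the size of the observed data.
#'
#' @inheritParams simulate_network
#' @param sampling A [sampling_config()].
#' @return A [pin_graph] with exactly `sampling$n_sampled` nodes.
#' @export
simulate_with_sampling <- function(model, params, sampling, seed = seed_graph()) {
  stopifnot(inherits(sampling, "sampling_config"))
  g <- simulate_network(model, params, sampling$n_total, seed = seed)
  if (sampling$n_sampled == sampling$n_total) return(g)
  induced_subsample(g, sampling$n_sampled)
}

#' Sampling fraction of an interaction dataset
#'
#' Proteins present in the interaction data divided by the organism's total
#' gene/protein count; e.g. 5035 proteins of a 6532-gene genome give 0.77.
#'
#' @param n_sampled Proteins in the data.
#' @param n_total Genome size (must be positive).
#' @return Fraction in `(0, 1]`.
#' @examples
#' sampling_fraction(5035, 6532)
#' @export
sampling_fraction <- function(n_sampled, n_total) {
  if (n_total <= 0) stop("`n_total` must be positive", call. = FALSE)
  if (n_sampled <= 0 || n_sampled > n_total) {
    stop("`n_sampled` must lie in 1..n_total", call. = FALSE)
  }
  n_sampled / n_total
}
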
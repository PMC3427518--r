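#' Seed network for the growth simulators
#'
#' Every simulator grows from a small connected seed.  The default — two
#' nodes joined by one edge — is the smallest graph on which every growth
#' move is defined; a ring or complete seed of a few nodes can be requested
#' instead.  Growth properties at the scales the package targets are
#' insensitive to this choice.
#'
#' @param size Number of seed nodes (at least 2).
#' @param topology `"pair"` (a path; with `size = 2` the default single
#'   edge), `"ring"`, or `"complete"`.
#' @return A [pin_graph].
#' @examples
#' seed_graph()            # 2 nodes, 1 edge
#' seed_graph(5, "ring")   # 5 nodes, 5 edges
#' @export
seed_graph <- function(size = 2L, topology = c("pair", "ring", "complete")) {
  size <- as.integer(size)
  topology <- match.arg(topology)
  if (size < 2L) stop("seed graphs need at least 2 nodes", call. = FALSE)
  edges <- switch(topology,
    pair = cbind(seq_len(size - 1L), seq_len(size - 1L) + 1L),
    ring = cbind(seq_len(size), c(seq_len(size - 1L) + 1L, 1L)),
    complete = t(utils::combn(size, 2L))
  )
  if (topology == "ring" && size == 2L) edges <- matrix(c(1L, 2L), ncol = 2L)
  pin_graph(size, edges)
}

# seed sanity shared by the growers
.check_seed <- function(seed, n_target) {
  if (!inherits(seed, "pin_graph")) stop("seed must be a pin_graph", call. = FALSE)
  if (seed$n > n_target) {
    stop("seed graph (", seed$n, " nodes) is larger than the growth target (",
         n_target, " nodes)", call. = FALSE)
  }
  invisible(seed)
}

# --- the six growth models --------------------------------------------------

#' Grow a network under a duplication–divergence model
#'
#' `grow_da()` and `grow_dac()` implement the two duplication models
#' described in [network_models()]: at each step a uniformly chosen node is
#' duplicated, inherited interactions diverge with probability `delta`, and a
#' heterodimer (original–copy) interaction forms with probability `alpha`.
#' `grow_dac()` preserves complementarity: a diverged interaction is lost
#' from the original *or* the copy (uniformly), never both, so the total
#' number of interactions never decreases.
#'
#' All simulators draw from the session random number generator in a fixed
#' documented order, so `set.seed()` makes runs exactly reproducible.
#'
#' @param n Target node count (`>=` seed size).
#' @param delta Divergence probability in `[0, 1]`.
#' @param alpha Heterodimerisation probability in `[0, 1]`.
#' @param seed Seed network ([seed_graph()] by default).
#' @return A [pin_graph] with exactly `n` nodes.
#' @examples
#' set.seed(1)
#' g <- grow_da(50, delta = 0.4, alpha = 0.25)
#' n_edges(g)
#' @export
grow_da <- function(n, delta, alpha, seed = seed_graph()) {
  th <- .check_params("DA", c(delta = delta, alpha = alpha))
  .check_seed(seed, n)
  e <- cpp_grow_dup(as.integer(n), th[["delta"]], th[["alpha"]], 1, 0,
                    1L, FALSE, seed$edges, seed$n)
  pin_graph(n, e)
}

#' @rdname grow_da
#' @export
grow_dac <- function(n, delta, alpha, seed = seed_graph()) {
  th <- .check_params("DAC", c(delta = delta, alpha = alpha))
  .check_seed(seed, n)
  e <- cpp_grow_dup(as.integer(n), th[["delta"]], th[["alpha"]], 1, 0,
                    1L, TRUE, seed$edges, seed$n)
  pin_graph(n, e)
}

#' Grow a network by linear preferential attachment
#'
#' Each step adds one node and `Poisson(m)` edges from it to existing nodes
#' chosen with probability proportional to their degree (`k / 2M`).  The
#' Poisson draw is capped at the number of existing nodes and duplicate
#' target proposals within a step are discarded, keeping the graph simple.
#' The limiting degree distribution is a power law with exponent 3.
#'
#' @inheritParams grow_da
#' @param m Mean number of edges added per step (`> 0`).
#' @return A [pin_graph] with exactly `n` nodes.
#' @export
grow_lpa <- function(n, m, seed = seed_graph()) {
  th <- .check_params("LPA", c(m = m))
  m <- th[["m"]]
  if (seed$n > n) {
    stop("seed graph (", seed$n, " nodes) is larger than the growth target (",
         n, " nodes)", call. = FALSE)
  }
  # degree-multiset "bag": node i appears deg(i) times; sampling a uniform
  # bag element is a draw proportional to degree.  LPA never deletes edges,
  # so the bag only ever grows.
  cap <- max(16L, as.integer(2 * (n * m + 10 * sqrt(n * m) + 64)))
  bag <- integer(cap)
  blen <- 0L
  emax <- cap %/% 2L
  e1 <- integer(emax); e2 <- integer(emax); ne <- 0L
  deg <- integer(n)
  add_edge <- function(a, b) {
    ne <<- ne + 1L
    if (ne > emax) {
      e1 <<- c(e1, integer(emax)); e2 <<- c(e2, integer(emax)); emax <<- 2L * emax
    }
    e1[ne] <<- a; e2[ne] <<- b
    if (blen + 2L > cap) { bag <<- c(bag, integer(cap)); cap <<- 2L * cap }
    bag[blen + 1L] <<- a; bag[blen + 2L] <<- b; blen <<- blen + 2L
    deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
  }
  for (r in seq_len(nrow(seed$edges))) add_edge(seed$edges[r, 1L], seed$edges[r, 2L])
  v <- seed$n
  while (v < n) {
    v <- v + 1L
    k <- min(rpois(1L, m), v - 1L)
    if (k > 0L) {
      chosen <- integer(0)
      for (j in seq_len(k)) {
        tgt <- if (blen == 0L) sample.int(v - 1L, 1L) else bag[sample.int(blen, 1L)]
        if (tgt %in% chosen) next
        chosen <- c(chosen, tgt)
      }
      for (tgt in chosen) add_edge(tgt, v)
    }
  }
  ed <- if (ne > 0L) cbind(e1[seq_len(ne)], e2[seq_len(ne)]) else NULL
  pin_graph(n, ed)
}

#' Grow a network under the generalized scale-free model
#'
#' Edge-weighted preferential attachment: each of the `Poisson(m)` new edges
#' selects an existing edge with probability proportional to its weight
#' (new edges start at weight 1), attaches the new node to a uniformly
#' chosen endpoint of the selected edge, and then increments the selected
#' edge's weight by `omega`.  The limiting degree exponent is
#' `2 + 1 / (1 + 2 * omega)`.  Weights update between attachments, so one
#' step may select the same edge repeatedly; duplicate attachment proposals
#' are discarded without retry (no new edge, no weight increment).
#'
#' @inheritParams grow_lpa
#' @param omega Weight increment per selection (`>= 0`).
#' @return A [pin_graph] with exactly `n` nodes.
#' @export
grow_gsf <- function(n, m, omega, seed = seed_graph()) {
  th <- .check_params("GSF", c(m = m, omega = omega))
  m <- th[["m"]]; omega <- th[["omega"]]
  if (seed$n > n) {
    stop("seed graph (", seed$n, " nodes) is larger than the growth target (",
         n, " nodes)", call. = FALSE)
  }
  if (nrow(seed$edges) == 0L) {
    stop("the generalized scale-free model needs a seed with at least one edge",
         call. = FALSE)
  }
  e1 <- seed$edges[, 1L]; e2 <- seed$edges[, 2L]
  w <- rep(1, length(e1))
  v <- seed$n
  while (v < n) {
    v <- v + 1L
    k <- rpois(1L, m)
    if (k > 0L) {
      for (j in seq_len(k)) {
        idx <- sample.int(length(w), 1L, prob = w)
        endpoint <- if (runif(1L) < 0.5) e1[idx] else e2[idx]
        # an edge created earlier in this step touches v, so the chosen
        # endpoint can be v itself: a self-pair, discarded like a collision
        dup <- endpoint == v ||
          any(e1 == v & e2 == endpoint) || any(e1 == endpoint & e2 == v)
        if (!dup) {
          e1 <- c(e1, endpoint); e2 <- c(e2, v); w <- c(w, 1)
          w[idx] <- w[idx] + omega
        }
      }
    }
  }
  g <- pin_graph(n, cbind(e1, e2))
  # final selection weights, in the row order of g$edges (canonicalised by
  # pin_graph but row order preserved); exposed for diagnostics and tests
  attr(g, "edge_weights") <- w
  g
}

#' Grow a network under a mixed duplication / edge-addition model
#'
#' With probability `p` a step is a complementarity-preserving duplication
#' (as in [grow_dac()]); otherwise a new node is added together with
#' `Poisson(m)` edges.  `grow_dacr()` places those edges between node pairs
#' chosen uniformly at random from the whole network; `grow_dacl()` attaches
#' them from the new node to existing nodes preferentially by degree (with a
#' uniform fallback when the graph has no edges).  Self-pairs and proposals
#' duplicating an existing edge are discarded without retry.  Every step adds
#' exactly one node, so growth reaches `n` exactly.
#'
#' @inheritParams grow_da
#' @param p Probability of a duplication step, in `[0, 1]`.
#' @param m Mean number of edges per edge-addition step (`> 0`).
#' @return A [pin_graph] with exactly `n` nodes.
#' @examples
#' set.seed(7)
#' g <- grow_dacr(200, delta = 0.4, alpha = 0.25, p = 0.7, m = 3)
#' @export
grow_dacr <- function(n, delta, alpha, p, m, seed = seed_graph()) {
  th <- .check_params("DACR", c(delta = delta, alpha = alpha, p = p, m = m))
  .check_seed(seed, n)
  e <- cpp_grow_dup(as.integer(n), th[["delta"]], th[["alpha"]], th[["p"]],
                    th[["m"]], 1L, TRUE, seed$edges, seed$n)
  pin_graph(n, e)
}

#' @rdname grow_dacr
#' @export
grow_dacl <- function(n, delta, alpha, p, m, seed = seed_graph()) {
  th <- .check_params("DACL", c(delta = delta, alpha = alpha, p = p, m = m))
  .check_seed(seed, n)
  e <- cpp_grow_dup(as.integer(n), th[["delta"]], th[["alpha"]], th[["p"]],
                    th[["m"]], 2L, TRUE, seed$edges, seed$n)
  pin_graph(n, e)
}

#' Simulate a network from any growth model
#'
#' Dispatches a named parameter vector to the matching `grow_*()` simulator.
#' Identical random seeds give identical graphs.
#'
#' @param model A model code (see [network_models()]).
#' @param params Named numeric vector holding the model's active parameters
#'   (extra entries trigger a warning, missing ones an error).
#' @param n Target node count.
#' @param seed Seed network ([seed_graph()] by default).
#' @return A [pin_graph] with exactly `n` nodes.
#' @examples
#' set.seed(42)
#' simulate_network("LPA", c(m = 2), n = 100)
#' @export
simulate_network <- function(model, params, n, seed = seed_graph()) {
  model <- .check_model(model)
  th <- .check_params(model, params)
  switch(model,
    DA   = grow_da(n, th[["delta"]], th[["alpha"]], seed = seed),
    DAC  = grow_dac(n, th[["delta"]], th[["alpha"]], seed = seed),
    LPA  = grow_lpa(n, th[["m"]], seed = seed),
    GSF  = grow_gsf(n, th[["m"]], th[["omega"]], seed = seed),
    DACR = grow_dacr(n, th[["delta"]], th[["alpha"]], th[["p"]], th[["m"]], seed = seed),
    DACL = grow_dacl(n, th[["delta"]], th[["alpha"]], th[["p"]], th[["m"]], seed = seed)
  )
}

#' Tail exponent of a degree distribution by discrete maximum likelihood
#'
#' Estimates the power-law exponent `a` of `P(k) ~ k^-a` from all node
#' degrees `k >= k_min`, using the standard discrete maximum-likelihood
#' estimator `1 + n / sum(log(k / (k_min - 0.5)))`.
#'
#' @param g A [pin_graph], or an integer vector of degrees.
#' @param k_min Smallest degree included in the tail (default 10).
#' @return The estimated exponent (numeric scalar).
#' @examples
#' set.seed(3)
#' degree_tail_exponent(grow_lpa(5000, m = 2))
#' @export
degree_tail_exponent <- function(g, k_min = 10) {
  d <- if (inherits(g, "pin_graph")) degrees(g) else as.integer(g)
  k <- d[d >= k_min]
  if (length(k) < 2L) {
    stop("fewer than 2 degrees above k_min = ", k_min,
         "; the tail is too short to fit", call. = FALSE)
  }
  1 + length(k) / sum(log(k / (k_min - 0.5)))
}
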
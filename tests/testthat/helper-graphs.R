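# small graph builders used across the suite

k_complete <- function(n) pin_graph(n, t(utils::combn(n, 2L)))

path_graph <- function(n) pin_graph(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))

# Bernoulli random graph fixture (test input generator, not a growth model)
random_graph <- function(n, p = 0.4) {
  pairs <- t(utils::combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  pin_graph(n, pairs[keep, , drop = FALSE])
}

random_permutation <- function(n) sample.int(n, n)

# degree distribution restricted to k >= 1 and renormalized
observed_degree_distribution <- function(g) {
  dd <- degree_distribution(g)
  dd <- dd[dd$degree >= 1L, ]
  dd$probability <- dd$probability / sum(dd$probability)
  dd
}
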
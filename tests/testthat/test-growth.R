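test_that("seed graphs have the advertised shapes", {
  g <- seed_graph()
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_edges(g), 1L)
  r <- seed_graph(5, "ring")
  expect_equal(n_nodes(r), 5L)
  expect_equal(n_edges(r), 5L)
  expect_error(grow_da(5, 0.1, 0.1, seed = seed_graph(10)), "larger than")
  expect_error(seed_graph(1), "at least 2")
})

test_that("duplication models reach their closed-form limits", {
  set.seed(1)
  expect_equal(n_edges(grow_da(5, delta = 0, alpha = 1)), 10L)    # K5
  expect_equal(n_edges(grow_dac(5, delta = 0, alpha = 1)), 10L)   # K5
  g <- grow_da(100, delta = 1, alpha = 0)
  expect_equal(n_edges(g), 1L)
  expect_equal(sum(degrees(g) == 0L), 98L)
  # DAC reassigns rather than deletes: with delta = 1, alpha = 0 the edge
  # count stays at the seed's forever while degrees shuffle
  h <- grow_dac(50, delta = 1, alpha = 0)
  expect_equal(n_edges(h), 1L)
})

test_that("growth always hits the target size and edge counts never shrink", {
  set.seed(2)
  cases <- list(
    function() grow_da(73, 0.4, 0.25),
    function() grow_dac(73, 0.4, 0.25),
    function() grow_lpa(73, 2),
    function() grow_gsf(73, 2, 0.5),
    function() grow_dacr(73, 0.4, 0.25, 0.7, 3),
    function() grow_dacl(73, 0.4, 0.25, 0.7, 3)
  )
  for (f in cases) {
    g <- f()                      # pin_graph() would error on loops/dups
    expect_equal(n_nodes(g), 73L)
    expect_gte(n_edges(g), 1L)
  }
})

test_that("LPA attaches to equal-degree nodes with equal probability", {
  set.seed(3)
  hits <- integer(2)
  reps <- 3000
  for (i in seq_len(reps)) {
    g <- grow_lpa(3, m = 1)
    e <- g$edges
    new_edges <- e[e[, 2L] == 3L, 1L]
    for (tgt in new_edges) hits[tgt] <- hits[tgt] + 1L
  }
  n <- sum(hits)
  se <- sqrt(n * 0.25)
  expect_lt(abs(hits[1] - n / 2), 3 * se)
})

test_that("an LPA step with a zero Poisson draw leaves the node isolated", {
  set.seed(4)
  g <- grow_lpa(200, m = 0.01)
  expect_gt(sum(degrees(g) == 0L), 0L)
})

test_that("GSF picks edge endpoints uniformly and keeps its weight ledger", {
  set.seed(5)
  hits <- integer(2)
  for (i in 1:2000) {
    g <- grow_gsf(3, m = 5, omega = 0)
    e <- g$edges
    first <- e[e[, 2L] == 3L, 1L]
    if (length(first) > 0L) hits[first[1L]] <- hits[first[1L]] + 1L
  }
  n <- sum(hits)
  expect_lt(abs(hits[1] - n / 2), 3 * sqrt(n * 0.25))
  # total weight = edges (weight 1 at creation) + omega x attachments
  g <- grow_gsf(100, m = 2, omega = 0.5)
  w <- attr(g, "edge_weights")
  attachments <- n_edges(g) - 1L   # every non-seed edge is one attachment
  expect_equal(sum(w), n_edges(g) + 0.5 * attachments)
  expect_error(grow_gsf(10, 2, 0.5, seed = pin_graph(2)), "at least one edge")
})

test_that("degenerate mixtures replay the pure duplication model exactly", {
  set.seed(6)
  a <- grow_dac(60, 0.4, 0.25)
  set.seed(6)
  b <- grow_dacr(60, 0.4, 0.25, p = 1, m = 3)
  set.seed(6)
  c <- grow_dacl(60, 0.4, 0.25, p = 1, m = 3)
  expect_identical(a$edges, b$edges)
  expect_identical(a$edges, c$edges)
})

test_that("pure random edge addition yields the expected edge count", {
  set.seed(7)
  reps <- 200
  n <- 500
  m <- 2
  counts <- replicate(reps, n_edges(grow_dacr(n, 0.5, 0.5, p = 0, m = m)))
  expected <- 1 + (n - 2) * m
  # discarded collision/self-pair proposals only ever remove edges, so the
  # mean sits at or slightly below the Poisson-sum expectation
  se <- sqrt(var(counts) / reps)
  expect_lt(mean(counts), expected + 3 * se)
  expect_gt(mean(counts), 0.95 * expected)
})

test_that("mixed-model growth with p = 0 matches LPA in distribution", {
  set.seed(8)
  reps <- 60
  a <- replicate(reps, n_edges(grow_dacl(120, 0.5, 0.5, p = 0, m = 2)))
  b <- replicate(reps, n_edges(grow_lpa(120, m = 2)))
  se <- sqrt(var(a) / reps + var(b) / reps)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("simulate_network dispatches, validates, and is reproducible", {
  set.seed(9)
  g <- simulate_network("DA", c(delta = 0, alpha = 1), n = 5)
  expect_equal(n_edges(g), 10L)
  expect_error(simulate_network("LPA", c(delta = 0.2), n = 10), "requires parameter")
  expect_error(simulate_network("XXX", c(m = 2), n = 10), "unknown model")
  expect_warning(simulate_network("LPA", c(m = 2, delta = 0.3), n = 10), "not used")
  expect_error(simulate_network("LPA", c(m = -1), n = 10), "positive")
  set.seed(10)
  g1 <- simulate_network("DACR", c(delta = 0.4, alpha = 0.25, p = 0.7, m = 3), 80)
  set.seed(10)
  g2 <- simulate_network("DACR", c(delta = 0.4, alpha = 0.25, p = 0.7, m = 3), 80)
  expect_identical(g1$edges, g2$edges)
})
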
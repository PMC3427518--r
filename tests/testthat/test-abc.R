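test_that("the repeated-simulation likelihood counts within-tolerance runs", {
  set.seed(1)
  data <- grow_da(30, 0.3, 0.2)
  s <- approximate_likelihood("DA", c(delta = 0.3, alpha = 0.2), data,
                              epsilon = Inf, n_repeats = 5)
  expect_equal(as.integer(s), 5L)
  s0 <- approximate_likelihood("DA", c(delta = 0.3, alpha = 0.2), data,
                               epsilon = 0, n_repeats = 5)
  expect_equal(as.integer(s0), 0L)
  expect_length(attr(s, "distances"), 5)
})

test_that("a deterministic degenerate model matches its own data exactly", {
  # delta = 1, alpha = 0 always produces one edge plus isolates, so every
  # simulation has the data's spectrum and s = R even at epsilon = 0
  set.seed(2)
  data <- grow_da(40, delta = 1, alpha = 0)
  s <- approximate_likelihood("DA", c(delta = 1, alpha = 0), data,
                              epsilon = 0, n_repeats = 4)
  expect_equal(as.integer(s), 4L)
})

test_that("the Gaussian kernel has the stated moments and a zero limit", {
  th <- c(delta = 0.5, alpha = 0.3)
  expect_equal(perturb_parameters(th, c(delta = 0, alpha = 0)), th)
  set.seed(3)
  draws <- t(replicate(20000, perturb_parameters(th, c(delta = 0.1, alpha = 0.2))))
  for (k in 1:2) {
    bw <- c(0.1, 0.2)[k]
    expect_lt(abs(mean(draws[, k]) - th[k]), 3 * bw / sqrt(20000))
    expect_lt(abs(var(draws[, k]) - bw^2), 3 * bw^2 * sqrt(2 / 19999))
  }
})

test_that("importance weights follow the sequential form", {
  expect_equal(compute_weight(c(delta = 0.5), s = 3), 3)
  expect_error(compute_weight(c(delta = 0.5), s = 0), "rejected")
  prior <- prior_spec(delta = c(0, 1))
  prev <- tibble::tibble(delta = 0.5, weight = 1)
  bw <- c(delta = 0.1)
  w <- compute_weight(c(delta = 0.5), s = 2, prev, bw, prior)
  expect_equal(w, 2 / dnorm(0, 0, 0.1))
  expect_gt(w, 0)
  # equal inputs, equal weights
  prev2 <- tibble::tibble(delta = c(0.4, 0.6), weight = c(0.5, 0.5))
  w1 <- compute_weight(c(delta = 0.45), 2, prev2, bw, prior)
  w2 <- compute_weight(c(delta = 0.55), 2, prev2, bw, prior)
  expect_equal(w1, w2)
  expect_error(compute_weight(c(delta = 0.5), 1, prev2[0, ], bw, prior), "empty")
})

test_that("the adaptive tolerance is a quantile of accepted distances", {
  expect_equal(adaptive_epsilon(rep(2.5, 10)), 2.5)
  expect_equal(adaptive_epsilon(c(1, 2, 3, 4), quantile = 0.5), 2.5)
  expect_error(adaptive_epsilon(c(1, 2), quantile = 1.5), "between 0 and 1")
  set.seed(4)
  for (i in 1:100) {
    d <- runif(20, 0, 5)
    eps_prev <- max(d) + runif(1)
    expect_lte(adaptive_epsilon(d, runif(1, 0.05, 0.95), eps_prev), eps_prev)
  }
})

test_that("abc_config validates schedules and counts", {
  expect_error(abc_config(n_particles = 1), "at least 2")
  expect_error(abc_config(epsilon = c(3, 3), n_populations = 2), "decreasing")
  expect_error(abc_config(epsilon = c(3, 2), n_populations = 3), "length")
  expect_silent(abc_config(epsilon = c(3, 2, 1), n_populations = 3))
})

test_that("a single prior-tolerance population is a weighted prior sample", {
  set.seed(5)
  data <- grow_da(30, 0.3, 0.2)
  fit <- run_abc_smc(data, "DA",
                     config = abc_config(n_particles = 50, n_populations = 1),
                     seed = 6)
  final <- tidy(fit)
  expect_equal(nrow(final), 50L)
  expect_equal(unique(final$weight), 1 / 50)   # all s = R, uniform
  expect_equal(fit$epsilons, Inf)
})

test_that("populations are normalized, in-prior, and tighten monotonically", {
  set.seed(7)
  data <- grow_da(50, 0.3, 0.2)
  prior <- prior_spec(delta = c(0.1, 0.9), alpha = c(0, 0.5))
  fit <- run_abc_smc(data, "DA", prior = prior,
                     config = abc_config(n_particles = 40, n_populations = 4),
                     seed = 8)
  for (t in 1:4) {
    gen <- tidy(fit, generation = t)
    expect_lt(abs(sum(gen$weight) - 1), 1e-12)
    expect_true(all(gen$delta >= 0.1 & gen$delta <= 0.9))
    expect_true(all(gen$alpha >= 0 & gen$alpha <= 0.5))
  }
  expect_true(all(diff(fit$epsilons) < 0))
  expect_true(all(tidy(fit, generation = 4)$distance <= fit$epsilons[4]))
})

test_that("a huge tolerance returns the uniform prior", {
  set.seed(9)
  data <- grow_da(20, 0.3, 0.2)
  fit <- run_abc_smc(data, "DA",
                     config = abc_config(n_particles = 1000, n_populations = 2,
                                         epsilon = c(1e9, 1e8)),
                     seed = 10)
  final <- tidy(fit)
  idx <- sample.int(1000, 1000, replace = TRUE, prob = final$weight)
  for (par in c("delta", "alpha")) {
    ks <- suppressWarnings(stats::ks.test(final[[par]][idx], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("identical seeds give bit-identical population traces", {
  set.seed(11)
  data <- grow_da(40, 0.3, 0.2)
  f1 <- run_abc_smc(data, "DA",
                    config = abc_config(n_particles = 25, n_populations = 3),
                    seed = 12)
  f2 <- run_abc_smc(data, "DA",
                    config = abc_config(n_particles = 25, n_populations = 3),
                    seed = 12)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$epsilons, f2$epsilons)
})

test_that("posteriors concentrate on the generating DAC parameters", {
  set.seed(13)
  data <- grow_dac(150, delta = 0.3, alpha = 0.2)
  fit <- run_abc_smc(data, "DAC",
                     config = abc_config(n_particles = 100, n_populations = 4),
                     seed = 14)
  final <- tidy(fit)
  ci <- function(x, w, probs = c(0.05, 0.95)) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    c(x[o][which(cw >= probs[1])[1]], x[o][which(cw >= probs[2])[1]])
  }
  d_ci <- ci(final$delta, final$weight)
  a_ci <- ci(final$alpha, final$weight)
  expect_true(d_ci[1] <= 0.3 && 0.3 <= d_ci[2])
  expect_true(a_ci[1] <= 0.2 && 0.2 <= a_ci[2])
})

test_that("a vanishing acceptance rate aborts with a diagnostic", {
  set.seed(15)
  data <- grow_da(25, 0.3, 0.2)
  expect_error(
    run_abc_smc(data, "DA",
                config = abc_config(n_particles = 10, n_populations = 2,
                                    epsilon = c(1e-12, 1e-13),
                                    min_acceptance = 0.5),
                seed = 16),
    "tolerance")
})
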
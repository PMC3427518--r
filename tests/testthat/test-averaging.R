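test_that("model averaging is a posterior-weighted convex combination", {
  expect_equal(model_averaged_statistic(c(A = 0.5, B = 0.5), list(A = 2, B = 4)), 3)
  expect_equal(model_averaged_statistic(c(A = 1, B = 0), list(A = 7, B = 99)), 7)
  # probability-vector statistics stay probability vectors
  pooled <- model_averaged_statistic(
    c(A = 0.3, B = 0.7),
    list(A = c(0.5, 0.5), B = c(0.1, 0.2, 0.7)))
  expect_equal(sum(pooled), 1)
  expect_length(pooled, 3)
  # linearity and invariance under zero-posterior additions
  v <- list(A = c(1, 2), B = c(3, 4))
  base <- model_averaged_statistic(c(A = 0.4, B = 0.6), v)
  expect_equal(model_averaged_statistic(c(A = 0.4, B = 0.6, C = 0), v), base)
  expect_equal(model_averaged_statistic(c(A = 0.4, B = 0.6),
                                        lapply(v, `*`, 2)), base * 2)
  expect_error(model_averaged_statistic(c(A = 0.5, B = 0.5), list(A = 1)),
               "positive posterior")
  expect_error(model_averaged_statistic(c(A = 0.7, B = 0.7), list(A = 1, B = 1)),
               "sum to 1")
})

test_that("a degenerate single-particle posterior predicts its own graph", {
  pop <- tibble::tibble(model = "DA", delta = 1, alpha = 0, p = NA_real_,
                        m = NA_real_, omega = NA_real_, weight = 1)
  set.seed(1)
  dd <- posterior_predictive_degree_distribution(
    pop, sampling = sampling_config(40, 40), n_draws = 5)
  # delta = 1, alpha = 0 always yields one edge plus isolates: P(k=1) = 1
  expect_equal(dd$degree, 1L)
  expect_equal(dd$probability, 1)
})

test_that("predictive degree distributions renormalize over k >= 1", {
  set.seed(2)
  data <- grow_dacr(80, 0.4, 0.25, 0.7, 3)
  fit <- run_abc_smc(data, "DACR",
                     config = abc_config(n_particles = 30, n_populations = 2),
                     seed = 3)
  dd <- posterior_predictive_degree_distribution(fit, n_draws = 20)
  expect_true(all(dd$degree >= 1))
  expect_lt(abs(sum(dd$probability) - 1), 1e-12)
  expect_true(all(dd$probability >= 0))
})

test_that("total variation distance behaves as a metric on distributions", {
  p <- tibble::tibble(degree = 1:2, probability = c(0.5, 0.5))
  q <- tibble::tibble(degree = 1:2, probability = c(0.2, 0.8))
  expect_equal(total_variation(p, p), 0)
  expect_equal(total_variation(p, q), 0.3)
  expect_equal(total_variation(q, p), 0.3)
  # vector interface and support alignment
  expect_equal(total_variation(c(0, 1), c(0, 0, 1)), 1)
})
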
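test_that("the model kernel switches with the stated probabilities", {
  expect_equal(perturb_model("DA", c("DA", "LPA"), switch_prob = 0), "DA")
  set.seed(1)
  for (i in 1:20) {
    expect_equal(perturb_model("DA", c("DA", "LPA"), switch_prob = 1), "LPA")
  }
  expect_message(perturb_model("DA", "DA", switch_prob = 0.5), "one model")
  expect_error(perturb_model("DA", character(0), 0.5), "nonempty")
  models <- network_models()   # 6 models
  set.seed(2)
  draws <- replicate(20000, perturb_model("DACR", models, switch_prob = 0.3,
                                          warn_singleton = FALSE))
  for (mm in setdiff(models, "DACR")) {
    phat <- mean(draws == mm)
    expect_lt(abs(phat - 0.06), 3 * sqrt(0.06 * 0.94 / 20000))
  }
})

test_that("marginal model posteriors are summed particle weights", {
  pop <- tibble::tibble(model = c("DA", "DA", "LPA"),
                        weight = c(0.2, 0.3, 0.5))
  post <- marginal_model_posterior(pop)
  expect_equal(post[["DA"]], 0.5)
  expect_equal(post[["LPA"]], 0.5)
  # invariant under row order / label ordering
  post_r <- marginal_model_posterior(pop[c(3, 1, 2), ], c("LPA", "DA"))
  expect_equal(post_r[["DA"]], post[["DA"]])
  one <- tibble::tibble(model = "DAC", weight = 1)
  expect_equal(marginal_model_posterior(one)[["DAC"]], 1)
  # absent configured models appear with probability zero
  post0 <- marginal_model_posterior(one, c("DAC", "GSF"))
  expect_equal(post0[["GSF"]], 0)
  expect_error(marginal_model_posterior(tibble::tibble(model = "DA", weight = 0.7)),
               "not normalized")
})

test_that("joint weights reduce to the single-model weights", {
  expect_equal(compute_weight_joint("DA", c(delta = 0.4, alpha = 0.1), s = 3), 3)
  prior <- prior_spec(delta = c(0, 1), alpha = c(0, 1))
  prev <- tibble::tibble(model = "DA", delta = c(0.4, 0.6), alpha = c(0.1, 0.2),
                         weight = c(0.5, 0.5))
  bw <- c(delta = 0.1, alpha = 0.1)
  w_single <- compute_weight(c(delta = 0.5, alpha = 0.15), 2, prev, bw, prior)
  w_joint <- compute_weight_joint("DA", c(delta = 0.5, alpha = 0.15), 2,
                                  prev, list(DA = bw), list(DA = prior),
                                  switch_prob = 0.2)
  expect_equal(w_joint, w_single)
})

test_that("symmetric proposals under mirrored populations get equal weights", {
  priors <- list(DA = prior_spec(delta = c(0, 1), alpha = c(0, 1)),
                 DAC = prior_spec(delta = c(0, 1), alpha = c(0, 1)))
  prev <- tibble::tibble(
    model = c("DA", "DAC"), delta = c(0.4, 0.4), alpha = c(0.2, 0.2),
    weight = c(0.5, 0.5))
  bws <- list(DA = c(delta = 0.1, alpha = 0.1), DAC = c(delta = 0.1, alpha = 0.1))
  wa <- compute_weight_joint("DA", c(delta = 0.45, alpha = 0.25), 1, prev,
                             bws, priors, switch_prob = 0.2)
  wb <- compute_weight_joint("DAC", c(delta = 0.45, alpha = 0.25), 1, prev,
                             bws, priors, switch_prob = 0.2)
  expect_equal(wa, wb)
})

test_that("the joint sampler with one model replays the single-model sampler", {
  set.seed(3)
  data <- grow_da(40, 0.3, 0.2)
  cfg <- abc_config(n_particles = 20, n_populations = 3)
  f1 <- run_abc_smc(data, "DA", config = cfg, seed = 4)
  f2 <- suppressMessages(spectrabc:::.abc_engine(
    data, models = "DA", priors = list(DA = default_prior("DA")),
    config = cfg, sampling = NULL, switch_prob = 0.2, seed = 4))
  expect_identical(f1$trace, f2$trace)
})

test_that("a zero switch probability makes the initial model absorbing", {
  set.seed(5)
  data <- grow_da(40, 0.3, 0.2)
  fit <- run_abc_smc_model_selection(
    data, c("DA", "DAC"),
    config = abc_config(n_particles = 25, n_populations = 3),
    switch_prob = 0, model_prior = c(DA = 1, DAC = 0), seed = 6)
  for (t in 1:3) {
    expect_true(all(tidy(fit, generation = t)$model == "DA"))
  }
  expect_equal(fit$model_posterior[["DA"]], 1)
})

test_that("model posteriors are normalized in every generation", {
  set.seed(7)
  data <- grow_da(50, 0.3, 0.2)
  fit <- run_abc_smc_model_selection(
    data, c("DA", "DAC", "LPA"),
    config = abc_config(n_particles = 40, n_populations = 3), seed = 8)
  for (t in 1:3) {
    gen <- tidy(fit, generation = t)
    post <- marginal_model_posterior(gen, fit$models)
    expect_lt(abs(sum(post) - 1), 1e-12)
    expect_true(all(post >= 0))
  }
})
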
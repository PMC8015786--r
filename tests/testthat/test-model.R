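test_that("log_prior matches closed forms and rejects non-positive SDs", {
  inp <- small_inputs()
  # all locations 0, all SDs at the half-Cauchy median (scale 2 -> median 2):
  # value equals the independent sum of textbook log-pdfs
  p <- model_parameters(inp, sigma_lambda = rep(2, inp$F),
                        sigma_obs = rep(2, inp$S), sigma_site = rep(2, inp$S))
  n_sd <- inp$F + 2 * inp$S
  # independent summation oracle
  lp_oracle <- (inp$F * 3 + inp$S) * dnorm(0, 0, 2, log = TRUE) +
    (inp$S * inp$K) * dnorm(0, 0, 2, log = TRUE) +       # gamma at 0, sd 2
    length(inp$y) * dnorm(0, 0, 2, log = TRUE) +         # eps at 0, sd 2
    n_sd * (log(2) + dcauchy(2, 0, 2, log = TRUE))
  expect_equal(log_prior(p, inp), lp_oracle, tolerance = 1e-12)

  # one Normal(0,2) term at its mode contributes -log(2*sqrt(2*pi))
  p2 <- p; p2$lambda_bar[1] <- 0
  p3 <- p; p3$lambda_bar[1] <- 1
  expect_equal(log_prior(p2, inp) - log_prior(p3, inp),
               dnorm(0, 0, 2, log = TRUE) - dnorm(1, 0, 2, log = TRUE))
  expect_equal(dnorm(0, 0, 2, log = TRUE), -log(2 * sqrt(2 * pi)))

  p4 <- p; p4$sigma_lambda[1] <- -1
  expect_identical(log_prior(p4, inp), -Inf)
})

test_that("process density evaluates the regime-appropriate normal", {
  gm <- data.frame(species = "A1", group = "benthic invertivore")
  survey <- data.frame(year = 2000:2001, month = 7L, site = "M",
                       species = "A1", count = 1L, effort = 1)
  inp <- build_model_inputs(survey, NULL, gm)
  p <- model_parameters(inp, sigma_lambda = 1, lambda = matrix(0, 1, 1))
  # one transition, lambda = lambda_bar = 0, sd 1: standard normal at its mean
  expect_equal(process_log_density(p, inp), -0.5 * log(2 * pi))

  # regime-2 deviation of zero gives the same value
  inp2 <- build_model_inputs(
    rbind(survey, data.frame(year = 2002L, month = 7L, site = "M",
                             species = "A1", count = 1L, effort = 1)),
    covariate_series(2000:2001, c(10, 30)), gm)
  p2 <- model_parameters(inp2, alpha = 0, beta = 1, sigma_lambda = 1,
                         lambda = matrix(inp2$x, 1, 2))
  expect_equal(process_log_density(p2, inp2), 2 * (-0.5 * log(2 * pi)))

  p3 <- model_parameters(inp, sigma_lambda = -0.1)
  expect_identical(process_log_density(p3, inp), -Inf)
})

test_that("observation density is the Poisson log-pmf at the exp-link mean", {
  gm <- data.frame(species = "A1", group = "benthic invertivore")
  survey <- data.frame(year = 2000:2001, month = 7L, site = "M",
                       species = "A1", count = c(0L, 2L), effort = 1)
  inp <- build_model_inputs(survey, NULL, gm)
  # state 0 -> mu = 1 for the first count; lambda = log(2) -> mu = 2 for the
  # second; log-factorial terms included
  p <- model_parameters(inp, n1 = 0, lambda = matrix(log(2), 1, 1),
                        gamma = matrix(0, 1, 1), eps = c(0, 0))
  lat <- latent_states(p, inp)
  expect_equal(observation_log_density(p, lat, inp),
               -1 + (2 * log(2) - 2 - log(2)))
})

test_that("joint log posterior equals an independently coded oracle", {
  # hand fixture: 2 species, 3 years (the oracle loops over every term)
  inp <- small_inputs()
  for (seed in 1:10) {
    p <- random_params(inp, seed)
    expect_equal(joint_log_posterior(p, inp), oracle_joint(p, inp),
                 tolerance = 1e-8)
  }
  # richer fixture from the simulator
  cfg <- tiny_sim_config()
  sim <- simulate_dataset(cfg, 77)
  inp2 <- build_model_inputs(sim$survey, sim$covariate, cfg$group_map)
  p2 <- random_params(inp2, 5)
  expect_equal(joint_log_posterior(p2, inp2), oracle_joint(p2, inp2),
               tolerance = 1e-8)
})

test_that("joint density decomposes into its three components", {
  inp <- small_inputs()
  for (seed in 1:100) {
    p <- random_params(inp, seed)
    expect_equal(joint_log_posterior(p, inp),
                 log_prior(p, inp) + process_log_density(p, inp) +
                   observation_log_density(p, latent_states(p, inp), inp),
                 tolerance = 1e-10)
  }
})

test_that("observation density is invariant to row order", {
  inp <- small_inputs()
  p <- random_params(inp, 42)
  set.seed(1)
  perm <- sample(length(inp$y))
  inp_p <- inp
  for (nm in c("y", "species_idx", "year_idx", "site_idx", "effort"))
    inp_p[[nm]] <- inp[[nm]][perm]
  p_p <- p
  p_p$eps <- p$eps[perm]
  expect_equal(joint_log_posterior(p_p, inp_p), joint_log_posterior(p, inp))
})

test_that("likelihood is exchangeable under species relabeling in a guild", {
  # two species in one guild with swapped labels and swapped parameters
  gm <- data.frame(species = c("A1", "A2"),
                   group = "benthic invertivore")
  survey <- expand.grid(year = 2000:2002, month = 7L, site = "M",
                        species = c("A1", "A2"), stringsAsFactors = FALSE)
  survey$count <- c(3L, 1L, 4L, 0L, 2L, 5L)
  survey$effort <- 1
  inp <- build_model_inputs(survey, NULL, gm)
  p <- random_params(inp, 8)
  # swap the two species everywhere (they share guild-level parameters)
  swap <- c(2L, 1L)
  p_sw <- p
  p_sw$n1 <- p$n1[swap]
  p_sw$lambda <- p$lambda[swap, , drop = FALSE]
  p_sw$gamma <- p$gamma[swap, , drop = FALSE]
  p_sw$sigma_obs <- p$sigma_obs[swap]
  p_sw$sigma_site <- p$sigma_site[swap]
  inp_sw <- inp
  inp_sw$species_idx <- swap[inp$species_idx]
  expect_equal(joint_log_posterior(p_sw, inp_sw), joint_log_posterior(p, inp))
})

test_that("fit_ssm returns the configured number of draws, reproducibly", {
  cfg <- tiny_sim_config()
  sim <- simulate_dataset(cfg, 3)
  inp <- build_model_inputs(sim$survey, sim$covariate, cfg$group_map)
  f1 <- fit_ssm(inp, chains = 2, iter = 300, warmup = 150, seed = 5)
  expect_equal(dim(f1$draws)[1], 150)
  expect_equal(dim(f1$draws)[2], 2)
  expect_equal(f1$mcmc$saved, 300)
  f2 <- fit_ssm(inp, chains = 2, iter = 300, warmup = 150, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ssm(inp, chains = 2, iter = 300, warmup = 150, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
  # all Table-2 parameter families monitored
  pars <- sub("\\[.*", "", dimnames(f1$draws)[[3]])
  expect_true(all(c("lambda_bar", "sigma_lambda", "alpha", "beta", "n1",
                    "lambda", "gamma", "sigma_obs", "sigma_site") %in% pars))
})

test_that("backend failures surface as structured errors", {
  cfg <- tiny_sim_config()
  sim <- simulate_dataset(cfg, 3)
  inp <- build_model_inputs(sim$survey, sim$covariate, cfg$group_map)
  inp$y[1] <- -5L  # impossible Poisson outcome
  expect_error(fit_ssm(inp, chains = 1, iter = 100, warmup = 50, seed = 1),
               "MCMC backend failure")
})
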
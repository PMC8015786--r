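# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# a tiny guild map: 2 benthic, 2 general, 1 planktivore
tiny_guilds <- function() {
  data.frame(species = c("A1", "A2", "B1", "B2", "C1"),
             group = rep(c("benthic invertivore", "general invertivore",
                           "planktivore"), c(2, 2, 1)),
             stringsAsFactors = FALSE)
}

# small simulation configuration used throughout: 5 species, 15 years,
# 2 sites, 2 events per site-year, covariate over the last 7 origins
tiny_sim_config <- function(...) {
  sim_config(
    group_map = tiny_guilds(),
    start_year = 2000, n_years = 15,
    eras = list(list(years = 2000:2014, sites = c("M", "K"), events = 2L)),
    covariate_onset_year = 2008,
    truth = list(n1 = c(2, 3, 2.5, 3.5, 3), sigma_obs = rep(0.5, 5),
                 sigma_site = rep(0.3, 5)),
    ...)
}

# model inputs for a hand-specified survey (2 species, 3 years, 2 sites)
small_inputs <- function() {
  survey <- expand.grid(year = 2000:2002, month = 7L, site = c("M", "K"),
                        species = c("A1", "B1"), stringsAsFactors = FALSE)
  survey$count <- c(5L, 3L, 8L, 2L, 0L, 4L, 7L, 1L, 9L, 6L, 2L, 3L)
  survey$effort <- 1
  gm <- data.frame(species = c("A1", "B1"),
                   group = c("benthic invertivore", "planktivore"),
                   stringsAsFactors = FALSE)
  # covariate years must end at or before the last transition origin (2001)
  cov <- covariate_series(2000:2001, c(10, 30))
  build_model_inputs(survey, cov, gm)
}

# random valid parameter point for given inputs
random_params <- function(inputs, seed) {
  set.seed(seed)
  model_parameters(
    inputs,
    lambda_bar = rnorm(inputs$F, 0, 0.5),
    sigma_lambda = runif(inputs$F, 0.1, 1),
    alpha = rnorm(inputs$F, 0, 0.5),
    beta = rnorm(inputs$F, 0, 0.5),
    n1 = rnorm(inputs$S, 1, 1),
    lambda = matrix(rnorm(inputs$S * (inputs$T - 1), 0, 0.4),
                    inputs$S, inputs$T - 1),
    gamma = matrix(rnorm(inputs$S * inputs$K, 0, 0.3), inputs$S, inputs$K),
    eps = rnorm(length(inputs$y), 0, 0.3),
    sigma_obs = runif(inputs$S, 0.2, 1),
    sigma_site = runif(inputs$S, 0.2, 1))
}

# Independently coded monolithic joint log posterior: one explicit loop per
# term, no shared code with the package implementation.
oracle_joint <- function(p, inp) {
  lp <- 0
  for (f in seq_len(inp$F)) {
    if (p$sigma_lambda[f] <= 0) return(-Inf)
    lp <- lp + dnorm(p$lambda_bar[f], 0, 2, log = TRUE) +
      dnorm(p$alpha[f], 0, 2, log = TRUE) +
      dnorm(p$beta[f], 0, 2, log = TRUE) +
      log(2) + dcauchy(p$sigma_lambda[f], 0, 2, log = TRUE)
  }
  for (s in seq_len(inp$S)) {
    if (p$sigma_obs[s] <= 0 || p$sigma_site[s] <= 0) return(-Inf)
    lp <- lp + dnorm(p$n1[s], 0, 2, log = TRUE) +
      log(2) + dcauchy(p$sigma_obs[s], 0, 2, log = TRUE) +
      log(2) + dcauchy(p$sigma_site[s], 0, 2, log = TRUE)
    for (k in seq_len(inp$K))
      lp <- lp + dnorm(p$gamma[s, k], 0, p$sigma_site[s], log = TRUE)
  }
  # process layer
  for (s in seq_len(inp$S)) {
    g <- inp$species_group[s]
    for (t in seq_len(inp$T - 1)) {
      mu <- if (inp$regime[t] == 2) p$alpha[g] + p$beta[g] * inp$x[t]
        else p$lambda_bar[g]
      lp <- lp + dnorm(p$lambda[s, t], mu, p$sigma_lambda[g], log = TRUE)
    }
  }
  # states by explicit accumulation, then observations one row at a time
  n <- matrix(NA_real_, inp$S, inp$T)
  for (s in seq_len(inp$S)) {
    n[s, 1] <- p$n1[s]
    for (t in 2:inp$T) n[s, t] <- n[s, t - 1] + p$lambda[s, t - 1]
  }
  for (i in seq_along(inp$y)) {
    lp <- lp + dnorm(p$eps[i], 0, p$sigma_obs[inp$species_idx[i]], log = TRUE)
    mu_i <- exp(n[inp$species_idx[i], inp$year_idx[i]] +
                  p$gamma[inp$species_idx[i], inp$site_idx[i]] + p$eps[i])
    lp <- lp + dpois(inp$y[i], mu_i, log = TRUE)
  }
  lp
}

# fabricate a guild_fit from a draw array (for summary-table oracles)
fake_fit <- function(inputs, draws) {
  structure(list(draws = draws, inputs = inputs,
                 mcmc = list(chains = dim(draws)[2],
                             saved = dim(draws)[1] * dim(draws)[2]),
                 backend = "fixture"),
            class = c("guild_fit", "posterior_draws"))
}

# draw array with given parameter names filled from a generator function
make_draws <- function(params, n_iter = 100, n_chain = 2,
                       gen = function(n, p) rnorm(n)) {
  a <- array(NA_real_, c(n_iter, n_chain, length(params)),
             dimnames = list(NULL, NULL, params))
  for (p in params) a[, , p] <- gen(n_iter * n_chain, p)
  a
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
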
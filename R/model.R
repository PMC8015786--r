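#' Model parameter bundle
#'
#' Collects every unknown of the state-space model into one list, with
#' dimensions matching a \code{model_inputs} object: per-guild
#' \code{lambda_bar}, \code{sigma_lambda}, \code{alpha}, \code{beta};
#' per-species \code{n1}, \code{sigma_obs}, \code{sigma_site}; the
#' species-by-transition growth draws \code{lambda}; the species-by-site
#' effects \code{gamma}; and the per-observation overdispersion draws
#' \code{eps}.
#'
#' @param inputs a \code{model_inputs} object (for dimensions).
#' @param ... named components overriding the zero/unit defaults.
#' @return A named list of parameter arrays.
#' @export
model_parameters <- function(inputs, ...) {
  p <- list(
    lambda_bar = rep(0, inputs$F),
    sigma_lambda = rep(1, inputs$F),
    alpha = rep(0, inputs$F),
    beta = rep(0, inputs$F),
    n1 = rep(0, inputs$S),
    lambda = matrix(0, inputs$S, inputs$T - 1),
    gamma = matrix(0, inputs$S, inputs$K),
    eps = rep(0, length(inputs$y)),
    sigma_obs = rep(1, inputs$S),
    sigma_site = rep(1, inputs$S)
  )
  utils::modifyList(p, list(...))
}

half_cauchy_log <- function(x, scale = 2) {
  if (any(x <= 0)) return(-Inf)
  sum(log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}

#' Log prior density
#'
#' Sum of the independent prior terms: Normal(0, 2) on the guild mean growth
#' rates, regression intercepts and slopes, and the initial log-abundances;
#' half-Cauchy(0, 2) on every standard deviation; and the hierarchical
#' normal priors on the site effects (SD \code{sigma_site[s]}) and
#' per-observation overdispersion draws (SD \code{sigma_obs[s]}).
#' Any non-positive SD yields \code{-Inf} rather than an error.
#'
#' @param params parameter list (\code{\link{model_parameters}}).
#' @param inputs \code{model_inputs} (supplies the species index of each
#'   observation's overdispersion draw).
#' @return Scalar log density.
#' @export
log_prior <- function(params, inputs) {
  lp_sd <- half_cauchy_log(c(params$sigma_lambda, params$sigma_obs,
                             params$sigma_site))
  if (!is.finite(lp_sd)) return(-Inf)
  lp <- lp_sd +
    sum(stats::dnorm(params$lambda_bar, 0, 2, log = TRUE)) +
    sum(stats::dnorm(params$alpha, 0, 2, log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, 2, log = TRUE)) +
    sum(stats::dnorm(params$n1, 0, 2, log = TRUE)) +
    sum(stats::dnorm(params$gamma, 0, params$sigma_site[row(params$gamma)],
                     log = TRUE)) +
    sum(stats::dnorm(params$eps, 0, params$sigma_obs[inputs$species_idx],
                     log = TRUE))
  lp
}

# regime-appropriate mean of lambda[s, t]
growth_mean_matrix <- function(params, inputs) {
  g <- inputs$species_group
  Tm1 <- inputs$T - 1
  mu <- matrix(params$lambda_bar[g], inputs$S, Tm1)
  r2 <- which(inputs$regime == 2L)
  if (length(r2))
    mu[, r2] <- outer(params$alpha[g], rep(1, length(r2))) +
      outer(params$beta[g], inputs$x[r2])
  mu
}

#' Process-layer log density
#'
#' Sum over species and year-transitions of the normal log density of the
#' growth draw at its regime-appropriate mean (guild mean in regime 1, guild
#' intercept + slope x covariate z-score in regime 2) with guild process SD.
#'
#' @inheritParams log_prior
#' @return Scalar log density; \code{-Inf} if any process SD is non-positive.
#' @export
process_log_density <- function(params, inputs) {
  if (any(params$sigma_lambda <= 0)) return(-Inf)
  mu <- growth_mean_matrix(params, inputs)
  sd_mat <- params$sigma_lambda[inputs$species_group][row(mu)]
  sum(stats::dnorm(params$lambda, mu, sd_mat, log = TRUE))
}

#' Latent log-abundance trajectories implied by the parameters
#'
#' The states are a deterministic function of the initial log-abundance and
#' the growth draws: n[s, t] = n1[s] + sum of lambda[s, 1:(t-1)].
#'
#' @inheritParams log_prior
#' @return S x T matrix of log-abundances.
#' @export
latent_states <- function(params, inputs) {
  cbind(params$n1, params$n1 + t(apply(params$lambda, 1, cumsum)))
}

#' Observation-layer log density
#'
#' Poisson log probability of each count at its exp-link mean
#' \code{exp(n[s,t] + gamma[s,site] + eps[i])}, summed over observations.
#' Log-factorial normalizing terms are included.
#'
#' @inheritParams log_prior
#' @param latent S x T latent state matrix (\code{\link{latent_states}}).
#' @return Scalar log density.
#' @export
observation_log_density <- function(params, latent, inputs) {
  log_mu <- latent[cbind(inputs$species_idx, inputs$year_idx)] +
    params$gamma[cbind(inputs$species_idx, inputs$site_idx)] +
    params$eps
  sum(stats::dpois(inputs$y, exp(log_mu), log = TRUE))
}

#' Joint log posterior (up to the marginal-likelihood constant)
#'
#' Exactly the sum of \code{\link{log_prior}},
#' \code{\link{process_log_density}} and
#' \code{\link{observation_log_density}}, with the latent states
#' reconstructed deterministically from \code{n1} and the growth draws.
#'
#' @inheritParams log_prior
#' @return Scalar log density; propagates \code{-Inf} from any component.
#' @export
joint_log_posterior <- function(params, inputs) {
  lp <- log_prior(params, inputs)
  if (!is.finite(lp)) return(-Inf)
  lproc <- process_log_density(params, inputs)
  if (!is.finite(lproc)) return(-Inf)
  lp + lproc +
    observation_log_density(params, latent_states(params, inputs), inputs)
}

# ---- JAGS backend -----------------------------------------------------------

is_fixed_zero <- function(fixed, nm) !is.null(fixed[[nm]]) && all(fixed[[nm]] == 0)

build_jags_code <- function(inputs, fixed = list(),
                            lambda_structure = "by_year",
                            pool_sigma = FALSE) {
  has_cov <- any(inputs$regime == 2L)
  has_eps <- !is_fixed_zero(fixed, "sigma_obs")
  has_gamma <- !is_fixed_zero(fixed, "sigma_site")
  prior_sd <- function(nm, pooled_name = NULL) {
    if (!is.null(fixed[[nm]])) return(NULL)   # supplied as data
    if (pool_sigma && !is.null(pooled_name))
      return(NULL)                            # scalar version declared elsewhere
    sprintf("    %s[idx] ~ dt(0, 0.25, 1) T(0,)", nm)
  }
  lines <- c("model {")
  # guild-level parameters
  lines <- c(lines, "  for (f in 1:F) {")
  if (is.null(fixed$lambda_bar))
    lines <- c(lines, "    lambda_bar[f] ~ dnorm(0, 0.25)")
  if (is.null(fixed$sigma_lambda))
    lines <- c(lines, "    sigma_lambda[f] ~ dt(0, 0.25, 1) T(0,)")
  if (has_cov) {
    if (is.null(fixed$alpha)) lines <- c(lines, "    alpha[f] ~ dnorm(0, 0.25)")
    if (is.null(fixed$beta))  lines <- c(lines, "    beta[f] ~ dnorm(0, 0.25)")
  }
  lines <- c(lines, "    tau_lambda[f] <- pow(sigma_lambda[f], -2)", "  }")
  # per-species scale parameters, optionally pooled across species
  if (pool_sigma) {
    if (has_eps && is.null(fixed$sigma_obs))
      lines <- c(lines, "  sigma_obs0 ~ dt(0, 0.25, 1) T(0,)")
    if (has_gamma && is.null(fixed$sigma_site))
      lines <- c(lines, "  sigma_site0 ~ dt(0, 0.25, 1) T(0,)")
  }
  lines <- c(lines, "  for (s in 1:S) {")
  if (is.null(fixed$n1)) lines <- c(lines, "    n1[s] ~ dnorm(0, 0.25)")
  if (has_eps && is.null(fixed$sigma_obs))
    lines <- c(lines, if (pool_sigma) "    sigma_obs[s] <- sigma_obs0"
               else "    sigma_obs[s] ~ dt(0, 0.25, 1) T(0,)")
  if (has_gamma && is.null(fixed$sigma_site))
    lines <- c(lines, if (pool_sigma) "    sigma_site[s] <- sigma_site0"
               else "    sigma_site[s] ~ dt(0, 0.25, 1) T(0,)")
  if (has_gamma)
    lines <- c(lines,
               "    for (k in 1:K) { gamma[s,k] ~ dnorm(0, pow(sigma_site[s], -2)) }")
  # regime-appropriate growth mean; x is 0-filled where regime 1, unused there
  mu_line <- if (has_cov)
    paste0("      mu_lam[s,t] <- equals(regime[t], 1) * lambda_bar[grp[s]] + ",
           "equals(regime[t], 2) * (alpha[grp[s]] + beta[grp[s]] * x[t])")
  else "      mu_lam[s,t] <- lambda_bar[grp[s]]"
  if (lambda_structure == "by_year") {
    lines <- c(lines, "    for (t in 1:(T-1)) {", mu_line,
               "      lambda[s,t] ~ dnorm(mu_lam[s,t], tau_lambda[grp[s]])",
               "    }")
  } else {
    lines <- c(lines, "    delta[s] ~ dnorm(0, tau_lambda[grp[s]])",
               "    for (t in 1:(T-1)) {", mu_line,
               "      lambda[s,t] <- mu_lam[s,t] + delta[s]",
               "    }")
  }
  lines <- c(lines, "    n[s,1] <- n1[s]",
             "    for (t in 2:T) { n[s,t] <- n[s,t-1] + lambda[s,t-1] }",
             "  }")
  # observation layer
  lines <- c(lines, "  for (i in 1:Nobs) {")
  if (has_eps)
    lines <- c(lines, "    eps[i] ~ dnorm(0, pow(sigma_obs[sp[i]], -2))")
  mu_terms <- c("n[sp[i], yr[i]]",
                if (has_gamma) "gamma[sp[i], st[i]]",
                if (has_eps) "eps[i]")
  lines <- c(lines,
             sprintf("    y[i] ~ dpois(exp(%s))", paste(mu_terms, collapse = " + ")),
             "  }", "}")
  paste(lines, collapse = "\n")
}

default_inits <- function(inputs, fixed, lambda_structure, pool_sigma,
                          chain_seed) {
  # start the latent states near the observed per-species mean counts so the
  # Poisson means are never astronomically far from the data
  mean_count <- tapply(inputs$y, inputs$species_idx, mean)
  n1 <- log(pmax(as.numeric(mean_count)[seq_len(inputs$S)], 0.5))
  n1[is.na(n1)] <- 0
  inits <- list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = chain_seed)
  if (is.null(fixed$n1)) inits$n1 <- n1
  if (is.null(fixed$lambda_bar)) inits$lambda_bar <- rep(0, inputs$F)
  if (is.null(fixed$sigma_lambda)) inits$sigma_lambda <- rep(0.5, inputs$F)
  if (any(inputs$regime == 2L)) {
    if (is.null(fixed$alpha)) inits$alpha <- rep(0, inputs$F)
    if (is.null(fixed$beta)) inits$beta <- rep(0, inputs$F)
  }
  if (lambda_structure == "by_year")
    inits$lambda <- matrix(0, inputs$S, inputs$T - 1)
  else inits$delta <- rep(0, inputs$S)
  if (!is_fixed_zero(fixed, "sigma_obs")) {
    inits$eps <- rep(0, length(inputs$y))
    if (is.null(fixed$sigma_obs)) {
      if (pool_sigma) inits$sigma_obs0 <- 0.5
      else inits$sigma_obs <- rep(0.5, inputs$S)
    }
  }
  if (!is_fixed_zero(fixed, "sigma_site")) {
    inits$gamma <- matrix(0, inputs$S, inputs$K)
    if (is.null(fixed$sigma_site)) {
      if (pool_sigma) inits$sigma_site0 <- 0.5
      else inits$sigma_site <- rep(0.5, inputs$S)
    }
  }
  inits
}

#' Fit the state-space model by MCMC
#'
#' Samples the joint posterior of the guild-pooled growth model with JAGS.
#' The default protocol runs 3 chains of 5,000 iterations each with the
#' first 2,000 per chain discarded, retaining 9,000 draws.
#'
#' @param inputs a \code{model_inputs} object.
#' @param chains number of MCMC chains.
#' @param iter total iterations per chain (warmup included).
#' @param warmup iterations per chain discarded as warmup/adaptation.
#' @param seed integer seed; chain c uses seed + c, making runs reproducible.
#' @param thin thinning interval for the saved draws.
#' @param fixed named list of parameters to hold fixed at known values
#'   instead of sampling them (passed to JAGS as data). Fixing
#'   \code{sigma_obs} or \code{sigma_site} to 0 removes the corresponding
#'   random-effect layer from the sampled model entirely.
#' @param lambda_structure \code{"by_year"} (default: an independent growth
#'   draw per species and transition) or \code{"species_constant"} (a single
#'   species offset around the guild mean, constant over time).
#' @param pool_sigma if TRUE, share one overdispersion SD and one site SD
#'   across species instead of the default per-species scales.
#' @param monitor extra node names to monitor in addition to the defaults.
#' @param quiet suppress JAGS progress output.
#' @return A \code{guild_fit} object: draw array \code{draws} with dimensions
#'   (iterations, chains, parameters), plus \code{inputs}, the MCMC
#'   configuration and the backend version string.
#' @export
fit_ssm <- function(inputs, chains = 3, iter = 5000, warmup = 2000,
                    seed = 1, thin = 1, fixed = list(),
                    lambda_structure = c("by_year", "species_constant"),
                    pool_sigma = FALSE, monitor = character(), quiet = TRUE) {
  lambda_structure <- match.arg(lambda_structure)
  stopifnot(inherits(inputs, "model_inputs"))
  if (warmup >= iter) stop("warmup must be smaller than iter")
  if (chains < 1) stop("need at least one chain")
  has_cov <- any(inputs$regime == 2L)
  code <- build_jags_code(inputs, fixed, lambda_structure, pool_sigma)
  x0 <- inputs$x
  x0[is.na(x0)] <- 0
  data <- list(y = inputs$y, sp = inputs$species_idx, yr = inputs$year_idx,
               st = inputs$site_idx, Nobs = length(inputs$y),
               S = inputs$S, F = inputs$F, T = inputs$T, K = inputs$K,
               grp = inputs$species_group, regime = inputs$regime, x = x0)
  if (!has_cov) { data$regime <- NULL; data$x <- NULL }
  if (!any(grepl("gamma", code))) { data$st <- NULL; data$K <- NULL }
  for (nm in names(fixed))
    if (!is_fixed_zero(fixed, nm)) data[[nm]] <- fixed[[nm]]
  inits <- lapply(seq_len(chains), function(ch)
    default_inits(inputs, fixed, lambda_structure, pool_sigma,
                  chain_seed = as.integer(seed) + ch))
  monitors <- c("lambda_bar", "sigma_lambda",
                if (has_cov) c("alpha", "beta"),
                "n1", "lambda",
                if (grepl("gamma", code, fixed = TRUE)) "gamma",
                if (is.null(fixed$sigma_obs) && grepl("eps", code, fixed = TRUE))
                  "sigma_obs",
                if (is.null(fixed$sigma_site) && grepl("gamma", code, fixed = TRUE))
                  "sigma_site",
                monitor)
  monitors <- setdiff(unique(monitors), names(fixed))
  run <- function() {
    m <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                           n.chains = chains,
                           n.adapt = min(1000, warmup), quiet = quiet)
    burn <- warmup - min(1000, warmup)
    if (burn > 0) stats::update(m, n.iter = burn, progress.bar = "none")
    rjags::coda.samples(m, variable.names = monitors,
                        n.iter = iter - warmup, thin = thin,
                        progress.bar = "none")
  }
  samp <- tryCatch(run(), error = function(e)
    stop("MCMC backend failure: ", conditionMessage(e),
         "\n(model had ", length(inputs$y), " observations, ",
         inputs$S, " species, ", inputs$T, " years)", call. = FALSE))
  draws <- coda_to_array(samp)
  dimnames(draws)[[3]] <- normalize_param_names(dimnames(draws)[[3]])
  structure(list(draws = draws, inputs = inputs,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup,
                             thin = thin, seed = seed,
                             saved = dim(draws)[1] * dim(draws)[2],
                             lambda_structure = lambda_structure,
                             pool_sigma = pool_sigma,
                             fixed = names(fixed)),
                 model_code = code,
                 backend = paste0("JAGS ",
                                  utils::packageVersion("rjags"))),
            class = c("guild_fit", "posterior_draws"))
}

# coda drops the index on length-1 nodes; restore it so parameter names are
# uniform regardless of dimensions
normalize_param_names <- function(nm) {
  bare <- !grepl("\\[", nm)
  vec1 <- nm %in% c("lambda_bar", "sigma_lambda", "alpha", "beta",
                    "n1", "sigma_obs", "sigma_site")
  mat1 <- nm %in% c("lambda", "gamma")
  nm[bare & vec1] <- paste0(nm[bare & vec1], "[1]")
  nm[bare & mat1] <- paste0(nm[bare & mat1], "[1,1]")
  nm
}

# coda mcmc.list -> array (iterations, chains, parameters)
coda_to_array <- function(samp) {
  mats <- lapply(samp, as.matrix)
  a <- array(NA_real_, c(nrow(mats[[1]]), length(mats), ncol(mats[[1]])),
             dimnames = list(NULL, NULL, colnames(mats[[1]])))
  for (ch in seq_along(mats)) a[, ch, ] <- mats[[ch]]
  a
}

#' Extract the draw matrix (iterations x chains) of one scalar parameter
#'
#' @param fit a \code{guild_fit} or a draw array.
#' @param parameter flattened parameter name, e.g. \code{"beta[2]"} or
#'   \code{"lambda[3,12]"}.
#' @return iterations x chains numeric matrix.
#' @export
draw_matrix <- function(fit, parameter) {
  a <- if (is.array(fit)) fit else fit$draws
  if (!parameter %in% dimnames(a)[[3]])
    stop("no monitored parameter named '", parameter, "'")
  m <- a[, , parameter, drop = FALSE]
  dim(m) <- dim(a)[1:2]
  m
}

#' @export
print.guild_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("State-space model fit (", x$backend, "): ",
      d[2], " chains x ", d[1], " saved draws (", x$mcmc$saved,
      " total), ", d[3], " monitored parameters\n", sep = "")
  invisible(x)
}
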
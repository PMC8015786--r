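#' Configuration for the forward simulator
#'
#' Bundles the survey design and the true parameter values used to
#' forward-simulate complete datasets (latent log-abundance trajectories,
#' growth-rate draws, trawl counts and a covariate series) from the model's
#' own generative process. The defaults emulate the southern Lake Michigan
#' study design: 10 species in 3 guilds (4 benthic invertivore, 3 general
#' invertivore, 3 planktivore), 33 annual states, a site roster growing
#' 2 -> 3 -> 4 across three eras (6 events per site-year while sampling ran
#' twice monthly June-August, 1 in the final once-a-year era), and a
#' zooplankton record covering the 19 final transition-origin years.
#'
#' @param group_map species-to-guild map (defines S and the guild sizes).
#' @param start_year first survey year.
#' @param n_years number of annual states T.
#' @param eras list of eras, each \code{list(years=, sites=, events=)} giving
#'   the site roster and the number of events per site-year; \code{NULL}
#'   builds the default three-era design scaled to \code{n_years}.
#' @param covariate_onset_year first year with a covariate value (first
#'   regime-2 transition origin); \code{NULL} disables the covariate and the
#'   whole series runs under the guild-mean regime.
#' @param cov_trend list \code{intercept}, \code{slope} (biomass units per
#'   year) and \code{sdlog} (lognormal noise SD) for the simulated covariate;
#'   defaults give a declining series with mean and spread comparable to a
#'   summer zooplankton biomass record in ug DW/m^3.
#' @param truth list of true parameter values: per-guild \code{lambda_bar},
#'   \code{sigma_lambda}, \code{alpha}, \code{beta}; per-species \code{n1}
#'   (initial log-abundance), \code{sigma_obs} (overdispersion SD) and
#'   \code{sigma_site} (site-effect SD). Missing entries take defaults with
#'   guild-level spread and covariate slopes of realistic magnitude.
#' @param count_cap Poisson means above this cap flag the event as an
#'   overflow rather than truncating it silently.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(group_map = lake_michigan_guilds(),
                       start_year = 1984, n_years = 33, eras = NULL,
                       covariate_onset_year = 1997,
                       cov_trend = list(intercept = 45000, slope = -1800,
                                        sdlog = 0.3),
                       truth = list(), count_cap = 1e8) {
  validate_group_map(group_map)
  species <- group_map$species
  groups <- unique(group_map$group)
  S <- length(species); F_ <- length(groups)
  if (n_years < 2) stop("n_years must be >= 2")
  years <- seq.int(start_year, start_year + n_years - 1)
  if (is.null(eras)) {
    # default three-era design: short 2-site start, long 3-site core,
    # 7-year 4-site tail with sparse sampling
    b1 <- min(5L, max(1L, n_years - 2L))
    b3 <- if (n_years >= 12) 7L else 0L
    eras <- list(
      list(years = years[seq_len(b1)], sites = c("M", "K"), events = 6L))
    if (n_years - b1 - b3 > 0)
      eras <- c(eras, list(list(years = years[(b1 + 1):(n_years - b3)],
                                sites = c("M", "K", "G"), events = 6L)))
    if (b3 > 0)
      eras <- c(eras, list(list(years = years[(n_years - b3 + 1):n_years],
                                sites = c("M", "K", "G", "E"), events = 1L)))
  }
  era_years <- unlist(lapply(eras, `[[`, "years"))
  if (!setequal(era_years, years) || anyDuplicated(era_years))
    stop("eras must partition the study years")
  for (e in eras) if (e$events < 1) stop("events per site-year must be >= 1")
  if (!is.null(covariate_onset_year)) {
    if (covariate_onset_year <= start_year ||
        covariate_onset_year > start_year + n_years - 2)
      stop("covariate onset must fall strictly inside the study span, ",
           "leaving at least one transition in each regime")
  }
  defaults <- list(
    lambda_bar = rep(0, F_),
    sigma_lambda = rep(c(0.5, 0.25, 0.6), length.out = F_),
    alpha = rep(-0.1, F_),
    beta = c(-0.07, -0.19, 0.22, rep(0, max(0, F_ - 3)))[seq_len(F_)],
    n1 = rep(c(-0.4, 0, 1.2, 3.8, 6.1, 6.3, 2.1, 3.3, 3.6, 4.4),
             length.out = S),
    sigma_obs = rep(1, S),
    sigma_site = rep(0.5, S)
  )
  truth <- utils::modifyList(defaults, truth)
  for (nm in c("lambda_bar", "sigma_lambda", "alpha", "beta"))
    if (length(truth[[nm]]) != F_)
      stop("truth$", nm, " must have one value per guild (", F_, ")")
  for (nm in c("n1", "sigma_obs", "sigma_site"))
    if (length(truth[[nm]]) != S)
      stop("truth$", nm, " must have one value per species (", S, ")")
  for (nm in c("sigma_lambda", "sigma_obs", "sigma_site"))
    if (any(truth[[nm]] < 0)) stop("truth$", nm, " must be >= 0")
  structure(list(group_map = group_map, species = species, groups = groups,
                 S = S, F = F_, start_year = start_year, n_years = n_years,
                 years = years, eras = eras,
                 covariate_onset_year = covariate_onset_year,
                 cov_trend = cov_trend, truth = truth,
                 count_cap = count_cap),
            class = "sim_config")
}

# fixed offsets give each simulation component its own RNG sub-stream,
# so e.g. adding species never perturbs the covariate draws
component_seed <- function(seed, component) {
  offsets <- c(covariate = 104729L, growth = 224737L,
               sites = 350377L, events = 479909L)
  (as.integer(seed) + offsets[[component]]) %% 2147483587L
}

#' Simulate an annual covariate series
#'
#' Draws a declining biomass series: a linear trend multiplied by lognormal
#' noise, mimicking a summer zooplankton dry-weight record.
#'
#' @param T_cov number of covariate years (>= 2).
#' @param seed integer seed for this component's RNG stream.
#' @param start_year calendar year of the first covariate value.
#' @param trend list with \code{intercept}, \code{slope}, \code{sdlog}.
#' @return A \code{covariate_series}.
#' @export
simulate_covariate <- function(T_cov, seed, start_year = 1997,
                               trend = list(intercept = 45000, slope = -1800,
                                            sdlog = 0.3)) {
  if (T_cov < 2) stop("T_cov must be >= 2 (z-scores undefined otherwise)")
  if (trend$sdlog == 0 && trend$slope == 0)
    stop("degenerate covariate configuration: no trend and no noise ",
         "produce a constant series")
  set.seed(component_seed(seed, "covariate"))
  base <- trend$intercept + trend$slope * (seq_len(T_cov) - 1)
  if (any(base <= 0)) stop("covariate trend line reaches zero or below")
  biomass <- base * exp(stats::rnorm(T_cov, 0, trend$sdlog))
  covariate_series(seq.int(start_year, start_year + T_cov - 1), biomass)
}

# regime and covariate z-score per transition implied by a sim_config
regime_layout <- function(config, covariate) {
  Tm1 <- config$n_years - 1
  origin <- config$years[seq_len(Tm1)]
  regime <- rep(1L, Tm1)
  x <- rep(NA_real_, Tm1)
  if (!is.null(config$covariate_onset_year)) {
    in_cov <- origin >= config$covariate_onset_year
    regime[in_cov] <- 2L
    x[in_cov] <- covariate$z[match(origin[in_cov], covariate$year)]
    if (anyNA(x[in_cov]))
      stop("covariate series does not cover every covariate-regime transition")
  }
  list(regime = regime, x = x)
}

#' Simulate species-year growth-rate draws
#'
#' One draw per species per year-transition from the regime-appropriate
#' normal: guild mean before the covariate record, guild intercept plus
#' slope times the covariate z-score during it; guild-specific process SD
#' throughout. SDs of zero make the draws exactly the regime mean.
#'
#' @param config a \code{sim_config}.
#' @param covariate \code{covariate_series} covering the covariate-regime
#'   transition origins (ignored when the config has no covariate).
#' @param seed integer seed.
#' @return S x (T-1) matrix of log-growth increments, species in rows.
#' @export
simulate_growth_rates <- function(config, covariate, seed) {
  lay <- regime_layout(config, covariate)
  tr <- config$truth
  g_of <- match(config$group_map$group, config$groups)
  mu_t <- function(g) ifelse(lay$regime == 2L,
                             tr$alpha[g] + tr$beta[g] * lay$x,
                             tr$lambda_bar[g])
  set.seed(component_seed(seed, "growth"))
  lam <- matrix(NA_real_, config$S, config$n_years - 1,
                dimnames = list(config$species, NULL))
  for (s in seq_len(config$S)) {   # species-major: stable under added species
    g <- g_of[s]
    lam[s, ] <- stats::rnorm(config$n_years - 1, mu_t(g), tr$sigma_lambda[g])
  }
  lam
}

#' Deterministic latent log-abundance trajectories
#'
#' Accumulates the log-growth increments from the initial log-abundance:
#' n[s, t+1] = n[s, t] + lambda[s, t].
#'
#' @param config a \code{sim_config} (supplies the initial states).
#' @param growth_rates S x (T-1) matrix from \code{\link{simulate_growth_rates}}.
#' @return S x T matrix of latent log-abundances.
#' @export
simulate_latent_states <- function(config, growth_rates) {
  n <- cbind(config$truth$n1,
             config$truth$n1 + t(apply(growth_rates, 1, cumsum)))
  dimnames(n) <- list(config$species, config$years)
  n
}

# expand the era design into one row per sampling event
era_events <- function(config) {
  ev <- lapply(config$eras, function(e) {
    months <- sort(rep(8:6, length.out = e$events))
    expand.grid(year = e$years, site = e$sites, month = months,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  ev[order(ev$year, ev$site, ev$month), , drop = FALSE]
}

#' Simulate trawl counts from latent states
#'
#' Draws the observation layer of the model: a site effect per species-site
#' (normal, SD \code{sigma_site[s]}), an overdispersion term per event and
#' species (normal, SD \code{sigma_obs[s]}), and a Poisson count with mean
#' \code{exp(n[s,t] + site effect + overdispersion)}. Events whose Poisson
#' mean exceeds the configured cap are flagged (count set to NA with a
#' warning) rather than silently truncated.
#'
#' @param config a \code{sim_config}.
#' @param latent_states S x T latent log-abundance matrix.
#' @param seed integer seed.
#' @return Long-format survey data.frame (year, month, site, species, count,
#'   effort) with attribute \code{site_effects} (the drawn gamma matrix) and,
#'   if any event overflowed, a logical \code{flagged} column.
#' @export
simulate_observations <- function(config, latent_states, seed) {
  ev <- era_events(config)
  sites <- sort(unique(ev$site))
  set.seed(component_seed(seed, "sites"))
  gamma <- matrix(NA_real_, config$S, length(sites),
                  dimnames = list(config$species, sites))
  for (s in seq_len(config$S))
    gamma[s, ] <- stats::rnorm(length(sites), 0, config$truth$sigma_site[s])

  set.seed(component_seed(seed, "events"))
  rows <- vector("list", config$S)
  for (s in seq_len(config$S)) {
    t_idx <- match(ev$year, config$years)
    eps <- stats::rnorm(nrow(ev), 0, config$truth$sigma_obs[s])
    log_mu <- latent_states[s, t_idx] + gamma[s, ev$site] + eps
    over <- log_mu > log(config$count_cap)
    count <- rep(NA_integer_, nrow(ev))
    count[!over] <- stats::rpois(sum(!over), exp(log_mu[!over]))
    rows[[s]] <- data.frame(year = ev$year, month = ev$month, site = ev$site,
                            species = config$species[s], count = count,
                            effort = 1, flagged = over,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$site, out$month, out$species), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$flagged))
    warning(sum(out$flagged), " event(s) exceeded the count cap and were flagged")
  else out$flagged <- NULL
  attr(out, "site_effects") <- gamma
  out
}

#' Simulate a complete dataset from the generative model
#'
#' Orchestrates the covariate, growth-rate, latent-state and observation
#' components under independent RNG sub-streams of one integer seed, and
#' returns the observed tables together with the simulation truth for
#' parameter-recovery studies.
#'
#' @param config a \code{sim_config}.
#' @param seed single integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return list with \code{survey} (long-format counts), \code{covariate}
#'   (a \code{covariate_series}, or NULL), \code{truth} (true parameters,
#'   growth draws, latent states, site effects) and \code{config}.
#' @export
simulate_dataset <- function(config, seed) {
  covariate <- NULL
  if (!is.null(config$covariate_onset_year)) {
    T_cov <- config$start_year + config$n_years - 1 - config$covariate_onset_year
    covariate <- simulate_covariate(T_cov, seed,
                                    start_year = config$covariate_onset_year,
                                    trend = config$cov_trend)
  }
  growth <- simulate_growth_rates(config, covariate, seed)
  latent <- simulate_latent_states(config, growth)
  survey <- simulate_observations(config, latent, seed)
  list(survey = survey, covariate = covariate,
       truth = c(config$truth,
                 list(growth_rates = growth, latent_states = latent,
                      site_effects = attr(survey, "site_effects"))),
       config = config)
}
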
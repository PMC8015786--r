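test_that("read_survey parses rows, defaults effort, and validates", {
  gm <- lake_michigan_guilds()
  p <- write_temp_csv(data.frame(year = 1984, month = 6, site = "M",
                                 species = "ALE", count = 10, effort = 1.0))
  obs <- read_survey(p, gm)
  expect_equal(nrow(obs), 1)
  expect_identical(obs$count, 10L)
  expect_identical(obs$site, "M")

  # effort column absent -> default one trawl hour per event
  p2 <- write_temp_csv(data.frame(year = 1984, month = 6, site = "M",
                                  species = "ALE", count = 3))
  expect_equal(read_survey(p2, gm)$effort, 1)

  # empty data section -> empty result with a warning
  p3 <- write_temp_csv(data.frame(year = integer(), month = integer(),
                                  site = character(), species = character(),
                                  count = integer()))
  expect_warning(empty <- read_survey(p3, gm), "empty")
  expect_equal(nrow(empty), 0)

  # unknown species rejected by name
  p4 <- write_temp_csv(data.frame(year = 1984, month = 6, site = "M",
                                  species = "XYZ", count = 1))
  expect_error(read_survey(p4, gm), "XYZ")

  # missing required column named in the error
  p5 <- write_temp_csv(data.frame(year = 1984, month = 6, species = "ALE",
                                  count = 1))
  expect_error(read_survey(p5, gm), "site")

  # negative count reported with its row number
  p6 <- write_temp_csv(data.frame(year = 1984, month = c(6, 7), site = "M",
                                  species = "ALE", count = c(2, -1)))
  expect_error(read_survey(p6, gm), "row\\(s\\): 2")

  # configured study span enforced
  p7 <- write_temp_csv(data.frame(year = 1983, month = 6, site = "M",
                                  species = "ALE", count = 1))
  expect_error(read_survey(p7, gm, study_years = c(1984, 2016)), "1983")
})

test_that("read_covariate z-scores use the n-1 divisor and reject bad series", {
  p <- write_temp_csv(data.frame(year = c(2000, 2001), biomass = c(10, 30)))
  cov <- read_covariate(p)
  expect_equal(cov$z, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_equal(attr(cov, "center"), 20)
  expect_equal(attr(cov, "scale"), sd(c(10, 30)))

  # constant series: z-scores undefined
  pc <- write_temp_csv(data.frame(year = 2000:2002, biomass = rep(5, 3)))
  expect_error(read_covariate(pc), "degenerate")

  # gap in years
  pg <- write_temp_csv(data.frame(year = c(2000, 2002), biomass = c(1, 2)))
  expect_error(read_covariate(pg), "contiguous")

  # non-numeric biomass reported with row number
  pn <- write_temp_csv(data.frame(year = 2000:2001, biomass = c("1", "oops")))
  expect_error(read_covariate(pn), "row\\(s\\): 2")
})

test_that("covariate z-scores have mean 0 and unit sample SD", {
  set.seed(11)
  for (n in c(5, 19, 40)) {
    cov <- covariate_series(2000 + seq_len(n) - 1, rlnorm(n, 10, 0.4))
    expect_lt(abs(mean(cov$z)), 1e-10)
    expect_lt(abs(sd(cov$z) - 1), 1e-10)
  }
})

test_that("summarize_cpue pools sites and months into annual CPUE", {
  gm <- tiny_guilds()
  # species A1: annual CPUE 2, 4, 12 over three years of 1 h effort
  survey <- data.frame(year = rep(2000:2002, each = 1), month = 7L,
                       site = "M", species = "A1", count = c(2L, 4L, 12L),
                       effort = 1)
  s <- summarize_cpue(survey, gm)
  expect_equal(s$mean, 6)
  expect_equal(s$sd, sd(c(2, 4, 12)))
  expect_equal(s$q1, unname(quantile(c(2, 4, 12), 0.25)))  # type-7: 3
  expect_equal(s$q3, unname(quantile(c(2, 4, 12), 0.75)))  # type-7: 8
  expect_equal(s$max, 12)
  expect_equal(s$group, "benthic invertivore")

  # a species never captured: mean, sd and max all exactly 0
  survey0 <- data.frame(year = 2000:2002, month = 7L, site = "M",
                        species = "B1", count = 0L, effort = 1)
  s0 <- summarize_cpue(survey0, gm)
  expect_identical(c(s0$mean, s0$sd, s0$max), c(0, 0, 0))

  # identical counts and effort every year -> sd exactly 0
  sameyr <- data.frame(year = 2000:2004, month = 7L, site = "M",
                       species = "A2", count = 7L, effort = 1)
  expect_identical(summarize_cpue(sameyr, gm)$sd, 0)

  # a species-year with no rows is a zero catch over the year's full effort
  two <- rbind(
    data.frame(year = rep(2000:2001, each = 2), month = 7L,
               site = rep(c("M", "K"), 2), species = "A1",
               count = c(4L, 6L, 2L, 2L), effort = 1),
    data.frame(year = 2000, month = 7L, site = "M", species = "C1",
               count = 8L, effort = 1))
  s2 <- summarize_cpue(two, gm)
  # C1 in 2001: 0 fish over the 2 h sampled that year -> annual CPUE {4, 0}
  expect_equal(s2$mean[s2$species == "C1"], 2)
  expect_equal(s2$max[s2$species == "C1"], 4)
  # A1: {5, 2}
  expect_equal(s2$mean[s2$species == "A1"], 3.5)
})

test_that("build_model_inputs assigns regimes by transition origin year", {
  gm <- lake_michigan_guilds()
  # survey spanning 1984-2016 with a 1997-2015 covariate record
  survey <- data.frame(year = c(1984L, 2016L), month = 8L, site = "M",
                       species = "ALE", count = c(1L, 2L), effort = 1)
  set.seed(3)
  cov <- covariate_series(1997:2015, rlnorm(19, 10, 0.3))
  inp <- build_model_inputs(survey, cov, gm)
  expect_equal(inp$T, 33)
  expect_equal(sum(inp$regime == 1L), 13)  # origins 1984..1996
  expect_equal(sum(inp$regime == 2L), 19)  # origins 1997..2015
  expect_true(all(is.na(inp$x[inp$regime == 1L])))
  expect_false(anyNA(inp$x[inp$regime == 2L]))
  # regime-2 z-scores aligned to origin years
  expect_equal(inp$x[inp$regime == 2L], cov$z)

  # covariate extending past the last transition origin is rejected
  cov_long <- covariate_series(1997:2016, rlnorm(20, 10, 0.3))
  expect_error(build_model_inputs(survey, cov_long, gm), "beyond")

  # a transition origin after the covariate record end is unassignable
  cov_short <- covariate_series(1997:2010, rlnorm(14, 10, 0.3))
  expect_error(build_model_inputs(survey, cov_short, gm), "origin")
})

test_that("build_model_inputs indexes observations bijectively", {
  cfg <- tiny_sim_config()
  sim <- simulate_dataset(cfg, 5)
  inp <- build_model_inputs(sim$survey, sim$covariate, cfg$group_map)
  expect_equal(length(inp$y), nrow(sim$survey))
  # every row maps to an index tuple and back to its original fields
  expect_identical(inp$species[inp$species_idx], sim$survey$species)
  expect_identical(inp$years[inp$year_idx], sim$survey$year)
  expect_identical(inp$sites[inp$site_idx], sim$survey$site)
  expect_identical(inp$y, sim$survey$count)
  # indices are dense and in range
  expect_true(all(inp$species_idx %in% seq_len(inp$S)))
  expect_true(all(inp$year_idx %in% seq_len(inp$T)))
  expect_true(all(inp$site_idx %in% seq_len(inp$K)))
  # guilds partition the species set
  expect_equal(sort(unique(inp$species_group)), seq_len(inp$F))
})

test_that("sites added mid-series only index years they were sampled", {
  cfg <- sim_config(
    group_map = tiny_guilds(), start_year = 2000, n_years = 6,
    eras = list(list(years = 2000:2002, sites = c("M", "K"), events = 1L),
                list(years = 2003:2005, sites = c("M", "K", "G"), events = 1L)),
    covariate_onset_year = 2003,
    truth = list(n1 = rep(1, 5), sigma_obs = rep(0.3, 5),
                 sigma_site = rep(0.3, 5)))
  sim <- simulate_dataset(cfg, 9)
  inp <- build_model_inputs(sim$survey, sim$covariate, cfg$group_map)
  g_idx <- which(inp$sites == "G")
  yrs_G <- sort(unique(inp$years[inp$year_idx[inp$site_idx == g_idx]]))
  expect_equal(yrs_G, 2003:2005)
})
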
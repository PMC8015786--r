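#' Load a pipeline configuration
#'
#' A configuration is a YAML file (or an equivalent nested list) with blocks:
#' \code{data} (paths and column maps for a real survey + covariate) or
#' \code{simulation} (arguments for \code{\link{sim_config}}), \code{model}
#' (\code{lambda_structure}, \code{pool_sigma}), \code{mcmc} (\code{chains},
#' \code{iter}, \code{warmup}, \code{thin}) and \code{output} (\code{dir}).
#'
#' @param config path to a YAML file or a list.
#' @return The validated configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$data) && is.null(config$simulation))
    stop("config needs either a 'data' block or a 'simulation' block")
  config
}

sim_config_from_block <- function(block) {
  args <- block[intersect(names(block),
                          c("start_year", "n_years", "covariate_onset_year",
                            "cov_trend", "truth", "count_cap", "eras"))]
  if (!is.null(args$truth)) args$truth <- lapply(args$truth, unlist)
  if (!is.null(block$group_map)) {
    gm <- block$group_map
    if (is.character(gm)) gm <- utils::read.csv(gm, stringsAsFactors = FALSE)
    args$group_map <- as.data.frame(gm)
  }
  if (!is.null(args$eras))
    args$eras <- lapply(args$eras, function(e)
      list(years = unlist(e$years), sites = unlist(e$sites),
           events = e$events))
  do.call(sim_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes data loading (or forward simulation), model fitting, convergence
#' diagnostics and derived-quantity tables in sequence, writing every output
#' table plus a run manifest into the output directory. Any stage failure
#' aborts with the stage name after writing a manifest of the partial
#' outputs.
#'
#' @param config configuration list or YAML path (\code{\link{load_config}}).
#' @param seed integer seed for simulation and MCMC.
#' @param out_dir output directory; overrides the config's \code{output$dir}.
#' @param allow_unconverged if FALSE (default), a failed split R-hat check
#'   aborts the pipeline.
#' @param quiet suppress backend progress output.
#' @return The run manifest (invisibly), with the fit attached as
#'   attribute \code{"fit"}.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL,
                         allow_unconverged = FALSE, quiet = TRUE) {
  config <- load_config(config)
  if (is.null(out_dir)) out_dir <- config$output$dir
  if (is.null(out_dir)) stop("no output directory: set output$dir or out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- "configure"
  manifest_path <- file.path(out_dir, "manifest.json")
  fail <- function(e) {
    write_manifest(manifest_path, config, seed, outputs, partial = stage)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "data"
    if (!is.null(config$simulation)) {
      scfg <- sim_config_from_block(config$simulation)
      sim <- simulate_dataset(scfg, seed)
      survey <- sim$survey
      survey$flagged <- NULL
      covariate <- sim$covariate
      group_map <- scfg$group_map
      utils::write.csv(survey, file.path(out_dir, "survey.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(covariate)[c("year", "biomass")],
                       file.path(out_dir, "covariate.csv"), row.names = FALSE)
      outputs$survey <- file.path(out_dir, "survey.csv")
      outputs$covariate <- file.path(out_dir, "covariate.csv")
      truth_file <- file.path(out_dir, "truth.json")
      jsonlite::write_json(
        lapply(sim$truth, function(z) if (is.matrix(z)) as.data.frame(z) else z),
        truth_file, digits = NA)
      outputs$truth <- truth_file
    } else {
      d <- config$data
      group_map <- if (is.null(d$group_map)) lake_michigan_guilds()
        else if (is.character(d$group_map))
          utils::read.csv(d$group_map, stringsAsFactors = FALSE)
        else as.data.frame(d$group_map)
      survey <- do.call(read_survey, c(
        list(path = d$survey, group_map = group_map),
        d[intersect(names(d), c("columns", "default_effort", "study_years"))]))
      covariate <- if (is.null(d$covariate)) NULL else read_covariate(d$covariate)
    }
    cpue <- summarize_cpue(survey, group_map)
    utils::write.csv(cpue, file.path(out_dir, "cpue_summary.csv"),
                     row.names = FALSE)
    outputs$cpue <- file.path(out_dir, "cpue_summary.csv")
    inputs <- build_model_inputs(survey, covariate, group_map,
                                 study_years = config$data$study_years)

    stage <- "fit"
    mc <- utils::modifyList(list(chains = 3, iter = 5000, warmup = 2000,
                                 thin = 1),
                            if (is.null(config$mcmc)) list() else config$mcmc)
    mdl <- utils::modifyList(list(lambda_structure = "by_year",
                                  pool_sigma = FALSE),
                             if (is.null(config$model)) list() else config$model)
    fit <- fit_ssm(inputs, chains = mc$chains, iter = mc$iter,
                   warmup = mc$warmup, thin = mc$thin, seed = seed,
                   lambda_structure = mdl$lambda_structure,
                   pool_sigma = mdl$pool_sigma, quiet = quiet)

    stage <- "diagnostics"
    summ <- summarize_draws(fit)
    utils::write.csv(summ, file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    outputs$summary <- file.path(out_dir, "posterior_summary.csv")
    report <- check_convergence(summ)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "convergence.txt"))
    outputs$convergence <- file.path(out_dir, "convergence.txt")
    if (!report$pass && !allow_unconverged)
      stop("split R-hat >= ", report$threshold, " for ",
           nrow(report$failed), " parameter(s); rerun with longer chains ",
           "or allow_unconverged = TRUE")

    stage <- "results"
    outputs <- c(outputs, write_derived_tables(fit, out_dir))

    stage <- "manifest"
    manifest <- write_manifest(manifest_path, config, seed, outputs,
                               backend = fit$backend)
    attr(manifest, "fit") <- fit
    invisible(manifest)
  }, error = fail)
}

write_manifest <- function(path, config, seed, outputs, partial = NULL,
                           backend = NULL) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  inputs <- unlist(config$data[c("survey", "covariate")])
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else NULL
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    input_checksums = checksums,
    backend = backend,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    partial_failure_stage = partial,
    outputs = lapply(outputs, as.character))
  unlink(cfg_file)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  manifest
}

#' Simulate-fit-recover study
#'
#' Repeatedly simulates a dataset from known parameters, fits the model, and
#' records whether each group-level parameter's central credible interval
#' covers its true value, together with the posterior-median bias. This is
#' the standard calibration check for the hierarchical growth model: with a
#' correctly implemented model and sampler, nominal 95\% intervals should
#' cover the truth in roughly 95\% of replicates (somewhat less in small
#' studies).
#'
#' @param config configuration with a \code{simulation} block (truth values
#'   are taken from it) and an \code{mcmc} block for the per-replicate fits.
#' @param replicates number of simulate-fit cycles (>= 1).
#' @param seed integer seed; replicate r uses seed + 1009 * r.
#' @param prob credible-interval probability checked for coverage.
#' @param quiet suppress backend output.
#' @return list with \code{coverage} (per group-level parameter: coverage
#'   proportion and mean bias), \code{details} (per replicate and parameter)
#'   and \code{replicates}.
#' @export
run_recovery_study <- function(config, replicates, seed = 1, prob = 0.95,
                               quiet = TRUE) {
  if (is.null(replicates) || replicates < 1)
    stop("replicates must be >= 1")
  config <- load_config(config)
  if (is.null(config$simulation))
    stop("recovery study needs a simulation block with true parameters")
  scfg <- sim_config_from_block(config$simulation)
  mc <- utils::modifyList(list(chains = 3, iter = 1000, warmup = 500,
                               thin = 1),
                          if (is.null(config$mcmc)) list() else config$mcmc)
  has_cov <- !is.null(scfg$covariate_onset_year)
  par_names <- c("lambda_bar", "sigma_lambda", if (has_cov) c("alpha", "beta"))
  details <- list()
  for (r in seq_len(replicates)) {
    rseed <- as.integer(seed) + 1009L * r
    sim <- simulate_dataset(scfg, rseed)
    survey <- sim$survey
    survey$flagged <- NULL
    inputs <- build_model_inputs(survey, sim$covariate, scfg$group_map)
    fit <- fit_ssm(inputs, chains = mc$chains, iter = mc$iter,
                   warmup = mc$warmup, thin = mc$thin, seed = rseed,
                   quiet = quiet)
    summ <- summarize_draws(fit, prob = prob, parameters = par_names)
    for (nm in par_names) for (f in seq_len(scfg$F)) {
      flat <- sprintf("%s[%d]", nm, f)
      row <- summ[summ$parameter == flat, ]
      truth <- scfg$truth[[nm]][f]
      details[[length(details) + 1]] <- data.frame(
        replicate = r, parameter = flat, group = scfg$groups[f],
        truth = truth, median = row$median, lower = row$lower,
        upper = row$upper, rhat = row$rhat,
        covered = row$lower <= truth & truth <= row$upper,
        bias = row$median - truth, stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)
  coverage <- do.call(rbind, lapply(split(details, details$parameter),
                                    function(d) data.frame(
    parameter = d$parameter[1], group = d$group[1], truth = d$truth[1],
    coverage = mean(d$covered), mean_bias = mean(d$bias),
    stringsAsFactors = FALSE)))
  rownames(coverage) <- NULL
  list(coverage = coverage, details = details, replicates = replicates)
}
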
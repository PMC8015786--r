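#' Functional feeding guild classification for the southern Lake Michigan survey
#'
#' The ten-species roster of the near-shore trawl survey with each species'
#' functional feeding guild: four benthic invertivores, three general
#' invertivores and three planktivores. Species codes are the conventional
#' three-letter abbreviations used throughout the package.
#'
#' @return A data.frame with columns \code{species} (code), \code{common_name}
#'   and \code{group} (one of \code{"benthic invertivore"},
#'   \code{"general invertivore"}, \code{"planktivore"}).
#' @export
lake_michigan_guilds <- function() {
  data.frame(
    species = c("WHS", "LOS", "JOD", "ROG", "YEP", "SPS", "TRP",
                "RAS", "BLO", "ALE"),
    common_name = c("White Sucker", "Longnose Sucker", "Johnny Darter",
                    "Round Goby", "Yellow Perch", "Spottail Shiner",
                    "Troutperch", "Rainbow Smelt", "Bloater", "Alewife"),
    group = c(rep("benthic invertivore", 4),
              rep("general invertivore", 3),
              rep("planktivore", 3)),
    stringsAsFactors = FALSE
  )
}

#' Validate a species-to-guild map
#'
#' @param group_map data.frame with columns \code{species} and \code{group}.
#' @return The map, invisibly, after validation.
#' @keywords internal
validate_group_map <- function(group_map) {
  if (!is.data.frame(group_map) || !all(c("species", "group") %in% names(group_map)))
    stop("group_map must be a data.frame with columns 'species' and 'group'")
  if (anyDuplicated(group_map$species))
    stop("group_map assigns some species to more than one guild: ",
         paste(unique(group_map$species[duplicated(group_map$species)]), collapse = ", "))
  invisible(group_map)
}

#' Read a long-format trawl survey table
#'
#' Reads a delimited file with one row per sampling event and species, carrying
#' the calendar year, month, site code, species code, fish count and trawl
#' effort in hours. Column names are configurable; the effort column is
#' optional and defaults to one hour per event, the survey's fixed tow length.
#'
#' @param path path to a CSV/TSV file (delimiter inferred from the extension,
#'   or set via \code{sep}).
#' @param group_map species-to-guild map; rows whose species code is absent
#'   from the map are rejected with an error naming the unknown codes.
#' @param columns named list mapping the roles \code{year}, \code{month},
#'   \code{site}, \code{species}, \code{count} and (optionally) \code{effort}
#'   to column names in the file.
#' @param default_effort effort in hours substituted when no effort column is
#'   present (default 1, one hour of trawling per event).
#' @param study_years optional length-2 integer vector; rows outside the span
#'   raise an error.
#' @param sep field separator; \code{NULL} infers "," or tab from the filename.
#' @return A data.frame of validated observations with columns
#'   \code{year}, \code{month}, \code{site}, \code{species}, \code{count},
#'   \code{effort}.
#' @export
read_survey <- function(path, group_map = lake_michigan_guilds(),
                        columns = list(year = "year", month = "month",
                                       site = "site", species = "species",
                                       count = "count", effort = "effort"),
                        default_effort = 1, study_years = NULL, sep = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  validate_group_map(group_map)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("year", "month", "site", "species", "count")
  for (role in required) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("survey file is missing required column '", columns[[role]],
           "' (role: ", role, ")")
  }
  if (nrow(raw) == 0) {
    warning("survey file has an empty data section")
    return(data.frame(year = integer(), month = integer(), site = character(),
                      species = character(), count = integer(),
                      effort = numeric(), stringsAsFactors = FALSE))
  }
  eff_col <- columns[["effort"]]
  effort <- if (!is.null(eff_col) && eff_col %in% names(raw))
    as.numeric(raw[[eff_col]]) else rep(default_effort, nrow(raw))
  obs <- data.frame(
    year = as.integer(raw[[columns$year]]),
    month = as.integer(raw[[columns$month]]),
    site = as.character(raw[[columns$site]]),
    species = as.character(raw[[columns$species]]),
    count = suppressWarnings(as.numeric(raw[[columns$count]])),
    effort = effort,
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(obs$count) | obs$count < 0 | obs$count != round(obs$count))
  if (length(bad))
    stop("invalid count (must be a non-negative integer) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  obs$count <- as.integer(obs$count)
  if (any(is.na(obs$effort) | obs$effort <= 0))
    stop("effort must be > 0 hours at row(s): ",
         paste(utils::head(which(is.na(obs$effort) | obs$effort <= 0), 5), collapse = ", "))
  if (any(is.na(obs$month) | obs$month < 1 | obs$month > 12))
    stop("month out of range 1-12 at row(s): ",
         paste(utils::head(which(is.na(obs$month) | obs$month < 1 | obs$month > 12), 5),
               collapse = ", "))
  unknown <- setdiff(unique(obs$species), group_map$species)
  if (length(unknown))
    stop("species not present in the guild map: ", paste(unknown, collapse = ", "))
  if (!is.null(study_years)) {
    out <- obs$year < study_years[1] | obs$year > study_years[2]
    if (any(out))
      stop("survey year(s) outside the configured study span ",
           study_years[1], "-", study_years[2], ": ",
           paste(unique(obs$year[out]), collapse = ", "))
  }
  obs
}

#' Read an annual covariate series (zooplankton biomass)
#'
#' Reads a year-by-biomass table (total zooplankton dry-weight biomass in
#' ug DW/m^3), checks that the years form a contiguous block, and attaches
#' z-scores computed with the sample standard deviation (divisor n - 1).
#'
#' @param path path to a CSV/TSV file.
#' @param columns named list mapping the roles \code{year} and \code{biomass}
#'   to column names.
#' @param sep field separator; \code{NULL} infers from the filename.
#' @return A \code{covariate_series}: data.frame with columns \code{year},
#'   \code{biomass}, \code{z}, plus attributes \code{center} (mean biomass)
#'   and \code{scale} (sample SD) for back-transformation.
#' @export
read_covariate <- function(path,
                           columns = list(year = "year", biomass = "biomass"),
                           sep = NULL) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("year", "biomass")) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("covariate file is missing required column '", columns[[role]],
           "' (role: ", role, ")")
  }
  year <- as.integer(raw[[columns$year]])
  biomass <- suppressWarnings(as.numeric(raw[[columns$biomass]]))
  if (any(is.na(biomass)))
    stop("non-numeric biomass at row(s): ",
         paste(utils::head(which(is.na(biomass)), 5), collapse = ", "))
  if (any(biomass < 0)) stop("biomass must be >= 0")
  ord <- order(year)
  year <- year[ord]; biomass <- biomass[ord]
  covariate_series(year, biomass)
}

#' Construct a covariate series from year and biomass vectors
#'
#' @param year contiguous integer years.
#' @param biomass non-negative annual totals, same length as \code{year}.
#' @return A \code{covariate_series} data.frame (see \code{\link{read_covariate}}).
#' @export
covariate_series <- function(year, biomass) {
  if (length(year) != length(biomass)) stop("year and biomass lengths differ")
  if (length(year) < 2) stop("a covariate series needs at least 2 years")
  if (!all(diff(year) == 1L))
    stop("covariate years must form a contiguous block; gap after ",
         paste(year[which(diff(year) != 1L)], collapse = ", "))
  m <- mean(biomass)
  s <- stats::sd(biomass)  # divisor n - 1
  if (s == 0)
    stop("degenerate covariate series: zero variance, z-scores undefined")
  out <- data.frame(year = as.integer(year), biomass = biomass,
                    z = (biomass - m) / s)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  class(out) <- c("covariate_series", "data.frame")
  out
}

#' Per-species annual catch-per-unit-effort summaries
#'
#' Computes, for each species, the annual CPUE (total catch across all sites
#' and months in a year divided by the year's total trawl hours) over every
#' sampled year, then summarizes the annual values by mean, sample SD, first
#' and third quartile (linear interpolation of order statistics) and maximum.
#' A species-year with no rows is a zero catch over the year's effort, not
#' missing data. The annual effort for a year is the largest per-species
#' effort total observed in that year, so incomplete long tables (positive
#' catches only) still divide by the full sampling effort.
#'
#' @param observations validated survey data.frame from \code{\link{read_survey}}.
#' @param group_map species-to-guild map used to label the output.
#' @return data.frame with columns \code{species}, \code{group}, \code{mean},
#'   \code{sd}, \code{q1}, \code{q3}, \code{max}, one row per observed species.
#' @export
summarize_cpue <- function(observations, group_map = lake_michigan_guilds()) {
  if (nrow(observations) == 0) stop("no observations to summarize")
  validate_group_map(group_map)
  years <- sort(unique(observations$year))
  species <- intersect(group_map$species, unique(observations$species))
  dropped <- setdiff(unique(observations$species), species)
  if (length(dropped))
    warning("species without guild labels excluded: ", paste(dropped, collapse = ", "))
  # per species-year totals
  eff_by <- tapply(observations$effort,
                   list(observations$species, observations$year), sum)
  cnt_by <- tapply(observations$count,
                   list(observations$species, observations$year), sum)
  year_effort <- apply(eff_by, 2, max, na.rm = TRUE)[as.character(years)]
  rows <- lapply(species, function(sp) {
    cnt <- cnt_by[sp, as.character(years)]
    cnt[is.na(cnt)] <- 0
    cpue <- cnt / year_effort
    q <- stats::quantile(cpue, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(species = sp,
               group = group_map$group[match(sp, group_map$species)],
               mean = mean(cpue), sd = stats::sd(cpue),
               q1 = q[1], q3 = q[2], max = max(cpue),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble flat index arrays for the state-space model
#'
#' Converts validated survey observations, the covariate series and the guild
#' map into the dense integer index arrays the model consumes, and assigns
#' each year-to-year transition to a growth regime: transitions originating
#' in years before the covariate record use the guild mean growth rate
#' (regime 1); transitions originating within the covariate record use the
#' covariate regression mean (regime 2).
#'
#' @param observations survey data.frame (\code{\link{read_survey}}).
#' @param covariate \code{covariate_series} or \code{NULL} for a
#'   single-regime model with no covariate.
#' @param group_map species-to-guild map.
#' @param study_years length-2 integer vector giving the survey span; default
#'   is the observed range.
#' @return A \code{model_inputs} list: observation vectors \code{y},
#'   \code{species_idx}, \code{year_idx}, \code{site_idx}, \code{effort};
#'   dimensions \code{S}, \code{F}, \code{T}, \code{K}; rosters
#'   \code{species}, \code{groups}, \code{sites}, \code{years};
#'   \code{species_group} (guild index per species); per-transition
#'   \code{regime} (length T - 1) and covariate z-score \code{x} (NA where
#'   regime 1); and the \code{covariate} series itself.
#' @export
build_model_inputs <- function(observations, covariate, group_map,
                               study_years = NULL) {
  validate_group_map(group_map)
  if (nrow(observations) == 0) stop("no observations")
  if (is.null(study_years)) study_years <- range(observations$year)
  if (any(observations$year < study_years[1] | observations$year > study_years[2]))
    stop("survey year outside the configured study span")
  years <- seq.int(study_years[1], study_years[2])
  T_ <- length(years)
  if (T_ < 2) stop("need at least two study years")
  species <- group_map$species[group_map$species %in% unique(observations$species)]
  unknown <- setdiff(unique(observations$species), species)
  if (length(unknown))
    stop("species not present in the guild map: ", paste(unknown, collapse = ", "))
  groups <- unique(group_map$group[match(species, group_map$species)])
  species_group <- match(group_map$group[match(species, group_map$species)], groups)
  sites <- sort(unique(observations$site))

  regime <- rep(1L, T_ - 1)
  x <- rep(NA_real_, T_ - 1)
  if (!is.null(covariate)) {
    if (!inherits(covariate, "covariate_series"))
      stop("covariate must be a covariate_series")
    if (max(covariate$year) > max(years) - 1)
      stop("covariate years extend beyond the last year-transition of the survey span")
    if (min(covariate$year) < min(years))
      stop("covariate starts before the survey span")
    origin <- years[seq_len(T_ - 1)]        # transition t originates at years[t]
    in_cov <- origin %in% covariate$year
    after <- origin > max(covariate$year)
    if (any(after))
      stop("transition origin year(s) after the covariate record end: ",
           paste(origin[after], collapse = ", "),
           "; the covariate must cover every transition from its onset onward")
    regime[in_cov] <- 2L
    x[in_cov] <- covariate$z[match(origin[in_cov], covariate$year)]
  }

  out <- list(
    y = observations$count,
    species_idx = match(observations$species, species),
    year_idx = match(observations$year, years),
    site_idx = match(observations$site, sites),
    effort = observations$effort,
    S = length(species), F = length(groups), T = T_, K = length(sites),
    species = species, groups = groups, sites = sites, years = years,
    species_group = species_group,
    regime = regime, x = x,
    covariate = covariate
  )
  class(out) <- "model_inputs"
  out
}

#' @export
print.model_inputs <- function(x, ...) {
  cat("Model inputs:", length(x$y), "observations;",
      x$S, "species in", x$F, "guilds;",
      x$T, "years (", min(x$years), "-", max(x$years), ");",
      x$K, "sites\n")
  cat("Regimes:", sum(x$regime == 1), "guild-mean transitions,",
      sum(x$regime == 2), "covariate-linked transitions\n")
  invisible(x)
}
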
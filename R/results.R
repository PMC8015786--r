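# pooled draw vector for one flattened parameter name
pooled_draws <- function(fit, parameter) as.vector(draw_matrix(fit, parameter))

cri_row <- function(v, prob) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  c(median = stats::median(v),
    lower = stats::quantile(v, qs[1], names = FALSE, type = 7),
    upper = stats::quantile(v, qs[2], names = FALSE, type = 7))
}

#' Species-by-year posterior growth-rate trajectories
#'
#' Posterior median and central credible interval of the species-year
#' log-growth draws, one row per species and year-transition (labelled by
#' the transition's origin year). Summaries are computed from the raw draws
#' per cell, never from summaries of summaries.
#'
#' @param fit a \code{guild_fit}.
#' @param prob central interval probability.
#' @return data.frame with columns \code{species}, \code{group}, \code{year},
#'   \code{median}, \code{lower}, \code{upper}.
#' @export
species_growth_trajectories <- function(fit, prob = 0.95) {
  inp <- fit$inputs
  rows <- list()
  for (s in seq_len(inp$S)) for (t in seq_len(inp$T - 1)) {
    v <- pooled_draws(fit, sprintf("lambda[%d,%d]", s, t))
    rows[[length(rows) + 1]] <- data.frame(
      species = inp$species[s],
      group = inp$groups[inp$species_group[s]],
      year = inp$years[t],
      t(cri_row(v, prob)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Guild-level process standard deviations
#'
#' Posterior median and credible interval of the growth-rate SD of each
#' functional feeding guild — the process-error summary that contrasts how
#' variable the guilds' annual growth rates are.
#'
#' @inheritParams species_growth_trajectories
#' @return data.frame with columns \code{group}, \code{median}, \code{lower},
#'   \code{upper}.
#' @export
group_process_sd <- function(fit, prob = 0.95) {
  inp <- fit$inputs
  rows <- lapply(seq_len(inp$F), function(f)
    data.frame(group = inp$groups[f],
               t(cri_row(pooled_draws(fit, sprintf("sigma_lambda[%d]", f)),
                         prob)),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Guild mean growth rate by regime
#'
#' Regime 1 (years before the covariate record) summarizes the guild mean
#' growth rate; regime 2 (covariate years) summarizes the expected growth
#' rate at mean covariate biomass, which is the regression intercept since
#' the covariate is z-scored (the mean has z-score 0, so the slope drops
#' out exactly).
#'
#' @inheritParams species_growth_trajectories
#' @return data.frame with columns \code{group}, \code{regime},
#'   \code{median}, \code{lower}, \code{upper}.
#' @export
regime_mean_growth <- function(fit, prob = 0.95) {
  inp <- fit$inputs
  has_cov <- any(inp$regime == 2L)
  rows <- list()
  for (f in seq_len(inp$F)) {
    rows[[length(rows) + 1]] <- data.frame(
      group = inp$groups[f], regime = 1L,
      t(cri_row(pooled_draws(fit, sprintf("lambda_bar[%d]", f)), prob)),
      stringsAsFactors = FALSE)
    if (has_cov)
      rows[[length(rows) + 1]] <- data.frame(
        group = inp$groups[f], regime = 2L,
        t(cri_row(pooled_draws(fit, sprintf("alpha[%d]", f)) +
                    pooled_draws(fit, sprintf("beta[%d]", f)) * 0, prob)),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior growth rate as a function of the covariate
#'
#' Evaluates the regime-2 regression \code{alpha + beta * x} per draw over a
#' grid of covariate z-scores and summarizes per guild and grid point, and
#' returns the per-guild slope summary alongside. Grid points are reported
#' both as z-scores and back-transformed to the covariate's original units
#' when the fit carries the covariate series.
#'
#' @inheritParams species_growth_trajectories
#' @param grid covariate z-score values; default 50 evenly spaced points
#'   spanning the observed z-score range.
#' @param n_grid grid size when \code{grid} is NULL.
#' @return list with \code{curves} (columns \code{group}, \code{z},
#'   \code{biomass}, \code{median}, \code{lower}, \code{upper}) and
#'   \code{slopes} (columns \code{group}, \code{median}, \code{lower},
#'   \code{upper}).
#' @export
growth_vs_covariate_curve <- function(fit, grid = NULL, n_grid = 50,
                                      prob = 0.95) {
  inp <- fit$inputs
  if (!any(inp$regime == 2L))
    stop("the fit has no covariate regime; no growth-covariate curve exists")
  if (is.null(grid)) {
    zr <- range(inp$x[inp$regime == 2L])
    grid <- seq(zr[1], zr[2], length.out = n_grid)
  }
  center <- if (!is.null(inp$covariate)) attr(inp$covariate, "center") else NA
  scale <- if (!is.null(inp$covariate)) attr(inp$covariate, "scale") else NA
  curves <- list(); slopes <- list()
  for (f in seq_len(inp$F)) {
    a <- pooled_draws(fit, sprintf("alpha[%d]", f))
    b <- pooled_draws(fit, sprintf("beta[%d]", f))
    for (x in grid)
      curves[[length(curves) + 1]] <- data.frame(
        group = inp$groups[f], z = x, biomass = x * scale + center,
        t(cri_row(a + b * x, prob)), stringsAsFactors = FALSE)
    slopes[[length(slopes) + 1]] <- data.frame(
      group = inp$groups[f], t(cri_row(b, prob)), stringsAsFactors = FALSE)
  }
  curves <- do.call(rbind, curves); rownames(curves) <- NULL
  slopes <- do.call(rbind, slopes); rownames(slopes) <- NULL
  list(curves = curves, slopes = slopes)
}

#' Write every derived-quantity table of a fit as CSV
#'
#' @param fit a \code{guild_fit}.
#' @param dir output directory (created if missing).
#' @param prob central interval probability.
#' @return Invisibly, the named list of written file paths.
#' @export
write_derived_tables <- function(fit, dir, prob = 0.95) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  has_cov <- any(fit$inputs$regime == 2L)
  tables <- list(
    fig5_trajectories = species_growth_trajectories(fit, prob),
    fig6_process_sd = group_process_sd(fit, prob),
    fig7_regime_means = regime_mean_growth(fit, prob))
  if (has_cov) {
    gc <- growth_vs_covariate_curve(fit, prob = prob)
    tables$fig8_curves <- gc$curves
    tables$fig8_slopes <- gc$slopes
  }
  paths <- lapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  })
  names(paths) <- names(tables)
  invisible(paths)
}
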
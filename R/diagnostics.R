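#' Split potential-scale-reduction statistic (split R-hat)
#'
#' Each chain is split into halves and the classic potential-scale-reduction
#' statistic is computed over the resulting half-chains:
#' \code{Rhat = sqrt(((N - 1)/N * W + B/N) / W)}, with \code{W} the mean
#' within-half-chain variance and \code{B} the between-half-chain variance of
#' the half-chain means times the half-chain length \code{N}. Splitting makes
#' the statistic sensitive to trends within a single chain, not only to
#' disagreement between chains. Values near 1 indicate convergence; the
#' conventional threshold is 1.1.
#'
#' @param x iterations x chains matrix of post-warmup draws (>= 2 chains,
#'   >= 4 draws per chain), or a vector interpreted as a single chain.
#' @param rank_normalize if TRUE, draws are replaced by normal scores of
#'   their pooled ranks before the computation (a robust variant); the
#'   default is the classic statistic.
#' @return Scalar R-hat. Draws that are all identical return exactly 1 with
#'   a degenerate-variance warning.
#' @export
split_rhat <- function(x, rank_normalize = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 draws per chain to split")
  if (ncol(x) < 2 && n < 8)
    stop("need at least 2 chains (or enough draws to split one)")
  if (rank_normalize) {
    r <- rank(x, ties.method = "average")
    x <- matrix(stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4)),
                nrow = n, ncol = ncol(x))
  }
  N <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(N), j], x[seq.int(n - N + 1, n), j])))
  if (all(halves == halves[1])) {
    warning("all draws identical: zero variance, split R-hat defined as 1")
    return(1)
  }
  W <- mean(apply(halves, 2, stats::var))
  B <- N * stats::var(colMeans(halves))
  if (W == 0) {
    warning("zero within-chain variance, split R-hat undefined; returning Inf")
    return(Inf)
  }
  sqrt(((N - 1) / N * W + B / N) / W)
}

#' Posterior summary table
#'
#' Per-parameter posterior median, equal-tailed central credible interval
#' (quantiles pooled across chains, linear interpolation of order statistics)
#' and split R-hat.
#'
#' @param fit a \code{guild_fit} or an (iterations, chains, parameters)
#'   draw array.
#' @param prob central interval probability (default 0.95).
#' @param parameters optional character vector restricting the summary, by
#'   exact flattened name or by base name (e.g. \code{"beta"} selects every
#'   \code{beta[f]}).
#' @return data.frame with columns \code{parameter}, \code{median},
#'   \code{lower}, \code{upper}, \code{rhat}.
#' @export
summarize_draws <- function(fit, prob = 0.95, parameters = NULL) {
  a <- if (is.array(fit)) fit else fit$draws
  if (length(a) == 0 || dim(a)[1] == 0) stop("no draws to summarize")
  pars <- dimnames(a)[[3]]
  if (!is.null(parameters)) {
    base <- sub("\\[.*", "", pars)
    keep <- pars %in% parameters | base %in% parameters
    if (!any(keep)) stop("no monitored parameters match the selection")
    pars <- pars[keep]
  }
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  rows <- lapply(pars, function(p) {
    m <- a[, , p, drop = FALSE]
    dim(m) <- dim(a)[1:2]
    v <- as.vector(m)
    rh <- suppressWarnings(split_rhat(m))
    data.frame(parameter = p, median = stats::median(v),
               lower = stats::quantile(v, qs[1], names = FALSE, type = 7),
               upper = stats::quantile(v, qs[2], names = FALSE, type = 7),
               rhat = rh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convergence check against an R-hat threshold
#'
#' @param rows summary table from \code{\link{summarize_draws}}.
#' @param threshold R-hat threshold; the conventional value 1.1.
#' @return A \code{convergence_report}: list with \code{pass} (logical),
#'   \code{threshold} and \code{failed} (parameters at or above the
#'   threshold, with their R-hat).
#' @export
check_convergence <- function(rows, threshold = 1.1) {
  if (nrow(rows) == 0) stop("empty summary table")
  bad <- rows[!is.na(rows$rhat) & rows$rhat >= threshold,
              c("parameter", "rhat")]
  structure(list(pass = nrow(bad) == 0, threshold = threshold, failed = bad),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  if (x$pass) {
    cat("Converged: all split R-hat <", x$threshold, "\n")
  } else {
    cat("NOT converged: split R-hat >=", x$threshold, "for",
        nrow(x$failed), "parameter(s):\n")
    print(utils::head(x$failed[order(-x$failed$rhat), ], 10),
          row.names = FALSE)
  }
  invisible(x)
}
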
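#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from two or more parallel chains of equal
#' length: with `W` the mean within-chain variance and `B/n` the variance
#' of the chain means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.
#'
#' @param chains A list of numeric matrices (iterations x parameters) or
#'   vectors, one per chain, all of equal length.
#' @param split Use split chains (each chain halved) instead of the
#'   classic estimator (default `FALSE`, matching the three-parallel-chain
#'   protocol).
#' @return A named numeric vector of R-hat values, one per parameter, with
#'   attribute `flagged` naming parameters exceeding 1.1.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (!is.list(chains)) stop("chains must be a list, one element per chain")
  chains <- lapply(chains, function(x) {
    x <- if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
    x
  })
  if (length(chains) < 2L) stop("need at least 2 chains")
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("chains must have equal lengths")
  if (lens[1L] < 2L) stop("need at least 2 draws per chain")
  if (split) {
    half <- lens[1L] %/% 2L
    chains <- unlist(lapply(chains, function(x) {
      list(x[seq_len(half), , drop = FALSE],
           x[(nrow(x) - half + 1L):nrow(x), , drop = FALSE])
    }), recursive = FALSE)
  }
  m <- length(chains)
  n <- nrow(chains[[1L]])
  means <- do.call(rbind, lapply(chains, colMeans))
  vars <- do.call(rbind, lapply(chains, function(x) apply(x, 2L, stats::var)))
  W <- colMeans(vars)
  if (any(W == 0)) stop("degenerate chain: zero within-chain variance")
  B_over_n <- apply(means, 2L, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  nm <- colnames(chains[[1L]])
  if (is.null(nm)) nm <- paste0("param_", seq_along(rhat))
  names(rhat) <- nm
  attr(rhat, "flagged") <- nm[rhat > 1.1]
  rhat
}

# Spectral density at frequency zero by a Bartlett lag-window estimate on
# the first 10% of the autocovariances. Demeaning biases every sample
# autocovariance by about -gamma0/n, which accumulates over the window;
# the multiplicative correction restores calibration of the z-scores.
spectrum0 <- function(x) {
  n <- length(x)
  K <- max(1L, floor(0.1 * n))
  ac <- stats::acf(x, lag.max = K, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  w <- 1 - seq_len(K) / (K + 1)
  s <- ac[1L] + 2 * sum(w * ac[-1L])
  s / max(1e-12, 1 - (1 + 2 * sum(w)) / n)
}

#' Geweke convergence diagnostic
#'
#' z-score for equality of the means of an early and a late window of a
#' single chain, `z = (m1 - m2) / sqrt(s1/n1 + s2/n2)` with `s` the
#' spectral density at zero of each window (Bartlett lag-window estimate
#' on 10% of the window autocovariances). Defaults compare the first 10%
#' with the last 50%; |z| > 1.96 flags a lack of convergence.
#'
#' @param chain Numeric vector or matrix (iterations x parameters).
#' @param frac_first Fraction of the chain in the early window (default
#'   0.1).
#' @param frac_last Fraction in the late window (default 0.5).
#' @return Named numeric vector of z-scores with attribute `flagged`.
#' @export
geweke <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  x <- if (is.null(dim(chain))) matrix(chain, ncol = 1L) else
    as.matrix(chain)
  n <- nrow(x)
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  if (n1 < 10L || n2 < 10L) stop("chain too short for the requested windows")
  z <- vapply(seq_len(ncol(x)), function(j) {
    x1 <- x[seq_len(n1), j]
    x2 <- x[(n - n2 + 1L):n, j]
    if (stats::var(x1) == 0 || stats::var(x2) == 0) {
      stop("zero variance in a Geweke window")
    }
    (mean(x1) - mean(x2)) / sqrt(spectrum0(x1) / n1 + spectrum0(x2) / n2)
  }, numeric(1))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("param_", seq_len(ncol(x)))
  names(z) <- nm
  attr(z, "flagged") <- nm[abs(z) > 1.96]
  z
}

#' Sampler-health summary for a NUTS run
#'
#' Divergence count and fraction, mean and maximum leapfrog steps and tree
#' depths, and the fraction of iterations hitting the leapfrog or
#' tree-depth limits.
#'
#' @param x A `chain_result`, an `mtvc_fit` from [fit_nuts()], or a data
#'   frame of per-draw sampler statistics.
#' @param max_leapfrog,max_tree_depth Limits used for the
#'   "fraction-at-limit" statistics (defaults 1000 and 10).
#' @return A named list of summary statistics.
#' @export
sampler_report <- function(x, max_leapfrog = 1000L, max_tree_depth = 10L) {
  st <- if (is.data.frame(x)) x else x$stats
  if (is.null(st)) stop("no sampler statistics available")
  if (inherits(x, "chain_result") || inherits(x, "nuts_fit")) {
    cfg <- x$config
    if (!is.null(cfg)) {
      max_leapfrog <- cfg$max_leapfrog
      max_tree_depth <- cfg$max_tree_depth
    }
  }
  list(n_draws = nrow(st),
       n_divergent = sum(st$divergent),
       divergence_fraction = mean(st$divergent),
       mean_leapfrog = mean(st$n_leapfrog),
       max_leapfrog = max(st$n_leapfrog),
       mean_tree_depth = mean(st$tree_depth),
       max_tree_depth = max(st$tree_depth),
       frac_at_leapfrog_limit = mean(st$n_leapfrog >= max_leapfrog),
       frac_at_depth_limit = mean(st$tree_depth >= max_tree_depth),
       mean_accept_stat = mean(st$accept_stat))
}

#' Write a diagnostics report as flat JSON
#'
#' @param report A named list (e.g. from [sampler_report()], possibly
#'   augmented with R-hat and Geweke values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
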
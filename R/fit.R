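#' Fit the multi-trait animal model by NUTS
#'
#' Builds the non-centered log-posterior for the chosen prior family and
#' runs one or more NUTS chains. Post-warm-up draws of the covariance
#' matrices, intercepts and the posterior mean of the breeding values are
#' extracted from the unconstrained positions.
#'
#' @param y n x t complete phenotype matrix.
#' @param A Relationship matrix, `relationship_matrix` or `grm_eigen()`
#'   structure.
#' @param prior A [prior_config()] (`"lkj"` default, or `"iw"`).
#' @param cfg A [nuts_config()].
#' @param chains Number of chains (seeds `cfg$seed`, `cfg$seed + 1`, ...).
#' @return An `mtvc_fit` object: arrays `G0`, `R0` (t x t x draws, chains
#'   concatenated), matrix `mu`, `a_hat` (posterior-mean breeding values),
#'   `stats` (per-draw sampler statistics with a `chain` column),
#'   `per_chain` (list of per-parameter draw matrices for multi-chain
#'   diagnostics), `step_size`, and the configurations.
#' @export
fit_nuts <- function(y, A, prior = prior_config("lkj"), cfg = nuts_config(),
                     chains = 1L) {
  y <- as.matrix(y)
  if (inherits(A, "relationship_matrix")) A <- A$A
  eig_or_mat <- A
  dat <- model_data(y, eig_or_mat)
  n <- dat$n; t <- dat$t
  prior <- resolve_prior(prior, t)
  ld <- animal_model_logdensity(dat, prior)
  sl <- param_slices(n, t)
  n_keep <- cfg$n_iter - cfg$n_warmup

  all_G <- array(NA_real_, c(t, t, n_keep * chains))
  all_R <- array(NA_real_, c(t, t, n_keep * chains))
  all_mu <- matrix(NA_real_, n_keep * chains, t)
  stats_list <- vector("list", chains)
  per_chain <- vector("list", chains)
  a_sum <- matrix(0, n, t)
  step_sizes <- numeric(chains)

  for (ch in seq_len(chains)) {
    rng <- local_rng(cfg$seed + 7919L * (ch - 1L))
    init <- init_position(n, t, jitter_sd = if (ch == 1L) 0.1 else 0.5)
    rng$restore()
    ccfg <- cfg
    ccfg$seed <- cfg$seed + 1000L * (ch - 1L)
    res <- sample_chain(ld, init, ccfg)
    idx <- (ch - 1L) * n_keep + seq_len(n_keep)
    pc <- matrix(NA_real_, n_keep, t * (t + 1) + t)
    for (k in seq_len(n_keep)) {
      u <- res$draws[k, ]
      p <- constrain_draw(u, sl, n, t)
      j <- idx[k]
      all_G[, , j] <- p$G0
      all_R[, , j] <- p$R0
      all_mu[j, ] <- p$mu
      # a = U (sqrt(d) * z) Ba' in the eigen frame; U applied once at the end
      a_sum <- a_sum + (dat$sqrt_d * p$z_a) %*% t(p$B_a)
      pc[k, ] <- c(p$G0[lower.tri(p$G0, diag = TRUE)],
                   p$R0[lower.tri(p$R0, diag = TRUE)], p$mu)
    }
    colnames(pc) <- c(cov_labels(t, "G"), cov_labels(t, "R"),
                      paste0("mu_", seq_len(t)))
    per_chain[[ch]] <- pc
    st <- res$stats
    st$chain <- ch
    stats_list[[ch]] <- st
    step_sizes[ch] <- res$step_size
  }
  structure(list(G0 = all_G, R0 = all_R, mu = all_mu,
                 a_hat = dat$U %*% (a_sum / (n_keep * chains)),
                 n_kept = n_keep * chains,
                 stats = do.call(rbind, stats_list), per_chain = per_chain,
                 step_size = step_sizes, config = cfg, prior = prior,
                 jitter = dat$jitter,
                 method = paste0("nuts-", prior$kind)),
            class = c("nuts_fit", "mtvc_fit"))
}

# Lightweight constrained extraction used per kept draw.
constrain_draw <- function(u, sl, n, t) {
  z_a <- matrix(u[sl$z_a], n, t)
  sa <- exp(u[sl$log_sd_a]); se <- exp(u[sl$log_sd_e])
  La <- corr_chol_forward(u[sl$u_corr_a], t)$L
  Le <- corr_chol_forward(u[sl$u_corr_e], t)$L
  Ba <- La * sa; Be <- Le * se
  list(z_a = z_a, B_a = Ba, G0 = tcrossprod(Ba), R0 = tcrossprod(Be),
       mu = u[sl$mu])
}

# Lower-triangle (column-major) covariance labels, e.g. G_11, G_21, G_22.
cov_labels <- function(t, prefix) {
  idx <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  sprintf("%s_%d%d", prefix, idx[, 1L], idx[, 2L])
}

# Random initial position on the unconstrained scale: small jitter keeps
# the start in a well-conditioned region while chains remain
# over-dispersed relative to each other.
init_position <- function(n, t, jitter_sd = 0.1) {
  sl <- param_slices(n, t)
  u <- numeric(param_dim(n, t))
  u[sl$z_a] <- stats::rnorm(n * t, 0, jitter_sd)
  u[sl$log_sd_a] <- stats::rnorm(t, 0, jitter_sd)
  u[sl$log_sd_e] <- stats::rnorm(t, 0, jitter_sd)
  u[sl$u_corr_a] <- stats::rnorm(length(sl$u_corr_a), 0, jitter_sd)
  u[sl$u_corr_e] <- stats::rnorm(length(sl$u_corr_e), 0, jitter_sd)
  u[sl$mu] <- stats::rnorm(t, 0, jitter_sd)
  u
}

#' @export
print.nuts_fit <- function(x, ...) {
  cat(sprintf("nuts_fit (%s): %d kept draws, %d divergent, mean leapfrog %.1f\n",
              x$method, x$n_kept, sum(x$stats$divergent),
              mean(x$stats$n_leapfrog)))
  invisible(x)
}

#' Posterior summary of an animal-model fit
#'
#' Posterior means and standard deviations of the covariance elements,
#' heritabilities and correlations (derived per draw, then averaged).
#'
#' @param object An `mtvc_fit` (from [fit_nuts()] or [run_gibbs()]).
#' @param ... Unused.
#' @return A data frame with `parameter`, `mean`, `sd`.
#' @export
summary.mtvc_fit <- function(object, ...) {
  t <- dim(object$G0)[1L]
  dp <- derived_parameters(object$G0, object$R0)
  lab <- function(prefix, i, j) sprintf("%s(trait%d,trait%d)", prefix, i, j)
  rows <- list()
  add <- function(name, draws) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, mean = mean(draws), sd = stats::sd(draws))
  }
  for (i in seq_len(t)) add(sprintf("sigma2_a(trait%d)", i), object$G0[i, i, ])
  for (j in seq_len(t)) for (i in seq_len(t)) if (i > j)
    add(lab("sigma_a", j, i), object$G0[i, j, ])
  for (i in seq_len(t)) add(sprintf("sigma2_e(trait%d)", i), object$R0[i, i, ])
  for (j in seq_len(t)) for (i in seq_len(t)) if (i > j)
    add(lab("sigma_e", j, i), object$R0[i, j, ])
  for (i in seq_len(t)) add(sprintf("h2(trait%d)", i), dp$draws$h2[, i])
  k <- 0L
  for (j in seq_len(t)) for (i in seq_len(t)) if (i > j) {
    k <- k + 1L
    add(lab("r_a", j, i), dp$draws$r_a[, k])
  }
  k <- 0L
  for (j in seq_len(t)) for (i in seq_len(t)) if (i > j) {
    k <- k + 1L
    add(lab("r_e", j, i), dp$draws$r_e[, k])
  }
  do.call(rbind, rows)
}
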
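#' No-U-Turn Sampler configuration
#'
#' Defaults follow the study protocol: 2000 iterations with the first 1000
#' discarded as warm-up, tree depth capped at 10 and leapfrog steps per
#' iteration capped at 1000, target acceptance 0.8, divergence declared
#' when the simulated energy error exceeds 1000.
#'
#' @param n_iter Total iterations (default 2000).
#' @param n_warmup Warm-up iterations discarded and used for step-size
#'   adaptation (default 1000).
#' @param target_accept Dual-averaging target mean acceptance (default
#'   0.8).
#' @param max_tree_depth Maximum doublings per iteration (default 10).
#' @param max_leapfrog Maximum leapfrog steps per iteration (default 1000).
#' @param divergence_threshold Energy-error bound beyond which a leaf is
#'   flagged divergent (default 1000).
#' @param metric `"diag"` (default) adapts a diagonal inverse mass matrix
#'   from the warm-up draws in expanding windows, as metric-adapting
#'   implementations do; `"unit"` keeps the identity metric.
#' @param adapt Logical; disable to keep the initial step size fixed.
#' @param init_step_size Step size used when adaptation is disabled, or as
#'   the heuristic's starting point.
#' @param seed Integer seed.
#' @return A `nuts_config` list.
#' @export
nuts_config <- function(n_iter = 2000L, n_warmup = 1000L,
                        target_accept = 0.8, max_tree_depth = 10L,
                        max_leapfrog = 1000L, divergence_threshold = 1000,
                        metric = c("diag", "unit"),
                        adapt = TRUE, init_step_size = NULL, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(n_warmup < n_iter, max_tree_depth >= 1L, max_leapfrog >= 1L,
            target_accept > 0, target_accept < 1)
  structure(list(n_iter = as.integer(n_iter), n_warmup = as.integer(n_warmup),
                 target_accept = target_accept,
                 max_tree_depth = as.integer(max_tree_depth),
                 max_leapfrog = as.integer(max_leapfrog),
                 divergence_threshold = divergence_threshold,
                 metric = metric,
                 adapt = isTRUE(adapt), init_step_size = init_step_size,
                 seed = as.integer(seed)),
            class = "nuts_config")
}

#' Construct a Hamiltonian state
#'
#' Recomputes the log density and gradient at `position` so the state is
#' always internally consistent.
#'
#' @param position Unconstrained parameter vector.
#' @param momentum Momentum vector of the same length (default: zeros).
#' @param logdensity Function returning `list(logp, grad)`.
#' @return An `hmc_state` list with `position`, `momentum`, `logp`, `grad`.
#' @export
hmc_state <- function(position, logdensity, momentum = NULL) {
  ld <- logdensity(position)
  if (is.null(momentum)) momentum <- numeric(length(position))
  structure(list(position = position, momentum = momentum,
                 logp = ld$logp, grad = ld$grad), class = "hmc_state")
}

#' One leapfrog step
#'
#' Half-step on the momentum, full step on the position, half-step on the
#' momentum, under an identity mass matrix. If the log density at the
#' proposal is non-finite the returned state carries `logp = -Inf` (the
#' caller treats it as a divergence).
#'
#' @param s An [hmc_state()].
#' @param eps Step size; negative values integrate backwards in time (used
#'   by the tree expansion).
#' @param logdensity Function returning `list(logp, grad)`.
#' @param inv_metric Diagonal of the inverse mass matrix (scalar 1 for the
#'   identity metric).
#' @return The advanced `hmc_state`.
#' @export
leapfrog <- function(s, eps, logdensity, inv_metric = 1) {
  stopifnot(eps != 0)
  p <- s$momentum + 0.5 * eps * s$grad
  q <- s$position + eps * inv_metric * p
  ld <- logdensity(q)
  if (!is.finite(ld$logp)) {
    return(structure(list(position = q, momentum = p, logp = -Inf,
                          grad = ld$grad), class = "hmc_state"))
  }
  p <- p + 0.5 * eps * ld$grad
  structure(list(position = q, momentum = p, logp = ld$logp,
                 grad = ld$grad), class = "hmc_state")
}

log_joint <- function(s, inv_metric = 1) {
  s$logp - 0.5 * sum(inv_metric * s$momentum^2)
}

uturn <- function(s_minus, s_plus, inv_metric = 1) {
  dq <- s_plus$position - s_minus$position
  sum(dq * inv_metric * s_minus$momentum) < 0 ||
    sum(dq * inv_metric * s_plus$momentum) < 0
}

#' Recursive trajectory doubling (slice variant)
#'
#' Implements the balanced binary-tree recursion of the original
#' No-U-Turn algorithm with slice-sampling leaf selection: the subtree
#' proposal is chosen uniformly among leaves whose joint density exceeds
#' the slice variable, expansion stops on a U-turn (momentum against the
#' end-to-end displacement at either end) or when the energy error exceeds
#' the divergence threshold. Exposed mainly for testing; [sample_chain()]
#' drives it.
#'
#' @param s An [hmc_state()] at the tree root.
#' @param logu Log of the slice variable.
#' @param direction `+1` or `-1`.
#' @param depth Tree depth (0 = a single leapfrog step).
#' @param eps Step size.
#' @param logdensity Log-density function.
#' @param joint0 Log joint density at the iteration start.
#' @param divergence_threshold Energy-error bound.
#' @return A list with the two end states, the selected `proposal`, leaf
#'   count `n_valid`, stop flag `s_ok`, `divergent`, `alpha`/`n_alpha`
#'   acceptance bookkeeping and the leapfrog count.
#' @export
build_tree <- function(s, logu, direction, depth, eps, logdensity, joint0,
                       divergence_threshold = 1000, inv_metric = 1) {
  if (depth == 0L) {
    s1 <- leapfrog(s, direction * eps, logdensity, inv_metric)
    joint <- log_joint(s1, inv_metric)
    n_valid <- if (is.finite(joint) && logu <= joint) 1L else 0L
    # divergence: simulated energy error beyond the threshold (or a
    # non-finite density), measured against the iteration's start
    divergent <- !is.finite(joint) ||
      abs(joint - joint0) > divergence_threshold
    alpha <- if (is.finite(joint)) min(1, exp(joint - joint0)) else 0
    return(list(s_minus = s1, s_plus = s1, proposal = s1,
                n_valid = n_valid, s_ok = !divergent, divergent = divergent,
                alpha = alpha, n_alpha = 1L, n_leapfrog = 1L))
  }
  t1 <- build_tree(s, logu, direction, depth - 1L, eps, logdensity, joint0,
                   divergence_threshold, inv_metric)
  if (!t1$s_ok) return(t1)
  if (direction == 1L) {
    t2 <- build_tree(t1$s_plus, logu, direction, depth - 1L, eps,
                     logdensity, joint0, divergence_threshold, inv_metric)
    s_minus <- t1$s_minus; s_plus <- t2$s_plus
  } else {
    t2 <- build_tree(t1$s_minus, logu, direction, depth - 1L, eps,
                     logdensity, joint0, divergence_threshold, inv_metric)
    s_minus <- t2$s_minus; s_plus <- t1$s_plus
  }
  n_total <- t1$n_valid + t2$n_valid
  proposal <- t1$proposal
  if (t2$n_valid > 0L && stats::runif(1) < t2$n_valid / max(n_total, 1L)) {
    proposal <- t2$proposal
  }
  list(s_minus = s_minus, s_plus = s_plus, proposal = proposal,
       n_valid = n_total,
       s_ok = t2$s_ok && !uturn(s_minus, s_plus, inv_metric),
       divergent = t1$divergent || t2$divergent,
       alpha = t1$alpha + t2$alpha, n_alpha = t1$n_alpha + t2$n_alpha,
       n_leapfrog = t1$n_leapfrog + t2$n_leapfrog)
}

# Step-size heuristic: double or halve until the single-leapfrog
# acceptance probability crosses 0.5.
find_reasonable_epsilon <- function(s, logdensity, eps = 1,
                                    inv_metric = 1) {
  p0 <- stats::rnorm(length(s$position)) / sqrt(inv_metric)
  s$momentum <- p0
  j0 <- log_joint(s, inv_metric)
  s1 <- leapfrog(s, eps, logdensity, inv_metric)
  ratio <- exp(log_joint(s1, inv_metric) - j0)
  if (!is.finite(ratio)) ratio <- 0
  dir <- if (ratio > 0.5) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^dir
    s1 <- leapfrog(s, eps, logdensity, inv_metric)
    ratio <- exp(log_joint(s1, inv_metric) - j0)
    if (!is.finite(ratio)) ratio <- 0
    if ((dir == 1 && ratio < 0.5) || (dir == -1 && ratio > 0.5)) break
  }
  eps
}

#' Dual-averaging step-size adaptation state
#'
#' Nesterov dual averaging with the standard constants `gamma = 0.05`,
#' `t0 = 10`, `kappa = 0.75`. One [da_update()] call per warm-up iteration
#' moves the current step size toward the target acceptance; the averaged
#' iterate is frozen after warm-up.
#'
#' @param eps0 Initial step size (from the doubling/halving heuristic).
#' @param target_accept Target mean acceptance statistic.
#' @return A dual-averaging state list.
#' @export
da_init <- function(eps0, target_accept = 0.8) {
  list(mu = log(10 * eps0), log_eps = log(eps0), log_eps_bar = 0,
       h_bar = 0, m = 0L, gamma = 0.05, t0 = 10, kappa = 0.75,
       target = target_accept)
}

#' @rdname da_init
#' @param da A dual-averaging state.
#' @param accept_stat Mean acceptance statistic of the last iteration.
#' @export
da_update <- function(da, accept_stat) {
  da$m <- da$m + 1L
  frac <- 1 / (da$m + da$t0)
  da$h_bar <- (1 - frac) * da$h_bar + frac * (da$target - accept_stat)
  da$log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
  w <- da$m^(-da$kappa)
  da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
  da
}

#' Run one NUTS chain
#'
#' Warm-up with dual-averaging step-size adaptation followed by sampling
#' at the frozen step size; per-draw sampler statistics (leapfrog count,
#' tree depth, divergence flag, mean acceptance, step size) are recorded.
#' Deterministic given `cfg$seed`.
#'
#' @param logdensity Function of the position returning `list(logp, grad)`.
#' @param init Initial position; the log density must be finite there.
#' @param cfg A [nuts_config()].
#' @param keep_warmup Retain warm-up draws as well (default `FALSE`).
#' @return A `chain_result` list: `draws` (matrix, post-warm-up iterations
#'   by parameters), `stats` (data frame of per-draw statistics),
#'   `warmup_draws` (optional), `step_size` (frozen value) and
#'   `adaptation` (step-size trace over warm-up).
#' @export
sample_chain <- function(logdensity, init, cfg = nuts_config(),
                         keep_warmup = FALSE) {
  rng <- local_rng(cfg$seed)
  on.exit(rng$restore())
  ld0 <- logdensity(init)
  if (!is.finite(ld0$logp)) {
    stop("log density is not finite at the initial value; re-initialize")
  }
  dim <- length(init)
  s <- structure(list(position = init, momentum = numeric(dim),
                      logp = ld0$logp, grad = ld0$grad), class = "hmc_state")
  inv_metric <- rep(1, dim)
  eps <- if (!is.null(cfg$init_step_size)) cfg$init_step_size else
    find_reasonable_epsilon(s, logdensity, inv_metric = inv_metric)
  da <- da_init(eps, cfg$target_accept)
  # expanding adaptation windows for the diagonal metric (step-size-only
  # buffers at both ends); skipped for short warm-ups or the unit metric
  use_metric <- cfg$adapt && identical(cfg$metric, "diag") &&
    cfg$n_warmup >= 200L
  # terminal buffer: step-size-only iterations after the last metric
  # update, long enough for dual averaging to settle on the final metric
  term_buffer <- max(50L, as.integer(0.15 * cfg$n_warmup))
  if (use_metric) {
    win_start <- 76L
    win_end <- min(win_start + 24L, cfg$n_warmup - term_buffer)
    acc_n <- 0L
    acc_mean <- numeric(dim)
    acc_m2 <- numeric(dim)
  }
  n_keep <- cfg$n_iter - cfg$n_warmup
  draws <- matrix(NA_real_, n_keep, dim)
  warmup <- if (keep_warmup) matrix(NA_real_, cfg$n_warmup, dim) else NULL
  stats_df <- data.frame(n_leapfrog = integer(n_keep),
                         tree_depth = integer(n_keep),
                         divergent = logical(n_keep),
                         accept_stat = numeric(n_keep),
                         step_size = numeric(n_keep))
  eps_trace <- numeric(cfg$n_warmup)

  for (m in seq_len(cfg$n_iter)) {
    p0 <- stats::rnorm(dim) / sqrt(inv_metric)
    s$momentum <- p0
    joint0 <- log_joint(s, inv_metric)
    logu <- joint0 - stats::rexp(1)
    s_minus <- s_plus <- s
    proposal <- s
    n_valid <- 1L
    depth <- 0L
    n_leapfrog <- 0L
    divergent <- FALSE
    alpha_sum <- 0; n_alpha <- 0L
    ok <- TRUE
    while (ok && depth < cfg$max_tree_depth &&
           n_leapfrog + 2^depth <= cfg$max_leapfrog) {
      direction <- if (stats::runif(1) < 0.5) -1L else 1L
      root <- if (direction == 1L) s_plus else s_minus
      tree <- build_tree(root, logu, direction, depth, eps, logdensity,
                         joint0, cfg$divergence_threshold, inv_metric)
      n_leapfrog <- n_leapfrog + tree$n_leapfrog
      divergent <- divergent || tree$divergent
      alpha_sum <- alpha_sum + tree$alpha
      n_alpha <- n_alpha + tree$n_alpha
      if (direction == 1L) s_plus <- tree$s_plus else s_minus <- tree$s_minus
      if (tree$s_ok && tree$n_valid > 0L &&
          stats::runif(1) < tree$n_valid / n_valid) {
        proposal <- tree$proposal
      }
      n_valid <- n_valid + tree$n_valid
      ok <- tree$s_ok && !uturn(s_minus, s_plus, inv_metric)
      depth <- depth + 1L
    }
    s <- proposal
    accept_stat <- if (n_alpha > 0L) alpha_sum / n_alpha else 0
    if (m <= cfg$n_warmup) {
      if (cfg$adapt) {
        da <- da_update(da, accept_stat)
        eps <- exp(da$log_eps)
      }
      if (use_metric && m >= win_start && m <= win_end) {
        # Welford accumulation of the warm-up draws in this window
        acc_n <- acc_n + 1L
        delta <- s$position - acc_mean
        acc_mean <- acc_mean + delta / acc_n
        acc_m2 <- acc_m2 + delta * (s$position - acc_mean)
        if (m == win_end) {
          if (acc_n >= 10L) {
            v <- acc_m2 / (acc_n - 1L)
            # regularized toward unity, as metric-adapting samplers do
            inv_metric <- acc_n / (acc_n + 5) * v +
              (5 / (acc_n + 5)) * 1e-3
            inv_metric[inv_metric <= 0] <- 1e-3
            # re-baseline the step size for the new metric
            eps <- find_reasonable_epsilon(s, logdensity, eps,
                                           inv_metric = inv_metric)
            da <- da_init(eps, cfg$target_accept)
          }
          acc_n <- 0L
          acc_mean <- numeric(dim)
          acc_m2 <- numeric(dim)
          width <- 2L * (win_end - win_start + 1L)
          win_start <- win_end + 1L
          win_end <- win_start + width - 1L
          # the final window swallows the remainder before the end buffer
          if (win_end + width > cfg$n_warmup - term_buffer) {
            win_end <- cfg$n_warmup - term_buffer
          }
        }
      }
      eps_trace[m] <- eps
      if (keep_warmup) warmup[m, ] <- s$position
      if (m == cfg$n_warmup && cfg$adapt) eps <- exp(da$log_eps_bar)
    } else {
      k <- m - cfg$n_warmup
      draws[k, ] <- s$position
      stats_df$n_leapfrog[k] <- n_leapfrog
      stats_df$tree_depth[k] <- depth
      stats_df$divergent[k] <- divergent
      stats_df$accept_stat[k] <- accept_stat
      stats_df$step_size[k] <- eps
    }
  }
  structure(list(draws = draws, stats = stats_df, warmup_draws = warmup,
                 step_size = eps, adaptation = eps_trace,
                 inv_metric = inv_metric),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain_result: %d draws x %d parameters, step size %.4g, %d divergent\n",
              nrow(x$draws), ncol(x$draws), x$step_size,
              sum(x$stats$divergent)))
  invisible(x)
}

#' Write a chain dump as CSV
#'
#' One row per draw: named model parameters followed by the sampler
#' statistic columns (`n_leapfrog`, `tree_depth`, `divergent`,
#' `accept_stat`, `step_size`); the statistics are empty for samplers that
#' do not produce them.
#'
#' @param draws Matrix of draws with column names.
#' @param path Output path.
#' @param stats Optional data frame of per-draw sampler statistics.
#' @return `path`, invisibly.
#' @export
write_chain <- function(draws, path, stats = NULL) {
  df <- as.data.frame(draws)
  cols <- c("n_leapfrog", "tree_depth", "divergent", "accept_stat",
            "step_size")
  if (is.null(stats)) {
    for (cn in cols) df[[cn]] <- NA
  } else {
    for (cn in cols) df[[cn]] <- stats[[cn]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
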
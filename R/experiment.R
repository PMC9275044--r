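#' Experiment configuration for scenario reproduction
#'
#' Bundles everything [run_experiment()] needs to reproduce a simulation
#' scenario: the scenario name and scale, methods to fit, LKJ shape values,
#' replicate count, sampler settings and the master seed. Replicate seeds
#' are derived deterministically as `seed + replicate`.
#'
#' @param scenario `"scenario1"` or `"scenario2"`.
#' @param methods Subset of `c("nuts-lkj", "nuts-iw", "gibbs")`.
#' @param eta Numeric vector of LKJ shape values for `"nuts-lkj"`
#'   (default 1; the sensitivity set is `c(0.25, 0.5, 1, 2, 4)`).
#' @param n_replicates Number of simulation replicates (default 10).
#' @param scale Scale factor on animal counts for desk-scale runs.
#' @param seed Master seed.
#' @param n_snps SNPs in the synthetic panel (default 2000).
#' @param family_size Full-sib family size in the synthetic panel
#'   (default 10; families cover roughly half the animals).
#' @param nuts Optional [nuts_config()] override.
#' @param gibbs Optional [gibbs_config()] override.
#' @param n_chains NUTS chains per fit (3 enables the R-hat workflow).
#' @param diagnostics Compute convergence diagnostics per replicate.
#' @param out_dir Output directory for CSV artifacts (`NULL`: in-memory
#'   only).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario = "scenario2",
                              methods = "nuts-lkj",
                              eta = 1.0, n_replicates = 10L, scale = 1,
                              seed = 1L, n_snps = 2000L, family_size = 10L,
                              nuts = NULL, gibbs = NULL, n_chains = 1L,
                              diagnostics = FALSE, out_dir = NULL) {
  methods <- match.arg(methods, c("nuts-lkj", "nuts-iw", "gibbs"),
                       several.ok = TRUE)
  structure(list(scenario = scenario, methods = methods, eta = eta,
                 n_replicates = as.integer(n_replicates), scale = scale,
                 seed = as.integer(seed), n_snps = as.integer(n_snps),
                 family_size = as.integer(family_size),
                 nuts = if (is.null(nuts)) nuts_config() else nuts,
                 gibbs = if (is.null(gibbs)) gibbs_config() else gibbs,
                 n_chains = as.integer(n_chains),
                 diagnostics = isTRUE(diagnostics), out_dir = out_dir),
            class = "experiment_config")
}

# True parameter values in the table row order.
truth_vector <- function(arch) {
  ip <- implied_parameters(arch)
  c(sigma2_a_trait1 = arch$G0[1, 1], sigma2_a_trait2 = arch$G0[2, 2],
    sigma_a_12 = arch$G0[2, 1],
    sigma2_e_trait1 = arch$R0[1, 1], sigma2_e_trait2 = arch$R0[2, 2],
    sigma_e_12 = arch$R0[2, 1],
    h2_trait1 = unname(ip$h2[1]), h2_trait2 = unname(ip$h2[2]),
    r_a_12 = ip$genetic_correlation[2, 1],
    r_e_12 = ip$residual_correlation[2, 1])
}

param_order <- c("sigma2_a_trait1", "sigma2_a_trait2", "sigma_a_12",
                 "sigma2_e_trait1", "sigma2_e_trait2", "sigma_e_12",
                 "h2_trait1", "h2_trait2", "r_a_12", "r_e_12")

# Posterior-mean point estimates of the table parameters from a fit.
fit_point_estimates <- function(fit) {
  dp <- derived_parameters(fit$G0, fit$R0)
  c(sigma2_a_trait1 = mean(fit$G0[1, 1, ]),
    sigma2_a_trait2 = mean(fit$G0[2, 2, ]),
    sigma_a_12 = mean(fit$G0[2, 1, ]),
    sigma2_e_trait1 = mean(fit$R0[1, 1, ]),
    sigma2_e_trait2 = mean(fit$R0[2, 2, ]),
    sigma_e_12 = mean(fit$R0[2, 1, ]),
    h2_trait1 = mean(dp$draws$h2[, 1]),
    h2_trait2 = mean(dp$draws$h2[, 2]),
    r_a_12 = mean(dp$draws$r_a[, 1]),
    r_e_12 = mean(dp$draws$r_e[, 1]))
}

stage_log <- function(cfg, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  if (!is.null(cfg$out_dir)) {
    cat(msg, "\n", file = file.path(cfg$out_dir, "experiment.log"),
        append = TRUE)
  }
  message(msg)
}

# Fit one method on the training records and return the fit plus test EBVs.
fit_one_method <- function(method, eta, y_train, eig_train, A_full, train,
                           test, cfg, rep_seed) {
  if (method == "gibbs") {
    gcfg <- cfg$gibbs
    gcfg$seed <- rep_seed
    fit <- run_gibbs(y_train, eig_train, gcfg)
  } else {
    kind <- if (method == "nuts-lkj") "lkj" else "iw"
    ncfg <- cfg$nuts
    ncfg$seed <- rep_seed
    fit <- fit_nuts(y_train, eig_train, prior_config(kind, eta = eta),
                    ncfg, chains = cfg$n_chains)
  }
  a_test <- if (length(test)) {
    predict_test_ebv(A_full, train, test, fit$a_hat)
  } else NULL
  list(fit = fit, a_test = a_test)
}

#' Run a seeded end-to-end simulation experiment
#'
#' For each replicate: generate synthetic genotypes, apply QC, build the
#' genomic relationship matrix, simulate correlated traits, fit the
#' requested methods on the training records, and compute derived
#' parameters, replicate error metrics, test-set breeding-value accuracy
#' and (optionally) convergence diagnostics. Deterministic given the
#' master seed.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_result` list: `estimates` (per replicate /
#'   method / parameter), `error_metrics`, `ebv` (per replicate), `ebv_summary`,
#'   `results_table` (parameter, true value, per-method mean and SE),
#'   `diagnostics`, `truth`, `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(cfg$out_dir) &&
      !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  sc <- make_scenario(cfg$scenario, scale = cfg$scale,
                      n_replicates = cfg$n_replicates)
  arch <- sc$architecture
  truth <- truth_vector(arch)
  n_fam <- max(0L, floor(sc$n_animals / (2L * cfg$family_size)))
  est_rows <- list()
  ebv_rows <- list()
  diag_rows <- list()
  nuts_divergent <- 0L
  nuts_leapfrog <- c()
  nuts_depth <- c()
  health_rows <- list()

  for (r in seq_len(cfg$n_replicates)) {
    rep_seed <- cfg$seed + r
    stage_log(cfg, "replicate %d (seed %d): genotypes %d x %d", r, rep_seed,
              sc$n_animals, cfg$n_snps)
    g <- synthetic_genotypes(sc$n_animals, cfg$n_snps,
                             n_families = n_fam,
                             family_size = cfg$family_size, seed = rep_seed)
    qc <- qc_filter(g)
    grm <- compute_grm(qc$genotypes)
    sim <- simulate_traits(grm, arch, seed = rep_seed + 10000L,
                           n_test = sc$n_test)
    train <- sim$train_ids; test <- sim$test_ids
    y_train <- sim$y[train, , drop = FALSE]
    eig_train <- grm_eigen(grm$A[train, train])
    stage_log(cfg, "replicate %d: GRM jitter %.2e, %d SNPs kept", r,
              eig_train$jitter, ncol(qc$genotypes))
    for (method in cfg$methods) {
      etas <- if (method == "nuts-lkj") cfg$eta else 1.0
      for (eta in etas) {
        label <- if (method == "nuts-lkj" && length(cfg$eta) > 1L) {
          sprintf("nuts-lkj-eta%g", eta)
        } else method
        res <- fit_one_method(method, eta, y_train, eig_train, grm$A,
                              train, test, cfg, rep_seed)
        if (inherits(res$fit, "nuts_fit")) {
          nuts_divergent <- nuts_divergent + sum(res$fit$stats$divergent)
          nuts_leapfrog <- c(nuts_leapfrog, mean(res$fit$stats$n_leapfrog))
          nuts_depth <- c(nuts_depth, mean(res$fit$stats$tree_depth))
          health_rows[[length(health_rows) + 1L]] <- data.frame(
            method = label, replicate = r,
            n_divergent = sum(res$fit$stats$divergent),
            mean_leapfrog = mean(res$fit$stats$n_leapfrog),
            max_leapfrog = max(res$fit$stats$n_leapfrog),
            mean_tree_depth = mean(res$fit$stats$tree_depth),
            max_tree_depth = max(res$fit$stats$tree_depth))
        }
        pe <- fit_point_estimates(res$fit)
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          method = label, replicate = r, parameter = names(pe),
          estimate = unname(pe))
        if (!is.null(res$a_test)) {
          em <- ebv_metrics(sim$a_true[test, , drop = FALSE], res$a_test)
          em$method <- label; em$replicate <- r
          ebv_rows[[length(ebv_rows) + 1L]] <- em
        }
        if (cfg$diagnostics) {
          dg <- replicate_diagnostics(res$fit, label, r)
          diag_rows[[length(diag_rows) + 1L]] <- dg
        }
        stage_log(cfg, "replicate %d: %s done (h2 = %.3f / %.3f)", r, label,
                  pe["h2_trait1"], pe["h2_trait2"])
      }
    }
  }
  estimates <- do.call(rbind, est_rows)
  ref <- if ("nuts-lkj" %in% estimates$method) "nuts-lkj" else
    estimates$method[1L]
  err <- error_metrics(estimates, truth, reference = ref)
  ebv <- if (length(ebv_rows)) do.call(rbind, ebv_rows) else NULL
  ebv_summary <- if (!is.null(ebv)) {
    stats::aggregate(cbind(accuracy, rmse) ~ method + trait, data = ebv,
                     FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  } else NULL
  table_df <- results_table(estimates, truth)
  out <- structure(list(estimates = estimates, error_metrics = err,
                        ebv = ebv, ebv_summary = ebv_summary,
                        results_table = table_df,
                        diagnostics = if (length(diag_rows))
                          do.call(rbind, diag_rows) else NULL,
                        nuts_health = if (length(health_rows))
                          do.call(rbind, health_rows) else NULL,
                        nuts_divergent = nuts_divergent,
                        nuts_mean_leapfrog = if (length(nuts_leapfrog))
                          mean(nuts_leapfrog) else NA_real_,
                        nuts_mean_tree_depth = if (length(nuts_depth))
                          mean(nuts_depth) else NA_real_,
                        truth = truth, config = cfg, scenario = sc),
                   class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

replicate_diagnostics <- function(fit, label, r) {
  rows <- list()
  if (inherits(fit, "nuts_fit")) {
    sr <- sampler_report(fit)
    rows[[1L]] <- data.frame(method = label, replicate = r,
                             statistic = names(sr),
                             value = unlist(sr, use.names = FALSE))
    if (length(fit$per_chain) >= 2L) {
      rh <- gelman_rubin(fit$per_chain)
      rows[[2L]] <- data.frame(method = label, replicate = r,
                               statistic = paste0("rhat_", names(rh)),
                               value = as.numeric(rh))
    }
    gw <- geweke(fit$per_chain[[1L]])
    rows[[length(rows) + 1L]] <- data.frame(
      method = label, replicate = r,
      statistic = paste0("geweke_z_", names(gw)), value = as.numeric(gw))
  } else {
    cols <- cbind(G_11 = fit$G0[1, 1, ], G_22 = fit$G0[2, 2, ],
                  R_11 = fit$R0[1, 1, ], R_22 = fit$R0[2, 2, ])
    gw <- geweke(cols)
    rows[[1L]] <- data.frame(method = label, replicate = r,
                             statistic = paste0("geweke_z_", names(gw)),
                             value = as.numeric(gw))
  }
  do.call(rbind, rows)
}

# Mean and SD over replicates per method, one row per parameter in the
# conventional table order.
results_table <- function(estimates, truth) {
  methods <- unique(estimates$method)
  df <- data.frame(parameter = param_order,
                   true = unname(truth[param_order]))
  for (m in methods) {
    sub <- estimates[estimates$method == m, ]
    mns <- tapply(sub$estimate, sub$parameter, mean)[param_order]
    sds <- tapply(sub$estimate, sub$parameter, stats::sd)[param_order]
    df[[paste0(m, "_mean")]] <- as.numeric(mns)
    df[[paste0(m, "_se")]] <- as.numeric(sds)
  }
  df
}

write_experiment <- function(res, dir) {
  utils::write.csv(res$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(res$error_metrics, file.path(dir, "error_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(res$results_table, file.path(dir, "results_table.csv"),
                   row.names = FALSE)
  if (!is.null(res$ebv)) {
    utils::write.csv(res$ebv, file.path(dir, "ebv_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$diagnostics)) {
    utils::write.csv(res$diagnostics, file.path(dir, "diagnostics.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %s (scale %g), %d replicates, methods: %s\n",
              x$config$scenario, x$config$scale, x$config$n_replicates,
              paste(unique(x$estimates$method), collapse = ", ")))
  print(x$results_table, digits = 3)
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    vals <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
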
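#' Desk-scale reproduction of the simulation study
#'
#' Runs the two simulation batches that drive the headline quantities of
#' the simulation study on synthetic genotypes and returns them as a flat
#' named list, each entry carrying `value` and the problem size `n` it was
#' computed at:
#'
#' * the analytic correlations implied by the simulation architecture;
#' * a scaled scenario-1 batch (population scaled to 500 animals,
#'   5 replicates, NUTS with the LKJ prior and the Gibbs sampler):
#'   recovery of the high heritability, the residual correlation, the
#'   genetic correlation, and the Gibbs estimate of the high heritability;
#' * a scenario-2 batch (578 animals, 3 replicates, NUTS with LKJ and
#'   inverse-Wishart priors): the low-trait heritability under each prior
#'   plus test-set breeding-value accuracies;
#' * NUTS sampler health (divergent transitions) pooled over all runs.
#'
#' All replicate seeds derive deterministically from `seed`.
#'
#' @param seed Master seed.
#' @param n_replicates_s1,n_replicates_s2 Replicates per batch (default 5
#'   each).
#' @param verbose Emit stage logs.
#' @return A list with `quantities` (named list of `value`/`n` pairs) and
#'   the two `experiment_result` objects (`scenario1`, `scenario2`).
#' @export
reproduce_study <- function(seed = 1L, n_replicates_s1 = 5L,
                            n_replicates_s2 = 5L, verbose = TRUE) {
  seed <- as.integer(seed)
  ip <- implied_parameters(default_architecture())
  qty <- list()
  put <- function(name, value, n) {
    qty[[name]] <<- list(value = as.numeric(value), n = as.numeric(n))
  }
  put("implied_genetic_correlation", ip$genetic_correlation[2, 1], 2)
  put("implied_residual_correlation", ip$residual_correlation[2, 1], 2)
  put("implied_h2_trait1", ip$h2[1], 2)
  put("implied_h2_trait2", ip$h2[2], 2)

  run_quiet <- function(cfg) {
    if (verbose) run_experiment(cfg) else
      suppressMessages(run_experiment(cfg))
  }
  # scenario 1 scaled so the population totals 500 animals
  s1 <- run_quiet(experiment_config(
    scenario = "scenario1", methods = c("nuts-lkj", "gibbs"),
    n_replicates = n_replicates_s1, scale = 500 / 2314, seed = seed))
  pm <- function(res, method, param) {
    sub <- res$estimates
    mean(sub$estimate[sub$method == method & sub$parameter == param])
  }
  n1 <- s1$scenario$n_train
  put("h2_trait2_nuts_lkj_scenario1", pm(s1, "nuts-lkj", "h2_trait2"), n1)
  put("residual_correlation_nuts_lkj_scenario1",
      pm(s1, "nuts-lkj", "r_e_12"), n1)
  put("genetic_correlation_nuts_lkj_scenario1",
      pm(s1, "nuts-lkj", "r_a_12"), n1)
  put("h2_trait1_nuts_lkj_scenario1", pm(s1, "nuts-lkj", "h2_trait1"), n1)
  put("h2_trait2_gibbs_scenario1", pm(s1, "gibbs", "h2_trait2"), n1)

  # scenario 2 at full size (578 animals, 500 train / 78 test)
  s2 <- run_quiet(experiment_config(
    scenario = "scenario2", methods = c("nuts-lkj", "nuts-iw"),
    n_replicates = n_replicates_s2, scale = 1, seed = seed + 100L))
  n2 <- s2$scenario$n_train
  put("h2_trait1_nuts_lkj_scenario2", pm(s2, "nuts-lkj", "h2_trait1"), n2)
  put("h2_trait1_nuts_iw_scenario2", pm(s2, "nuts-iw", "h2_trait1"), n2)
  put("h2_trait2_nuts_lkj_scenario2", pm(s2, "nuts-lkj", "h2_trait2"), n2)
  acc <- function(res, method, trait) {
    sub <- res$ebv
    mean(sub$accuracy[sub$method == method & sub$trait == trait])
  }
  put("ebv_accuracy_trait1_nuts_lkj_scenario2", acc(s2, "nuts-lkj", 1),
      s2$scenario$n_test)
  put("ebv_accuracy_trait2_nuts_lkj_scenario2", acc(s2, "nuts-lkj", 2),
      s2$scenario$n_test)
  put("ebv_accuracy_trait1_nuts_iw_scenario2", acc(s2, "nuts-iw", 1),
      s2$scenario$n_test)

  health <- rbind(s1$nuts_health, s2$nuts_health)
  lkj <- health[health$method == "nuts-lkj", ]
  put("nuts_divergent_transitions",
      sum(s1$nuts_divergent, s2$nuts_divergent), n1 + n2)
  put("nuts_lkj_divergent_transitions", sum(lkj$n_divergent), n1 + n2)
  put("nuts_mean_leapfrog_steps", mean(health$mean_leapfrog), n1 + n2)
  put("nuts_mean_tree_depth", mean(health$mean_tree_depth), n1 + n2)
  list(quantities = qty, scenario1 = s1, scenario2 = s2)
}
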
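# 1-D and 2-D Gaussian targets used throughout.
gauss_ld <- function(Sigma) {
  Si <- solve(Sigma)
  function(x) list(logp = -0.5 * sum(x * (Si %*% x)),
                   grad = -as.vector(Si %*% x))
}
std1d <- function(x) list(logp = -0.5 * x^2, grad = -x)

test_that("leapfrog conserves energy, is reversible, and respects flat densities", {
  flat <- function(x) list(logp = 0, grad = numeric(length(x)))
  s0 <- hmc_state(c(1.5, -2), flat)
  s1 <- leapfrog(s0, 0.3, flat)
  expect_equal(s1$position, s0$position)  # zero momentum, zero gradient

  # energy conservation on a standard normal: 1000 steps of eps = 0.01
  # from (x, p) = (1, 0); Hamiltonian drift stays below 1e-3
  s <- hmc_state(1, std1d, momentum = 0)
  H0 <- 0.5 * s$position^2 + 0.5 * s$momentum^2
  drift <- 0
  for (i in 1:1000) {
    s <- leapfrog(s, 0.01, std1d)
    H <- 0.5 * s$position^2 + 0.5 * s$momentum^2
    drift <- max(drift, abs(H - H0))
  }
  expect_lt(drift, 1e-3)

  # energy error scales as O(eps^2): quarter the step, ~1/16 the drift
  drift_at <- function(eps, steps) {
    s <- hmc_state(1, std1d, momentum = 0.3)
    H0 <- 0.5 * s$position^2 + 0.5 * s$momentum^2
    d <- 0
    for (i in seq_len(steps)) {
      s <- leapfrog(s, eps, std1d)
      d <- max(d, abs(0.5 * s$position^2 + 0.5 * s$momentum^2 - H0))
    }
    d
  }
  ratio <- drift_at(0.2, 100) / drift_at(0.05, 400)
  expect_gt(ratio, 8)   # ~16 in exact arithmetic

  # reversibility: forward, negate momentum, forward, negate = identity
  set.seed(5)
  ld <- gauss_ld(matrix(c(1, 0.6, 0.6, 2), 2))
  s0 <- hmc_state(rnorm(2), ld, momentum = rnorm(2))
  s1 <- leapfrog(s0, 0.17, ld)
  s1$momentum <- -s1$momentum
  s2 <- leapfrog(s1, 0.17, ld)
  expect_lt(max(abs(s2$position - s0$position)), 1e-10)
  expect_lt(max(abs(-s2$momentum - s0$momentum)), 1e-10)
})

test_that("tree building takes single steps at depth 0 and flags divergences", {
  ld <- gauss_ld(diag(2))
  set.seed(7)
  s <- hmc_state(c(0.3, -0.5), ld, momentum = rnorm(2))
  tr <- build_tree(s, log_joint(s) - 0.5, 1L, 0L, 0.2, ld, log_joint(s))
  expect_equal(tr$n_leapfrog, 1L)
  expect_equal(tr$proposal$position, leapfrog(s, 0.2, ld)$position)

  # degenerate divergence threshold flags every iteration
  res <- sample_chain(ld, c(0, 0),
                      nuts_config(n_iter = 60, n_warmup = 20, seed = 1,
                                  divergence_threshold = 0,
                                  adapt = FALSE, init_step_size = 0.5))
  expect_equal(mean(res$stats$divergent), 1)

  # well-conditioned 2-D normal: adapted tree depths concentrate low
  res2 <- sample_chain(ld, c(0, 0),
                       nuts_config(n_iter = 600, n_warmup = 300, seed = 2))
  expect_true(mean(res2$stats$tree_depth) >= 1 &&
                mean(res2$stats$tree_depth) <= 4)
  expect_equal(sum(res2$stats$divergent), 0)
})

test_that("dual averaging calibrates the acceptance rate and responds to the target", {
  ld <- gauss_ld(diag(10))
  res <- sample_chain(ld, rep(0, 10),
                      nuts_config(n_iter = 1500, n_warmup = 750, seed = 3))
  expect_lt(abs(mean(res$stats$accept_stat) - 0.8), 0.05)

  # higher target => smaller adapted step size, same problem and seed
  eps_hi <- sample_chain(ld, rep(0, 10),
                         nuts_config(n_iter = 400, n_warmup = 300, seed = 4,
                                     target_accept = 0.999))$step_size
  eps_lo <- sample_chain(ld, rep(0, 10),
                         nuts_config(n_iter = 400, n_warmup = 300, seed = 4,
                                     target_accept = 0.6))$step_size
  expect_lt(eps_hi, eps_lo)

  # adaptation disabled: step size constant
  res3 <- sample_chain(ld, rep(0, 10),
                       nuts_config(n_iter = 100, n_warmup = 50, seed = 5,
                                   adapt = FALSE, init_step_size = 0.3))
  expect_true(all(res3$stats$step_size == 0.3))
})

test_that("NUTS recovers Gaussian moments", {
  # standard 2-D normal, averaged over seeds (single 1000-draw chains
  # carry autocorrelation-inflated moment noise)
  ld <- gauss_ld(diag(2))
  devs <- sapply(1:4, function(s) {
    res <- sample_chain(ld, c(0, 0),
                        nuts_config(n_iter = 2000, n_warmup = 1000,
                                    seed = s))
    c(mean = max(abs(colMeans(res$draws))),
      cov = max(abs(stats::cov(res$draws) - diag(2))))
  })
  expect_lt(mean(devs["mean", ]), 0.1)
  expect_lt(mean(devs["cov", ]), 0.15)

  # correlated normal rho = 0.9
  ld2 <- gauss_ld(matrix(c(1, 0.9, 0.9, 1), 2))
  res2 <- sample_chain(ld2, c(0, 0),
                       nuts_config(n_iter = 2000, n_warmup = 1000, seed = 7))
  expect_lt(abs(stats::cor(res2$draws)[1, 2] - 0.9), 0.05)

  # determinism given seed
  res3 <- sample_chain(ld2, c(0, 0),
                       nuts_config(n_iter = 300, n_warmup = 150, seed = 7))
  res4 <- sample_chain(ld2, c(0, 0),
                       nuts_config(n_iter = 300, n_warmup = 150, seed = 7))
  expect_identical(res3$draws, res4$draws)

  expect_error(sample_chain(function(x) list(logp = -Inf, grad = 0), 0,
                            nuts_config(n_iter = 10, n_warmup = 5)),
               "re-initialize")
})

test_that("draws pass a Kolmogorov-Smirnov check against the analytic CDF", {
  ld <- function(x) list(logp = -0.5 * x^2, grad = -x)
  ks <- vapply(1:4, function(s) {
    res <- sample_chain(ld, 0.5,
                        nuts_config(n_iter = 2500, n_warmup = 500, seed = s))
    x <- sort(res$draws[, 1])
    n <- length(x)
    max(abs(pnorm(x) - seq_len(n) / n), abs(pnorm(x) - (seq_len(n) - 1) / n))
  }, numeric(1))
  # 1% critical value at n = 2000: 1.628 / sqrt(n)
  expect_lt(mean(ks), 1.628 / sqrt(2000))
})

test_that("chain dumps carry parameters and sampler statistics", {
  ld <- gauss_ld(diag(2))
  res <- sample_chain(ld, c(0, 0),
                      nuts_config(n_iter = 60, n_warmup = 30, seed = 9))
  colnames(res$draws) <- c("x1", "x2")
  tmp <- tempfile(fileext = ".csv")
  write_chain(res$draws, tmp, res$stats)
  df <- read.csv(tmp)
  expect_named(df, c("x1", "x2", "n_leapfrog", "tree_depth", "divergent",
                     "accept_stat", "step_size"))
  expect_equal(nrow(df), 30)
  expect_equal(df$n_leapfrog, res$stats$n_leapfrog)
})
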
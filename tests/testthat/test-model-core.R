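test_that("constrained transform is valid and round-trips", {
  n <- 5; t <- 3
  # zero unconstrained correlation coordinates give identity factors
  u0 <- numeric(mtvc:::param_dim(n, t))
  p0 <- constrain_transform(u0, n, t)
  expect_equal(p0$L_corr_a, diag(t))
  expect_equal(p0$sd_a, rep(1, t))   # log sd 0 -> sd 1
  expect_equal(p0$sd_e, rep(1, t))

  set.seed(17)
  for (rep in 1:5) {
    u <- rnorm(mtvc:::param_dim(n, t), 0, 0.8)
    p <- constrain_transform(u, n, t)
    # unit row norms and valid correlation matrix
    expect_lt(max(abs(rowSums(p$L_corr_a^2) - 1)), 1e-12)
    Om <- tcrossprod(p$L_corr_a)
    expect_lt(max(abs(diag(Om) - 1)), 1e-12)
    expect_true(all(eigen(Om, only.values = TRUE)$values > 0))
    # round trip
    expect_lt(max(abs(unconstrain_transform(p, n, t) - u)), 1e-10)
  }
  expect_error(constrain_transform(numeric(3), n, t), "dimension")
})

test_that("LKJ-Cholesky density is uniform over correlations at eta = 1", {
  expect_equal(lkj_cholesky_logpdf(matrix(1, 1, 1), 2), 0)

  # t = 2: transform the Cholesky-space density to the correlation r and
  # integrate numerically; eta = 1 must give the uniform density on (-1,1)
  dens_r <- function(r, eta) {
    # L = [[1,0],[r, sqrt(1-r^2)]]; d L22/dr term: density of r equals
    # exp(lkj_chol_lpdf) because the (t-i+2eta-2) exponent already
    # contains the Omega->L Jacobian
    L <- matrix(c(1, r, 0, sqrt(1 - r^2)), 2)
    exp(lkj_cholesky_logpdf(L, eta))
  }
  rs <- seq(-0.999, 0.999, length.out = 2001)
  vals1 <- vapply(rs, dens_r, numeric(1), eta = 1)
  # constant over r...
  expect_lt(diff(range(vals1)), 1e-12)
  # ...and integrates to 2 * constant => normalized density 1/2 everywhere
  # (1-D quadrature)
  Z <- sum(vals1) * diff(rs[1:2])
  expect_equal(Z / vals1[1], 2, tolerance = 1e-3)

  # for t = 2 the free coordinate of L is r itself, so the log density in
  # correlation space is lkj_cholesky_logpdf directly: it must equal
  # (eta - 1) * log|Omega| up to a constant, hence be flat at eta = 1
  omega_logdens <- function(r, eta) {
    L <- matrix(c(1, r, 0, sqrt(1 - r^2)), 2)
    lkj_cholesky_logpdf(L, eta)
  }
  expect_equal(omega_logdens(0.3, 1), omega_logdens(-0.6, 1),
               tolerance = 1e-12)
  # and matches the determinant kernel |Omega|^(eta-1) exactly for eta = 2
  expect_equal(omega_logdens(0.3, 2) - omega_logdens(-0.6, 2),
               log(1 - 0.3^2) - log(1 - 0.6^2), tolerance = 1e-12)

  expect_error(lkj_cholesky_logpdf(diag(c(1, -1)), 1), "positive")
})

test_that("breeding-value reconstruction has Kronecker covariance", {
  # degenerate inputs
  L_A <- t(chol(rand_spd(3, 5)))
  expect_equal(reconstruct_breeding_values(L_A, matrix(0, 3, 2),
                                           c(1, 2), diag(2)),
               matrix(0, 3, 2))
  z <- matrix(rnorm(6), 3, 2)
  expect_equal(reconstruct_breeding_values(diag(3), z, c(1, 1), diag(2)), z)
  expect_error(reconstruct_breeding_values(diag(3), z, c(1, 1, 1), diag(2)),
               "shape")

  # Monte Carlo: cov(vec a) = G0 (x) A for random factors
  set.seed(23)
  sd_a <- c(0.7, 1.6)
  Lc <- mtvc:::corr_chol_forward(c(0.4), 2)$L
  B <- Lc * sd_a
  G0 <- tcrossprod(B)
  A <- tcrossprod(L_A)
  reps <- 200000
  Zs <- matrix(rnorm(reps * 6), reps, 6)
  K <- kronecker(B, L_A)
  vecs <- Zs %*% t(K)
  emp <- crossprod(vecs) / reps
  target <- kronecker(G0, A)
  se <- sqrt((outer(diag(target), diag(target)) + target^2) / reps)
  expect_lt(max(abs(emp - target) / se), 3 * 1.5)
})

test_that("scalar model log-posterior matches a hand-coded formula", {
  # n = 1 animal, 1 trait, A = 1: the joint density reduces to
  # N(y | mu + sd_a*z, sd_e^2) * N(z) * halfCauchy(sd_a) * halfCauchy(sd_e)
  # plus the exp-transform Jacobians
  y <- matrix(1.3, 1, 1)
  dat <- model_data(y, matrix(1, 1, 1))
  pr <- prior_config("lkj", cauchy_scale = 5)
  u <- c(z = 0.4, lsa = -0.2, lse = 0.3, mu = 0.7)
  hand <- function(z, lsa, lse, mu, yv = 1.3, cs = 5) {
    sa <- exp(lsa); se <- exp(lse)
    dnorm(yv, mu + sa * z, se, log = TRUE) +
      dnorm(z, log = TRUE) +
      (log(2) - log(pi * cs) - log1p((sa / cs)^2)) +
      (log(2) - log(pi * cs) - log1p((se / cs)^2)) +
      lsa + lse
  }
  got <- log_posterior(unname(u), dat, pr)
  expect_equal(got$logp, unname(hand(u[1], u[2], u[3], u[4])),
               tolerance = 1e-10)
})

test_that("likelihood equals a dense Kronecker-covariance MVN oracle", {
  n <- 4; t <- 2
  A <- rand_spd(n, 12)
  set.seed(13)
  y <- matrix(rnorm(n * t), n, t)
  dat <- model_data(y, A)
  u <- rnorm(mtvc:::param_dim(n, t), 0, 0.6)
  p <- constrain_transform(u, n, t)
  # breeding values under the model's own factor of A
  root <- dat$U %*% diag(dat$sqrt_d)
  a <- reconstruct_breeding_values(root, p$z_a, p$sd_a, p$L_corr_a)
  # dense 8x8 MVN likelihood of vec(y) ~ N(vec(mu + a), R0 (x) I)
  mu_mat <- matrix(p$mu, n, t, byrow = TRUE)
  V <- kronecker(p$R0, diag(n))
  r <- as.vector(y - mu_mat - a)
  dense <- -0.5 * n * t * log(2 * pi) - 0.5 * determinant(V)$modulus[1] -
    0.5 * sum(r * solve(V, r))
  # subtract everything except the likelihood from the joint
  pr <- prior_config("lkj")
  full <- log_posterior(u, dat, pr)$logp
  rest <- -0.5 * n * t * log(2 * pi) - 0.5 * sum(p$z_a^2) +
    lkj_cholesky_logpdf(p$L_corr_a, 1) + lkj_cholesky_logpdf(p$L_corr_e, 1) +
    sum(log(2) - log(5 * pi) - log1p((p$sd_a / 5)^2)) +
    sum(log(2) - log(5 * pi) - log1p((p$sd_e / 5)^2)) +
    p$log_jacobian
  expect_equal(full - rest, dense, tolerance = 1e-8)
})

test_that("gradients match central finite differences for both priors", {
  n <- 6; t <- 2
  A <- rand_spd(n, 7)
  set.seed(29)
  y <- matrix(rnorm(n * t, 0, 2), n, t)
  dat <- model_data(y, A)
  for (kind in c("lkj", "iw")) {
    pr <- prior_config(kind, eta = 1.5)
    D <- mtvc:::param_dim(n, t)
    for (rep in 1:10) {
      u <- rnorm(D, 0, 0.6)
      got <- log_posterior(u, dat, pr)
      h <- 1e-5
      fd <- vapply(seq_len(D), function(i) {
        up <- u; um <- u
        up[i] <- up[i] + h; um[i] <- um[i] - h
        (log_posterior(up, dat, pr)$logp -
           log_posterior(um, dat, pr)$logp) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(fd - got$grad) / pmax(abs(got$grad), 1)), 1e-5)
    }
  }
})

test_that("compiled and interpreted log-posterior agree exactly", {
  n <- 7; t <- 3
  A <- rand_spd(n, 3)
  set.seed(31)
  y <- matrix(rnorm(n * t), n, t)
  dat <- model_data(y, A)
  for (kind in c("lkj", "iw")) {
    pr <- prior_config(kind, eta = 0.7, v_A = 4, v_E = 5)
    ldR <- mtvc:::animal_model_logdensity(dat, pr, compiled = FALSE)
    ldC <- mtvc:::animal_model_logdensity(dat, pr, compiled = TRUE)
    for (rep in 1:10) {
      u <- rnorm(mtvc:::param_dim(n, t), 0, 0.8)
      a <- ldR(u); b <- ldC(u)
      expect_equal(a$logp, b$logp, tolerance = 1e-12)
      expect_equal(a$grad, as.vector(b$grad), tolerance = 1e-10)
    }
  }
})

test_that("data validation rejects incomplete or non-finite records", {
  A <- rand_spd(3, 1)
  y <- matrix(rnorm(6), 3, 2)
  y[2, 1] <- NA
  expect_error(model_data(y, A), "incomplete")
  y[2, 1] <- Inf
  expect_error(model_data(y, A), "finite")
})

test_that("posterior mean of the genetic variance matches quadrature on a tiny single-trait check", {
  # 4 animals, 1 trait: integrate mu analytically (flat prior) and the
  # scale parameters on a 2-D grid; compare with the NUTS posterior mean.
  # (With fewer than 3 animals the half-Cauchy tail makes the posterior
  # mean of the variance non-integrable, so 4 is the smallest sound size.)
  set.seed(41)
  A <- rand_spd(4, 19)
  y <- matrix(c(1.2, -0.4, 0.8, 2.1), 4, 1)
  marg <- function(sa, se) {
    V <- sa^2 * A + se^2 * diag(4)
    Vi <- solve(V)
    muhat <- sum(Vi %*% y) / sum(Vi)
    r <- y - muhat
    exp(-0.5 * determinant(V)$modulus[1] - 0.5 * log(sum(Vi)) -
          0.5 * sum(r * (Vi %*% r))) *
      (1 / (1 + (sa / 5)^2)) * (1 / (1 + (se / 5)^2))
  }
  gr <- exp(seq(log(0.02), log(60), length.out = 220))
  W <- outer(gr, gr, Vectorize(function(sa, se) marg(sa, se) * sa * se))
  # trapezoid in log space: weight sa*se already applied as Jacobian
  post_mean_sa2 <- sum(W * outer(gr^2, rep(1, length(gr)))) / sum(W)

  dat <- model_data(y, A)
  fit <- fit_nuts(y, A, prior_config("lkj"),
                  nuts_config(n_iter = 6000, n_warmup = 1000, seed = 2))
  draws <- fit$G0[1, 1, ]
  se_mc <- mcmc_se(draws)
  expect_lt(abs(mean(draws) - post_mean_sa2), 4 * se_mc + 0.02 * post_mean_sa2)
})
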
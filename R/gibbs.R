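#' Gibbs sampler configuration
#'
#' Defaults follow the study protocol: a single chain of 10,000
#' iterations, 1000 discarded as burn-in, thinning interval 10;
#' inverse-Wishart hyperparameters `S_A = S_E = I` and `v_A = v_E = t`
#' (filled at run time when `NULL`).
#'
#' @param n_iter Total iterations (default 10000).
#' @param burn_in Burn-in iterations (default 1000).
#' @param thin Thinning interval (default 10).
#' @param seed Integer seed.
#' @param S_A,S_E Inverse-Wishart scale hyperparameters.
#' @param v_A,v_E Inverse-Wishart degrees of freedom.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 10000L, burn_in = 1000L, thin = 10L,
                         seed = 1L, S_A = NULL, S_E = NULL, v_A = NULL,
                         v_E = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 S_A = S_A, S_E = S_E, v_A = v_A, v_E = v_E),
            class = "gibbs_config")
}

#' Draw from an inverse-Wishart distribution
#'
#' `X ~ IW(df, Psi)` with density proportional to
#' `|X|^{-(df+t+1)/2} exp(-tr(X^{-1} Psi)/2)`; the mean is
#' `Psi / (df - t - 1)` for `df > t + 1`. Implemented as the inverse of a
#' Wishart draw with scale `Psi^{-1}`.
#'
#' @param df Degrees of freedom, `>= t`.
#' @param Psi Symmetric positive-definite scale matrix.
#' @return A t x t symmetric positive-definite draw.
#' @export
rinvwishart <- function(df, Psi) {
  Psi <- as.matrix(Psi)
  t <- nrow(Psi)
  if (df < t) stop("inverse-Wishart needs df >= dimension")
  ev <- eigen((Psi + t(Psi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("inverse-Wishart scale matrix is not SPD")
  W <- stats::rWishart(1L, df, solve(Psi))[, , 1L]
  X <- solve(W)
  (X + t(X)) / 2
}

# Simultaneous diagonalization of (G0, R0): returns T with
# G0 = T^{-1} Phi T^{-T}, R0 = T^{-1} T^{-T}; in the transformed
# coordinates each eigen-component of A decouples.
whiten_pair <- function(G0, R0) {
  C <- t(chol(R0))                       # R0 = C C'
  Ci <- forwardsolve(C, diag(nrow(R0)))
  M <- Ci %*% G0 %*% t(Ci)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(T = t(e$vectors) %*% Ci, phi = pmax(e$values, 0))
}

# Precompute the pieces of the location full conditional that depend only
# on (y, A): the eigenbasis projections of the records and the intercept
# column.
location_precompute <- function(y, eig) {
  list(ystar = crossprod(eig$U, y), cvec = as.vector(crossprod(eig$U, rep(1, nrow(y)))),
       d = eig$d, U = eig$U, n = nrow(y), t = ncol(y))
}

#' Joint draw of intercepts and breeding values from their full conditional
#'
#' Samples `(mu, a)` jointly from the multivariate-normal full conditional
#' whose mean solves the mixed-model equations (intercept-only fixed
#' effects, `Z = I`) and whose covariance is the inverse MME coefficient
#' matrix. The draw is factorized through the eigendecomposition of the
#' relationship matrix: `mu` is drawn from its marginal conditional (with
#' `a` integrated out) and `a` from its conditional given `mu`, which is
#' the same joint distribution by the chain rule but costs `O(n t^3)`
#' instead of a dense `(n+1)t` Cholesky per sweep.
#'
#' @param loc A `location_precompute()` structure (built internally by
#'   [run_gibbs()] from `y` and the eigendecomposition of `A`).
#' @param G0,R0 Current t x t covariance draws (SPD).
#' @param draw If `FALSE`, return the conditional mean (the MME solution)
#'   instead of a random draw.
#' @return A list with `mu` (length t) and `a` (n x t).
#' @export
sample_location <- function(loc, G0, R0, draw = TRUE) {
  t <- loc$t
  wp <- whiten_pair(G0, R0)
  Tm <- wp$T
  denom <- outer(loc$d, wp$phi) + 1          # n x t: d_i phi_k + 1
  Yt <- loc$ystar %*% t(Tm)                  # row i = T y*_i
  cv <- loc$cvec
  # marginal conditional of mu: precision T' diag(sum_i c_i^2/denom) T
  s2 <- colSums(cv^2 / denom)
  b <- crossprod(Tm, colSums(cv * Yt / denom))
  P <- crossprod(Tm, Tm * s2)
  Rp <- chol((P + t(P)) / 2)
  mu_mean <- backsolve(Rp, forwardsolve(t(Rp), b))
  mu <- if (draw) {
    as.vector(mu_mean + backsolve(Rp, stats::rnorm(t)))
  } else as.vector(mu_mean)
  # conditional of the transformed genetic values given mu: independent
  # scalar posteriors with prior variance d_i phi_k and unit noise
  mt <- as.vector(Tm %*% mu)
  resid <- Yt - outer(cv, mt)
  vpost <- outer(loc$d, wp$phi) / denom
  alpha <- vpost * resid
  if (draw) {
    alpha <- alpha + sqrt(vpost) *
      matrix(stats::rnorm(loc$n * t), loc$n, t)
  }
  astar <- t(solve(Tm, t(alpha)))            # a*_i = T^{-1} alpha_i
  a <- loc$U %*% astar
  list(mu = mu, a = a)
}

#' Full-conditional draw of the genetic covariance matrix
#'
#' `G0 ~ IW(v_A + n, S_A^{-1} + a' A^{-1} a)`, the conjugate update of the
#' inverse-Wishart prior whose density carries `S_A^{-1}` inside the
#' trace.
#'
#' @param a Current n x t breeding-value draw.
#' @param eig Eigendecomposition of `A` from `grm_eigen()` (used for
#'   `A^{-1}`, computed once per run).
#' @param S_A Prior scale hyperparameter (default identity).
#' @param v_A Prior degrees of freedom (default t).
#' @return A t x t SPD draw.
#' @export
sample_genetic_covariance <- function(a, eig, S_A = NULL, v_A = NULL) {
  a <- as.matrix(a)
  t <- ncol(a)
  if (is.null(S_A)) S_A <- diag(t)
  if (is.null(v_A)) v_A <- t
  if (min(eig$d) <= 0) stop("A is singular even after jitter")
  q <- crossprod(crossprod(eig$U, a) / sqrt(eig$d))
  rinvwishart(v_A + nrow(a), solve(S_A) + q)
}

#' Full-conditional draw of the residual covariance matrix
#'
#' `R0 ~ IW(v_E + n_records, S_E^{-1} + e'e)` with `e = y - mu - a`.
#'
#' @param e Current n x t residual matrix.
#' @param S_E Prior scale hyperparameter (default identity).
#' @param v_E Prior degrees of freedom (default t).
#' @return A t x t SPD draw.
#' @export
sample_residual_covariance <- function(e, S_E = NULL, v_E = NULL) {
  e <- as.matrix(e)
  t <- ncol(e)
  if (is.null(S_E)) S_E <- diag(t)
  if (is.null(v_E)) v_E <- t
  rinvwishart(v_E + nrow(e), solve(S_E) + crossprod(e))
}

#' Run the conjugate Gibbs sampler for the multi-trait animal model
#'
#' Cycles location effects (joint `(mu, a)` block) -> genetic covariance
#' -> residual covariance; applies burn-in and thinning; reports posterior
#' means and standard deviations as the estimates and their standard
#' errors. Deterministic given `cfg$seed`.
#'
#' @param y n x t complete phenotype matrix.
#' @param A Relationship matrix (or `grm_eigen()` structure).
#' @param cfg A [gibbs_config()].
#' @return A `gibbs_samples` object: arrays `G0`, `R0` (t x t x kept),
#'   matrix `mu` (kept x t), `a_hat` (running posterior mean of `a`), and
#'   the configuration.
#' @export
run_gibbs <- function(y, A, cfg = gibbs_config()) {
  y <- as.matrix(y)
  if (anyNA(y) || !all(is.finite(y))) stop("incomplete or non-finite records")
  t <- ncol(y); n <- nrow(y)
  if (inherits(A, "relationship_matrix")) A <- A$A
  eig <- if (is.list(A) && !is.null(A$U)) A else grm_eigen(A)
  if (min(eig$d) <= 0) stop("A not positive definite after jitter")
  S_A <- if (is.null(cfg$S_A)) diag(t) else cfg$S_A
  S_E <- if (is.null(cfg$S_E)) diag(t) else cfg$S_E
  v_A <- if (is.null(cfg$v_A)) t else cfg$v_A
  v_E <- if (is.null(cfg$v_E)) t else cfg$v_E
  loc <- location_precompute(y, eig)

  rng <- local_rng(cfg$seed)
  on.exit(rng$restore())
  # init: half the phenotypic (co)variance to each component
  S0 <- stats::cov(y) / 2
  G0 <- S0; R0 <- S0
  n_keep <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  keep_G <- array(NA_real_, c(t, t, n_keep))
  keep_R <- array(NA_real_, c(t, t, n_keep))
  keep_mu <- matrix(NA_real_, n_keep, t)
  a_sum <- matrix(0, n, t)
  k <- 0L
  for (it in seq_len(cfg$n_iter)) {
    locdraw <- sample_location(loc, G0, R0)
    mu <- locdraw$mu; a <- locdraw$a
    G0 <- sample_genetic_covariance(a, eig, S_A, v_A)
    E <- y - a - rep(mu, each = n)
    R0 <- sample_residual_covariance(E, S_E, v_E)
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      k <- k + 1L
      keep_G[, , k] <- G0
      keep_R[, , k] <- R0
      keep_mu[k, ] <- mu
      a_sum <- a_sum + a
    }
  }
  structure(list(G0 = keep_G, R0 = keep_R, mu = keep_mu,
                 a_hat = a_sum / max(k, 1L), n_kept = k, config = cfg,
                 jitter = eig$jitter, method = "gibbs"),
            class = c("gibbs_samples", "mtvc_fit"))
}

#' @export
print.gibbs_samples <- function(x, ...) {
  cat(sprintf("gibbs_samples: %d kept draws, %d traits\n",
              x$n_kept, ncol(x$mu)))
  invisible(x)
}
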
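#' Trait architecture: genetic and residual covariance matrices
#'
#' Defines the simulation truth and the estimand of the multi-trait animal
#' model: the t x t additive-genetic covariance matrix `G0` and residual
#' covariance matrix `R0`. Both must be symmetric positive definite and
#' every implied heritability `G0_ii / (G0_ii + R0_ii)` must lie in (0, 1).
#'
#' @param G0,R0 Symmetric positive-definite t x t matrices.
#' @return A `trait_architecture` list with `G0`, `R0` and `t`.
#' @export
trait_architecture <- function(G0, R0) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  stopifnot(nrow(G0) == ncol(G0), nrow(R0) == ncol(R0),
            nrow(G0) == nrow(R0))
  check_spd <- function(M, name) {
    if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M)))) {
      stop(name, " is not symmetric")
    }
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(name, " is not positive definite")
  }
  check_spd(G0, "G0"); check_spd(R0, "R0")
  t <- nrow(G0)
  tn <- paste0("trait", seq_len(t))
  dimnames(G0) <- dimnames(R0) <- list(tn, tn)
  structure(list(G0 = G0, R0 = R0, t = t), class = "trait_architecture")
}

#' The two-trait architecture of the simulation study
#'
#' `G0 = [[1, 0.67], [0.67, 5]]`, `R0 = [[9, 0.67], [0.67, 5]]`, giving
#' heritabilities 0.1 and 0.5, genetic correlation ~0.30 and residual
#' correlation ~0.10.
#'
#' @return A [trait_architecture()].
#' @export
default_architecture <- function() {
  trait_architecture(G0 = matrix(c(1.0, 0.67, 0.67, 5.0), 2, 2),
                     R0 = matrix(c(9.0, 0.67, 0.67, 5.0), 2, 2))
}

#' Heritabilities and correlations implied by an architecture
#'
#' @param arch A [trait_architecture()].
#' @return A list with `h2` (per-trait heritabilities
#'   `G0_ii/(G0_ii + R0_ii)`), `genetic_correlation` and
#'   `residual_correlation` (t x t correlation matrices).
#' @export
implied_parameters <- function(arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  h2 <- diag(arch$G0) / (diag(arch$G0) + diag(arch$R0))
  list(h2 = h2,
       genetic_correlation = stats::cov2cor(arch$G0),
       residual_correlation = stats::cov2cor(arch$R0))
}

#' Simulate correlated multi-trait phenotypes on a relationship structure
#'
#' Draws breeding values `a` with `cov(vec a) = G0 (x) A` and residuals
#' `e` with `cov(vec e) = R0 (x) I`, then `y = a + e`. The Kronecker
#' structure is exploited: `a = L_A Z B'` with `Z` an n x t standard-normal
#' matrix and `B = chol(G0)` (lower), which has exactly the target
#' covariance without ever materializing the nt x nt matrix.
#'
#' @param A A `relationship_matrix`, a plain symmetric matrix, or a
#'   precomputed `grm_eigen()` structure.
#' @param arch A [trait_architecture()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param n_test Number of animals to assign (uniformly at random) to the
#'   test set; the rest form the training set. Default 0.
#' @return A `simulated_dataset` list: `y`, `a_true`, `e_true` (n x t
#'   matrices, `y = a_true + e_true` exactly), `train_ids`, `test_ids`
#'   (integer index sets partitioning the animals), `seed`, and `jitter`
#'   (diagonal jitter used to factorize `A`).
#' @export
simulate_traits <- function(A, arch, seed = 1L, n_test = 0L) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (inherits(A, "relationship_matrix")) A <- A$A
  if (is.matrix(A)) {
    ch <- cholesky_psd(A)
  } else if (is.list(A) && !is.null(A$L)) {
    ch <- A
  } else {
    stop("A must be a matrix, relationship_matrix or grm_eigen structure")
  }
  n <- nrow(ch$L)
  t <- arch$t
  if (n_test < 0L || n_test >= n) stop("n_test must be in [0, n)")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  Bg <- t(chol(arch$G0))
  Br <- t(chol(arch$R0))
  Za <- matrix(stats::rnorm(n * t), n, t)
  Ze <- matrix(stats::rnorm(n * t), n, t)
  a <- ch$L %*% Za %*% t(Bg)
  e <- Ze %*% t(Br)
  y <- a + e
  # store the residual as the representable difference so that
  # y - a - e == 0 holds exactly in floating point
  e <- y - a
  ids <- paste0("A", seq_len(n))
  tn <- paste0("trait", seq_len(t))
  dimnames(y) <- dimnames(a) <- dimnames(e) <- list(ids, tn)
  test_ids <- if (n_test > 0L) sort(sample.int(n, n_test)) else integer(0)
  train_ids <- setdiff(seq_len(n), test_ids)
  structure(list(y = y, a_true = a, e_true = e, train_ids = train_ids,
                 test_ids = test_ids, seed = as.integer(seed),
                 jitter = ch$jitter),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d animals x %d traits (%d train / %d test), seed %d\n",
              nrow(x$y), ncol(x$y), length(x$train_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Named simulation scenarios
#'
#' `"scenario1"`: 2314 animals (2000 train / 314 test); `"scenario2"`: 578
#' animals (500 train / 78 test). Both use the two-trait architecture of
#' [default_architecture()] and 10 replicates. A `scale` factor shrinks the
#' animal counts proportionally (preserving the train:test ratio to
#' rounding) for desk-scale runs.
#'
#' @param name `"scenario1"` or `"scenario2"`.
#' @param scale Positive scale factor applied to the animal counts.
#' @param n_replicates Number of simulation replicates (default 10).
#' @return A `scenario_config` list: `name`, `n_animals`, `n_train`,
#'   `n_test`, `architecture`, `n_replicates`.
#' @export
make_scenario <- function(name, scale = 1, n_replicates = 10L) {
  sizes <- list(scenario1 = c(train = 2000L, test = 314L),
                scenario2 = c(train = 500L, test = 78L))
  if (!name %in% names(sizes)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(sizes), collapse = ", "))
  }
  stopifnot(scale > 0)
  s <- sizes[[name]]
  n_train <- max(2L, as.integer(round(s["train"] * scale)))
  n_test <- as.integer(round(s["test"] * scale))
  structure(list(name = name, n_animals = n_train + n_test,
                 n_train = n_train, n_test = n_test,
                 architecture = default_architecture(),
                 n_replicates = as.integer(n_replicates)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config '%s': %d animals (%d train / %d test), %d replicates\n",
              x$name, x$n_animals, x$n_train, x$n_test, x$n_replicates))
  invisible(x)
}
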
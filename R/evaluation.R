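#' Replicate error metrics: RMSE, MAE and relative versions
#'
#' `RMSE = sqrt(mean((est - truth)^2))` and `MAE = mean(|est - truth|)`
#' over replicates, per parameter and method; relative metrics divide each
#' method's value by the reference method's (so the reference is exactly
#' 1.0).
#'
#' @param estimates Data frame with columns `method`, `replicate`,
#'   `parameter`, `estimate`: one point estimate (posterior mean) per
#'   replicate.
#' @param truth Named numeric vector of true parameter values (the values
#'   set in the simulation).
#' @param reference Method name whose metrics define the relative scale
#'   (default `"nuts-lkj"`); relative columns are `NA` when the reference
#'   is absent.
#' @return Data frame with `method`, `parameter`, `rmse`, `mae`,
#'   `rel_rmse`, `rel_mae`.
#' @export
error_metrics <- function(estimates, truth, reference = "nuts-lkj") {
  stopifnot(all(c("method", "replicate", "parameter", "estimate") %in%
                  names(estimates)))
  miss <- setdiff(unique(estimates$parameter), names(truth))
  if (length(miss)) stop("no true value for: ", paste(miss, collapse = ", "))
  agg <- function(f) {
    stats::aggregate(
      err ~ method + parameter,
      data = transform(estimates,
                       err = estimate - truth[as.character(parameter)]),
      FUN = f)
  }
  rmse <- agg(function(e) sqrt(mean(e^2)))
  mae <- agg(function(e) mean(abs(e)))
  out <- merge(rmse, mae, by = c("method", "parameter"),
               suffixes = c("_rmse", "_mae"))
  names(out)[names(out) == "err_rmse"] <- "rmse"
  names(out)[names(out) == "err_mae"] <- "mae"
  has_ref <- reference %in% out$method
  out$rel_rmse <- NA_real_
  out$rel_mae <- NA_real_
  if (has_ref) {
    ref <- out[out$method == reference, c("parameter", "rmse", "mae")]
    i <- match(out$parameter, ref$parameter)
    denom_r <- ref$rmse[i]
    denom_m <- ref$mae[i]
    bad <- (denom_r == 0 & out$rmse > 0) | (denom_m == 0 & out$mae > 0)
    if (any(bad)) {
      stop("relative metric undefined: reference metric is zero for ",
           paste(unique(out$parameter[bad]), collapse = ", "))
    }
    out$rel_rmse <- ifelse(denom_r == 0, 1, out$rmse / denom_r)
    out$rel_mae <- ifelse(denom_m == 0, 1, out$mae / denom_m)
  }
  out[order(out$method, out$parameter), ]
}

#' Derived genetic parameters from posterior covariance draws
#'
#' Per draw: heritabilities `h2_i = G0_ii / (G0_ii + R0_ii)` and the
#' off-diagonal genetic and residual correlations; posterior mean and SD
#' are computed per-draw-then-averaged (not as ratios of averaged
#' components).
#'
#' @param G0_draws,R0_draws t x t x k arrays of posterior draws.
#' @return A list with `draws` (matrices `h2`, `r_a`, `r_e`; one row per
#'   draw) and `summary` (data frame of posterior means and SDs).
#' @export
derived_parameters <- function(G0_draws, R0_draws) {
  stopifnot(length(dim(G0_draws)) == 3L, length(dim(R0_draws)) == 3L,
            all(dim(G0_draws) == dim(R0_draws)))
  t <- dim(G0_draws)[1L]
  k <- dim(G0_draws)[3L]
  lt <- which(lower.tri(diag(t)), arr.ind = TRUE)
  n_off <- nrow(lt)
  h2 <- matrix(NA_real_, k, t)
  r_a <- matrix(NA_real_, k, max(n_off, 1L))
  r_e <- matrix(NA_real_, k, max(n_off, 1L))
  for (d in seq_len(k)) {
    G <- G0_draws[, , d]; R <- R0_draws[, , d]
    for (M in list(G, R)) {
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) stop("non-SPD covariance draw at index ", d)
    }
    h2[d, ] <- diag(G) / (diag(G) + diag(R))
    if (n_off > 0L) {
      r_a[d, ] <- G[lt] / sqrt(diag(G)[lt[, 1L]] * diag(G)[lt[, 2L]])
      r_e[d, ] <- R[lt] / sqrt(diag(R)[lt[, 1L]] * diag(R)[lt[, 2L]])
    }
  }
  colnames(h2) <- sprintf("h2_trait%d", seq_len(t))
  if (n_off > 0L) {
    nm <- sprintf("_%d%d", lt[, 2L], lt[, 1L])
    colnames(r_a) <- paste0("r_a", nm)
    colnames(r_e) <- paste0("r_e", nm)
  }
  summarize <- function(m) data.frame(parameter = colnames(m),
                                      mean = colMeans(m),
                                      sd = apply(m, 2L, stats::sd),
                                      row.names = NULL)
  sm <- rbind(summarize(h2),
              if (n_off > 0L) summarize(r_a),
              if (n_off > 0L) summarize(r_e))
  list(draws = list(h2 = h2, r_a = r_a, r_e = r_e), summary = sm)
}

#' Accuracy and RMSE of estimated breeding values on a test set
#'
#' Per-trait Pearson correlation ("accuracy") and root-mean-square error
#' between true and estimated breeding values of test animals whose
#' phenotypes were withheld from the fit.
#'
#' @param a_true_test,a_hat_test n_test x t matrices.
#' @return Data frame with `trait`, `accuracy`, `rmse`.
#' @export
ebv_metrics <- function(a_true_test, a_hat_test) {
  a_true_test <- as.matrix(a_true_test)
  a_hat_test <- as.matrix(a_hat_test)
  stopifnot(all(dim(a_true_test) == dim(a_hat_test)))
  t <- ncol(a_true_test)
  res <- lapply(seq_len(t), function(j) {
    x <- a_true_test[, j]; y <- a_hat_test[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("accuracy undefined: zero variance in trait ", j)
    }
    data.frame(trait = j, accuracy = stats::cor(x, y),
               rmse = sqrt(mean((x - y)^2)))
  })
  do.call(rbind, res)
}

#' Project training breeding values onto test animals through the GRM
#'
#' With `cov(vec a) = G0 (x) A`, the conditional expectation of the test
#' animals' breeding values given the training animals' is
#' `A[test, train] A[train, train]^{-1} a_train` for every trait (the
#' trait covariance cancels), so the posterior-mean test EBVs follow from
#' the posterior-mean training EBVs by the same linear map.
#'
#' @param A Full relationship matrix (or `relationship_matrix`).
#' @param train,test Disjoint integer index vectors.
#' @param a_hat_train n_train x t posterior-mean breeding values.
#' @return n_test x t matrix of predicted test breeding values.
#' @export
predict_test_ebv <- function(A, train, test, a_hat_train) {
  if (inherits(A, "relationship_matrix")) A <- A$A
  if (length(intersect(train, test))) stop("train and test sets overlap")
  ch <- cholesky_psd(A[train, train, drop = FALSE])
  sol <- backsolve(t(ch$L), forwardsolve(ch$L, as.matrix(a_hat_train)))
  A[test, train, drop = FALSE] %*% sol
}
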
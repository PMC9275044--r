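# Shared fixture builders and independent oracles used across test files.

# Small SPD matrix with controlled conditioning.
rand_spd <- function(n, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n)
  crossprod(B) / n + diag(n)
}

# Brute-force VanRaden GRM: double loop, literal formula.
grm_oracle <- function(codes) {
  n <- nrow(codes); m <- ncol(codes)
  p <- colMeans(codes, na.rm = TRUE) / 2
  denom <- sum(2 * p * (1 - p))
  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i, j] <- if (is.na(codes[i, j])) 0 else codes[i, j] - 2 * p[j]
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    A[i, k] <- sum(M[i, ] * M[k, ]) / denom
  }
  A
}

# Per-SNP QC statistics by direct tallying (independent of snp_stats).
qc_oracle_keep <- function(codes, maf_min = 0.05, call_rate_min = 0.95,
                           hwe_p_min = 0.001) {
  n <- nrow(codes)
  keep <- logical(ncol(codes))
  for (j in seq_len(ncol(codes))) {
    g <- codes[, j]
    g <- g[!is.na(g)]
    cr <- length(g) / n
    if (length(g) == 0) { keep[j] <- FALSE; next }
    p <- mean(g) / 2
    maf <- min(p, 1 - p)
    if (p <= 0 || p >= 1) {
      hwe <- 1
    } else {
      obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
      exp <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
      hwe <- pchisq(sum((obs - exp)^2 / exp), df = 1, lower.tail = FALSE)
    }
    keep[j] <- maf >= maf_min && cr >= call_rate_min && hwe >= hwe_p_min
  }
  which(keep)
}

# Monte-Carlo standard error via the Geweke spectral variance estimate.
mcmc_se <- function(x) sqrt(mtvc:::spectrum0(x) / length(x))

# Tiny complete dataset on a fixed relationship structure.
toy_dataset <- function(n = 8, t = 2, seed = 3) {
  A <- rand_spd(n, seed)
  set.seed(seed + 1)
  arch <- default_architecture()
  sim <- simulate_traits(A, if (t == 2) arch else
    trait_architecture(diag(t), diag(t)), seed = seed + 2)
  list(A = A, y = sim$y, sim = sim)
}
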
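#' SNP genotype matrix
#'
#' Container for biallelic SNP genotypes coded as counts of the second
#' allele (0, 1 or 2), with `NA` marking missing calls. Rows are animals,
#' columns are SNPs.
#'
#' @param codes Integer or numeric matrix, n_animals x n_snps, entries in
#'   `{0, 1, 2}` or `NA`.
#' @param animal_ids Character vector of row identifiers (defaults to
#'   `A1..An`).
#' @param snp_ids Character vector of column identifiers (defaults to
#'   `S1..Sm`).
#' @return An object of class `genotype_matrix`: the validated codes matrix
#'   with dimnames set to the identifiers.
#' @export
genotype_matrix <- function(codes, animal_ids = NULL, snp_ids = NULL) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L) stop("need at least 2 animals")
  if (ncol(codes) < 1L) stop("need at least 1 SNP")
  vals <- codes[!is.na(codes)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  storage.mode(codes) <- "double"
  if (is.null(animal_ids)) animal_ids <- rownames(codes)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- colnames(codes)
  if (is.null(snp_ids)) snp_ids <- paste0("S", seq_len(ncol(codes)))
  stopifnot(length(animal_ids) == nrow(codes), length(snp_ids) == ncol(codes))
  dimnames(codes) <- list(as.character(animal_ids), as.character(snp_ids))
  structure(codes, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' SNP quality-control thresholds
#'
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum per-SNP call rate (default 0.95).
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium chi-square
#'   goodness-of-fit p-value (default 0.001).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.95,
                          hwe_p_min = 0.001) {
  for (v in c(maf_min, call_rate_min, hwe_p_min)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("QC thresholds must be single numbers in (0, 1)")
    }
  }
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

# Per-SNP genotype tallies on non-missing calls: counts of 0/1/2, call rate,
# second-allele frequency, and the 1-df HWE chi-square p-value.
snp_stats <- function(g) {
  n <- nrow(g)
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  nc <- n0 + n1 + n2
  call_rate <- nc / n
  p <- ifelse(nc > 0, (n1 + 2 * n2) / (2 * nc), NA_real_)
  maf <- pmin(p, 1 - p)
  # HWE chi-square goodness of fit, 1 df; expected counts from observed p.
  e0 <- nc * (1 - p)^2
  e1 <- nc * 2 * p * (1 - p)
  e2 <- nc * p^2
  chi2 <- rep(NA_real_, length(nc))
  ok <- !is.na(p) & p > 0 & p < 1
  chi2[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  hwe_p <- rep(NA_real_, length(nc))
  hwe_p[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  # Monomorphic SNPs carry no HWE evidence: p-value 1 by convention.
  hwe_p[!is.na(p) & (p == 0 | p == 1)] <- 1
  data.frame(snp = colnames(g), n0 = n0, n1 = n1, n2 = n2,
             call_rate = call_rate, freq = p, maf = maf, hwe_p = hwe_p,
             row.names = NULL)
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' Retains the SNPs with minor allele frequency at or above `maf_min`, call
#' rate at or above `call_rate_min` and HWE chi-square goodness-of-fit
#' p-value (1 df, computed on non-missing genotypes with expected counts
#' from the observed allele frequency) at or above `hwe_p_min`. Column
#' order is preserved. SNPs with zero non-missing calls fail the call-rate
#' rule and are never divided by.
#'
#' @param g A [genotype_matrix()].
#' @param thr A [qc_thresholds()] object.
#' @return A list with `genotypes` (the filtered `genotype_matrix`) and
#'   `kept` (integer indices of the retained SNPs in the input order).
#' @export
qc_filter <- function(g, thr = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(thr, "qc_thresholds"))
  st <- snp_stats(g)
  keep <- !is.na(st$maf) & st$maf >= thr$maf_min &
    st$call_rate >= thr$call_rate_min &
    !is.na(st$hwe_p) & st$hwe_p >= thr$hwe_p_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("empty panel: all SNPs removed by QC")
  kept <- which(keep)
  out <- genotype_matrix(unclass(g)[, kept, drop = FALSE],
                         animal_ids = rownames(g),
                         snp_ids = colnames(g)[kept])
  list(genotypes = out, kept = kept)
}

#' VanRaden genomic relationship matrix
#'
#' Computes `A = M M' / sum_j 2 p_j (1 - p_j)` where `m_ij = g_ij - 2 p_j`
#' and `p_j` is the observed frequency of the allele counted by the 0/1/2
#' coding. Missing genotypes are imputed to the SNP mean `2 p_j`
#' (equivalently `m_ij = 0`), which keeps the centering exact.
#'
#' @param g A [genotype_matrix()] that passed QC: every SNP must be
#'   polymorphic so that the denominator term `2 p (1 - p)` is positive.
#' @return A `relationship_matrix` object: a list with `A` (n x n symmetric
#'   matrix), `freq` (per-SNP allele frequencies) and `denom` (the scalar
#'   denominator).
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g) == 0L) stop("no SNPs in panel")
  st <- snp_stats(g)
  bad <- which(is.na(st$freq) | st$freq <= 0 | st$freq >= 1)
  if (length(bad)) {
    stop("monomorphic SNP(s) in panel: ",
         paste(utils::head(st$snp[bad], 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  }
  p <- st$freq
  M <- sweep(unclass(g), 2L, 2 * p, `-`)
  M[is.na(M)] <- 0
  denom <- sum(2 * p * (1 - p))
  A <- tcrossprod(M) / denom
  A <- (A + t(A)) / 2
  dimnames(A) <- list(rownames(g), rownames(g))
  structure(list(A = A, freq = p, denom = denom),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d animals, mean diag %.3f\n",
              nrow(x$A), mean(diag(x$A))))
  invisible(x)
}

#' Generate synthetic SNP genotypes
#'
#' Draws per-SNP second-allele frequencies `p_j ~ Uniform(maf_low,
#' maf_high)`. Unrelated animals receive `Binomial(2, p_j)` genotypes. If
#' `n_families > 0`, the first `2 * n_families` "parents" are simulated
#' internally and full-sib families are produced by gene dropping (each sib
#' inherits one uniformly chosen allele from each parent per SNP), so the
#' genomic relationship matrix has off-diagonal block structure; remaining
#' animals are unrelated.
#'
#' @param n_animals Number of animals (rows).
#' @param n_snps Number of SNPs (columns).
#' @param maf_low,maf_high Bounds of the uniform allele-frequency
#'   distribution, `0 < maf_low <= maf_high <= 0.5`.
#' @param n_families Number of full-sib families; `0` for a fully unrelated
#'   panel.
#' @param family_size Animals per full-sib family (default 10).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A [genotype_matrix()] with attributes `freq` (the drawn `p_j`)
#'   and `family` (integer family index per animal, 0 = unrelated).
#' @export
synthetic_genotypes <- function(n_animals, n_snps, maf_low = 0.05,
                                maf_high = 0.5, n_families = 0L,
                                family_size = 10L, seed = 1L) {
  stopifnot(maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            n_families >= 0, n_animals >= 2, n_snps >= 1)
  n_fam_animals <- n_families * family_size
  if (n_animals < 2 * n_families || n_fam_animals > n_animals) {
    stop("n_animals too small for the requested families")
  }
  rng <- local_rng(seed)
  on.exit(rng$restore())
  p <- stats::runif(n_snps, maf_low, maf_high)
  codes <- matrix(0, n_animals, n_snps)
  family <- integer(n_animals)
  if (n_families > 0L) {
    for (f in seq_len(n_families)) {
      # Two parents per family as ordered allele pairs; each sib draws one
      # allele from each parent per SNP (gene dropping).
      sire <- matrix(stats::rbinom(2L * n_snps, 1L, p), 2L, n_snps,
                     byrow = TRUE)
      dam <- matrix(stats::rbinom(2L * n_snps, 1L, p), 2L, n_snps,
                    byrow = TRUE)
      rows <- ((f - 1L) * family_size + 1L):(f * family_size)
      for (i in rows) {
        pick_s <- stats::runif(n_snps) < 0.5
        pick_d <- stats::runif(n_snps) < 0.5
        codes[i, ] <- ifelse(pick_s, sire[1L, ], sire[2L, ]) +
          ifelse(pick_d, dam[1L, ], dam[2L, ])
      }
      family[rows] <- f
    }
  }
  n_unrel <- n_animals - n_fam_animals
  if (n_unrel > 0L) {
    rows <- (n_fam_animals + 1L):n_animals
    codes[rows, ] <- matrix(
      stats::rbinom(n_unrel * n_snps, 2L, rep(p, each = n_unrel)),
      n_unrel, n_snps)
  }
  g <- genotype_matrix(codes)
  attr(g, "freq") <- p
  attr(g, "family") <- family
  g
}

#' Cholesky factorization with diagonal jitter escalation
#'
#' Attempts `chol(A)`; on failure adds `jitter * I` with jitter escalating
#' through `{1e-10, 1e-8, 1e-6} * mean(diag(A))` until the factorization
#' succeeds. Returns the lower-triangular factor.
#'
#' @param A Symmetric matrix (checked to 1e-10 relative asymmetry).
#' @param jitter_policy Numeric vector of relative jitter levels to try
#'   after the unjittered attempt.
#' @return A list with `L` (lower-triangular, `L %*% t(L) = A + jitter*I`)
#'   and `jitter` (the absolute jitter used, 0 if none).
#' @export
cholesky_psd <- function(A, jitter_policy = c(1e-10, 1e-8, 1e-6)) {
  A <- as.matrix(A)
  asym <- max(abs(A - t(A)))
  if (asym > 1e-10 * max(1, max(abs(A)))) stop("matrix is not symmetric")
  A <- (A + t(A)) / 2
  scale <- mean(diag(A))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (j in c(0, jitter_policy * scale)) {
    R <- tryCatch(chol(A + diag(j, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(L = t(R), jitter = j))
    }
  }
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf(
    "matrix indefinite after maximum jitter; most negative eigenvalue %.3e",
    ev))
}

# Eigendecomposition of a relationship matrix (jittered to PD), cached form
# used by both samplers: A + jitter*I = U diag(d) U'.
grm_eigen <- function(A, jitter_policy = c(1e-10, 1e-8, 1e-6)) {
  if (inherits(A, "relationship_matrix")) A <- A$A
  ch <- cholesky_psd(A, jitter_policy)
  Aj <- (A + t(A)) / 2 + diag(ch$jitter, nrow(A))
  e <- eigen(Aj, symmetric = TRUE)
  d <- pmax(e$values, 0)
  list(U = e$vectors, d = d, L = ch$L, jitter = ch$jitter, A = Aj)
}

# Seed scoping: apply a seed inside a function without disturbing the
# caller's RNG stream.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}
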
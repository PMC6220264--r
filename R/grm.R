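# Genetic relationship matrix construction, relatedness pruning and
# GRM principal components.

#' Compute a genetic relationship matrix from a genotype panel
#'
#' `G[i, j] = (1/m) * sum_k (x[i,k] - 2 p_k)(x[j,k] - 2 p_k) /
#' (2 p_k (1 - p_k))` with `p_k` the sample allele frequency, i.e. the
#' average product of standardized dosages — the usual GCTA-style GRM.
#' Missing dosages are mean-imputed per SNP; monomorphic SNPs carry no
#' information about relatedness and are excluded.
#'
#' @param panel A `genotype_panel` (or any list with a numeric `dosages`
#'   matrix and `sample_ids`/`snp_ids`).
#' @param strict_monomorphic If `TRUE`, monomorphic SNPs raise an error
#'   listing their ids instead of being dropped with a warning.
#' @return A `grm` object: list with `G` (n x n symmetric matrix),
#'   `sample_ids` and `n_snps` (SNPs actually used per entry).
#' @examples
#' panel <- simulate_genotypes(100, 1000, seed = 1)
#' grm <- compute_grm(panel)
#' mean(diag(grm$G))  # close to 1 under HWE
#' @export
compute_grm <- function(panel, strict_monomorphic = FALSE) {
  X <- panel$dosages
  if (!is.matrix(X) || ncol(X) < 2) {
    stop("panel must contain a dosage matrix with at least 2 SNPs",
         call. = FALSE)
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    ids <- panel$snp_ids[mono]
    if (strict_monomorphic) {
      stop("monomorphic SNP(s): ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping ", sum(mono), " monomorphic SNP(s)")
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  m <- ncol(X)
  if (m < 2) stop("fewer than 2 polymorphic SNPs remain", call. = FALSE)
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / m
  dimnames(G) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(G = G, sample_ids = panel$sample_ids, n_snps = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", nrow(x$G), "individuals,", x$n_snps, "SNPs;",
      sprintf("mean diagonal %.3f\n", mean(diag(x$G))))
  invisible(x)
}

#' Prune related individuals from a GRM
#'
#' Removes one member of every pair whose relatedness exceeds `cutoff`
#' (default 0.025, roughly the relatedness of fifth cousins) so that the
#' remaining sample relies only on chance genetic similarity. The rule is
#' deterministic given the sample ordering: pairs are scanned in id order
#' and the later member of each offending pair is dropped.
#'
#' @param grm A `grm` object.
#' @param cutoff Relatedness threshold above which a pair is pruned.
#' @return Character vector of retained sample ids (attribute `removed`
#'   lists the dropped ids).
#' @export
prune_related <- function(grm, cutoff = 0.025) {
  G <- grm$G
  n <- nrow(G)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    js <- which(keep & seq_len(n) > i & G[i, ] > cutoff)
    keep[js] <- FALSE
  }
  out <- grm$sample_ids[keep]
  attr(out, "removed") <- grm$sample_ids[!keep]
  out
}

#' Subset a GRM to a set of individuals
#'
#' @param grm A `grm` object.
#' @param ids Sample ids to retain (e.g. the output of [prune_related()]).
#' @return The subsetted `grm`.
#' @export
subset_grm <- function(grm, ids) {
  idx <- match(ids, grm$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  structure(list(G = grm$G[idx, idx, drop = FALSE],
                 sample_ids = grm$sample_ids[idx], n_snps = grm$n_snps),
            class = "grm")
}

#' Principal components of a GRM
#'
#' The top-`k` eigenvectors of the relatedness matrix, scaled by the square
#' roots of their eigenvalues — the standard ancestry covariates used to
#' control for population stratification.
#'
#' @param grm A `grm` object.
#' @param k Number of components, `k < n`.
#' @return An `n x k` matrix of scaled PCs; attributes `eigenvalues` and
#'   `vectors` carry the unscaled decomposition.
#' @export
grm_pca <- function(grm, k = 10) {
  n <- nrow(grm$G)
  if (k >= n) stop("k must be smaller than the sample size", call. = FALSE)
  e <- eigen(grm$G, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  pcs <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(pcs) <- grm$sample_ids
  colnames(pcs) <- paste0("PC", seq_len(k))
  attr(pcs, "eigenvalues") <- e$values
  attr(pcs, "vectors") <- e$vectors[, seq_len(k), drop = FALSE]
  pcs
}
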
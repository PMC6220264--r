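# Polygenic scoring and incremental prediction.

#' Compute polygenic scores from a genotype panel and weight table
#'
#' Scores are the weighted sums of each individual's dosages over the SNPs
#' shared between the panel and the weight table. Weights whose effect
#' allele is the panel's non-counted allele are applied to the flipped
#' dosage (`2 - x`); weights naming an allele absent from the panel's pair
#' are dropped and counted. Scores are z-standardized.
#'
#' @param panel A `genotype_panel`.
#' @param weights A `data.frame` with columns `snp_id`, `effect_allele`,
#'   `weight` (see [read_weight_table()]).
#' @return Standardized score vector (named by sample id) with attributes
#'   `n_matched` and `n_dropped`. If every matched weight is zero the
#'   unstandardized all-zero score is returned with a warning.
#' @export
polygenic_score <- function(panel, weights) {
  stopifnot(all(c("snp_id", "effect_allele", "weight") %in% names(weights)))
  if (anyDuplicated(weights$snp_id)) {
    stop("weight table has duplicated snp ids", call. = FALSE)
  }
  idx <- match(weights$snp_id, panel$snp_ids)
  ok <- !is.na(idx)
  allele_ok <- rep(FALSE, nrow(weights))
  flip <- rep(FALSE, nrow(weights))
  allele_ok[ok] <- weights$effect_allele[ok] == panel$a1[idx[ok]] |
    weights$effect_allele[ok] == panel$a2[idx[ok]]
  flip[ok] <- weights$effect_allele[ok] == panel$a2[idx[ok]]
  use <- ok & allele_ok
  n_dropped <- sum(!use)
  if (!any(use)) stop("zero weights matched the panel", call. = FALSE)
  if (n_dropped > 0) {
    message(n_dropped, " weight(s) dropped (unmatched snp id or allele)")
  }
  X <- panel$dosages[, idx[use], drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  w <- weights$weight[use]
  X[, flip[use]] <- 2 - X[, flip[use]]
  score <- drop(X %*% w)
  s <- stats::sd(score)
  if (!is.finite(s) || s == 0) {
    warning("score has zero variance; returning unstandardized values")
  } else {
    score <- (score - mean(score)) / s
  }
  names(score) <- panel$sample_ids
  attr(score, "n_matched") <- sum(use)
  attr(score, "n_dropped") <- n_dropped
  score
}

#' Incremental R-squared of a predictor beyond a baseline model
#'
#' Fits the outcome on the baseline covariates with and without the added
#' predictor and returns the increase in R-squared — the usual estimate of
#' the variance a polygenic score explains over, e.g., ancestry principal
#' components.
#'
#' @param y Outcome vector.
#' @param baseline Matrix (or vector) of baseline covariates; an intercept
#'   is always included. `NULL` for an intercept-only baseline.
#' @param addition Vector (or matrix) of added predictor(s).
#' @return The difference in R-squared (non-negative up to numerical
#'   tolerance). Invariant to affine transformations of `addition`.
#' @export
incremental_r2 <- function(y, baseline, addition) {
  n <- length(y)
  B <- if (is.null(baseline)) matrix(numeric(0), n, 0) else
    as.matrix(baseline)
  A <- as.matrix(addition)
  if (nrow(B) != n || nrow(A) != n) {
    stop("baseline and addition must be row-aligned with y", call. = FALSE)
  }
  keep <- is.finite(y) & rowSums(!is.finite(B)) == 0 &
    rowSums(!is.finite(A)) == 0
  y <- y[keep]; B <- B[keep, , drop = FALSE]; A <- A[keep, , drop = FALSE]
  X0 <- cbind(rep(1, length(y)), B)
  if (qr(X0)$rank < ncol(X0)) {
    stop("rank-deficient baseline design", call. = FALSE)
  }
  X1 <- cbind(X0, A)
  if (qr(X1)$rank < ncol(X1)) {
    stop("rank-deficient design after adding the predictor", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- function(X) 1 - sum(stats::lm.fit(X, y)$residuals^2) / ss_tot
  r2(X1) - r2(X0)
}

#' Age-specific polygenic-score prediction beyond earlier achievement
#'
#' The incremental R-squared of a polygenic score for achievement at one
#' age once ancestry principal components and achievement at all earlier
#' ages are already in the model. When the score's prediction operates
#' through a stable component carried by earlier achievement, this
#' age-specific increment is small (below 1% of variance in the default
#' simulated cohorts).
#'
#' @param y_t Achievement at the target age.
#' @param gps Polygenic score vector.
#' @param prior_achievement Matrix of achievement at all earlier ages.
#' @param pcs Optional matrix of ancestry principal components.
#' @return The age-specific incremental R-squared.
#' @export
age_specific_gps_r2 <- function(y_t, gps, prior_achievement, pcs = NULL) {
  baseline <- cbind(pcs, as.matrix(prior_achievement))
  incremental_r2(y_t, baseline, gps)
}
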
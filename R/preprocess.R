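# Phenotype preparation: covariate residualization, rank-based
# normalization, composites, descriptive group statistics, and
# regression-based control for general cognitive ability.

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.vector(covariates) && !is.list(covariates)) {
    covariates <- matrix(covariates, ncol = 1,
                         dimnames = list(NULL, "covariate"))
  }
  if (is.data.frame(covariates)) {
    covariates <- stats::model.matrix(~ . - 1, data = covariates)
  }
  if (!is.matrix(covariates) || nrow(covariates) != n) {
    stop("covariates must be row-aligned with the phenotype", call. = FALSE)
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
  }
  covariates
}

#' Residualize a phenotype on covariates and standardize
#'
#' Fits an ordinary least-squares regression of the phenotype on the
#' covariates (age and sex in the canonical use) and rescores the variable
#' as the standardized residual (mean 0, sd 1 over non-missing entries).
#' This removes mean effects that would otherwise inflate twin estimates of
#' the shared environment, because co-twins are identical in age and MZ
#' co-twins in sex.
#'
#' @param pheno Numeric vector, missing values allowed.
#' @param covariates Vector, matrix or data frame row-aligned with `pheno`.
#'   An intercept is always added.
#' @param fit_subset Optional index vector: the regression coefficients are
#'   estimated on these rows only (e.g. one randomly selected twin per
#'   family to avoid double-counting) and then applied to every row.
#' @return Standardized residual vector; missing entries stay missing. If
#'   the covariates explain the phenotype exactly, a zero vector is
#'   returned with attribute `degenerate = TRUE` and a warning.
#' @examples
#' age <- runif(100, 6, 8)
#' y <- 2 * age + rnorm(100)
#' r <- residualize(y, age)
#' round(c(mean(r), sd(r), cor(r, age)), 8)
#' @export
residualize <- function(pheno, covariates, fit_subset = NULL) {
  n <- length(pheno)
  X <- cbind(`(Intercept)` = 1, as_covariate_matrix(covariates, n))
  obs <- which(is.finite(pheno) & rowSums(!is.finite(X)) == 0)
  if (length(obs) == 0) stop("all phenotype values are missing", call. = FALSE)
  if (stats::var(pheno[obs]) == 0) {
    stop("phenotype is constant; nothing to residualize", call. = FALSE)
  }
  fit_rows <- if (is.null(fit_subset)) obs else intersect(obs, fit_subset)
  if (length(fit_rows) <= ncol(X)) {
    stop("too few complete rows to estimate the regression", call. = FALSE)
  }
  qrX <- qr(X[fit_rows, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariates: column(s) ",
         paste(bad, collapse = ", "), " are linearly dependent",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, pheno[fit_rows])
  out <- rep(NA_real_, n)
  out[obs] <- pheno[obs] - drop(X[obs, , drop = FALSE] %*% beta)
  s <- stats::sd(out[obs])
  if (!is.finite(s) || s < 1e-12) {
    warning("covariates explain the phenotype exactly; returning zeros")
    out[obs] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out[obs] <- (out[obs] - mean(out[obs])) / s
  out
}

#' Rank-based van der Waerden transformation
#'
#' Maps the value with rank `r` among `n` non-missing observations to the
#' standard-normal quantile at `r / (n + 1)`, correcting skew by forcing the
#' marginal distribution onto a normal shape. Ties receive the quantile of
#' their mid-rank. The output is invariant to any strictly monotone
#' transformation of the input.
#'
#' @param pheno Numeric vector with at least 3 non-missing values.
#' @return Transformed vector; missing entries stay missing.
#' @examples
#' vdw_transform(c(10, 20, 30))  # quantiles at 0.25, 0.50, 0.75
#' @export
vdw_transform <- function(pheno) {
  obs <- which(is.finite(pheno))
  if (length(obs) < 3) {
    stop("at least 3 non-missing values are required", call. = FALSE)
  }
  x <- pheno[obs]
  if (max(x) == min(x)) {
    stop("all values identical; ranks carry no information", call. = FALSE)
  }
  out <- rep(NA_real_, length(pheno))
  out[obs] <- stats::qnorm(rank(x, ties.method = "average") /
                             (length(x) + 1))
  out
}

#' Composite score as the mean of standardized components
#'
#' Each component is z-scored over its non-missing entries and the
#' composite is the per-individual mean of whatever components are
#' available, provided at least `min_available` are present — so an
#' individual missing one source still receives a score from the others.
#'
#' @param components List of row-aligned numeric vectors.
#' @param min_available Minimum number of non-missing components required.
#' @return Numeric composite vector (NA where fewer than `min_available`
#'   components are present).
#' @export
composite_mean <- function(components, min_available = 1) {
  if (!is.list(components) || length(components) == 0) {
    stop("components must be a non-empty list", call. = FALSE)
  }
  if (min_available < 1) stop("min_available must be >= 1", call. = FALSE)
  n <- length(components[[1]])
  if (any(vapply(components, length, 1L) != n)) {
    stop("components must be row-aligned", call. = FALSE)
  }
  Z <- vapply(components, function(v) {
    obs <- is.finite(v)
    z <- rep(NA_real_, n)
    z[obs] <- (v[obs] - mean(v[obs])) / stats::sd(v[obs])
    z
  }, numeric(n))
  Z <- matrix(Z, nrow = n)
  k <- rowSums(is.finite(Z))
  out <- rowMeans(Z, na.rm = TRUE)
  out[k < min_available] <- NA_real_
  out
}

#' Variance in a phenotype explained by sex and zygosity
#'
#' Eta-squared (between-groups sum of squares over total) from a two-factor
#' ANOVA of the phenotype on sex, zygosity and their interaction. Used to
#' verify that mean group differences account for a trivial share of
#' variance before pooling sexes and zygosity groups.
#'
#' @param pheno Numeric vector.
#' @param sex,zygosity Factors (or coercible), each with at least 2 levels
#'   among the non-missing rows.
#' @return Eta-squared as a fraction in `[0, 1]`.
#' @export
variance_explained_by_groups <- function(pheno, sex, zygosity) {
  keep <- is.finite(pheno) & !is.na(sex) & !is.na(zygosity)
  d <- data.frame(y = pheno[keep], sex = factor(sex[keep]),
                  zyg = factor(zygosity[keep]))
  if (nlevels(d$sex) < 2) stop("factor sex has a single level", call. = FALSE)
  if (nlevels(d$zyg) < 2) {
    stop("factor zygosity has a single level", call. = FALSE)
  }
  fit <- stats::lm(y ~ sex * zyg, data = d)
  ss_tot <- sum((d$y - mean(d$y))^2)
  1 - sum(stats::resid(fit)^2) / ss_tot
}

#' Regress general cognitive ability out of achievement measures
#'
#' Replaces each phenotype by its standardized residual from an OLS
#' regression on the g composite, so that downstream twin analyses describe
#' achievement variance independent of intelligence.
#'
#' @param phenos List of numeric vectors (or a single vector).
#' @param g Numeric vector of the g composite, row-aligned, non-constant.
#' @return List of standardized residual vectors (same names as input).
#' @export
regress_out_g <- function(phenos, g) {
  single <- !is.list(phenos)
  if (single) phenos <- list(phenos)
  obs_g <- is.finite(g)
  if (sum(obs_g) < 3 || stats::var(g[obs_g]) == 0) {
    stop("g must be non-constant with at least 3 observed values",
         call. = FALSE)
  }
  out <- lapply(phenos, residualize, covariates = cbind(g = g))
  if (single) out[[1]] else out
}
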
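# Multi-group covariance-structure likelihood. Estimation works on the
# per-zygosity sample covariance of the stacked pair vector (twin 1
# measures, twin 2 measures), computed from complete-case pairs with the
# maximum-likelihood divisor n, so that the saturated -2lnL is attained
# exactly when the implied covariance equals the sample covariance.

#' Per-zygosity sample covariances of a twin-pair table
#'
#' Extracts, for the MZ and DZ groups (opposite-sex DZ pairs are pooled
#' with same-sex DZ pairs), the complete-case sample covariance of the
#' stacked vector of both twins' measures.
#'
#' @param data A `twin_pairs` data frame (one row per pair) with columns
#'   `<measure>_1` and `<measure>_2` per measure, or an existing
#'   `group_covariances` object (returned unchanged).
#' @param measures Character vector of measure labels, in occasion order
#'   for longitudinal models.
#' @param min_pairs Minimum number of complete pairs required per group.
#' @return A `group_covariances` object: list with `MZ` and `DZ` elements
#'   (each `S`, the ML covariance, and `n`), plus `labels`.
#' @export
group_covariances <- function(data, measures, min_pairs = 3) {
  if (inherits(data, "group_covariances")) return(data)
  cols <- c(paste0(measures, "_1"), paste0(measures, "_2"))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("twin-pair table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  zyg <- ifelse(data$zygosity == "MZ", "MZ", "DZ")
  out <- list(labels = measures)
  for (g in c("MZ", "DZ")) {
    M <- as.matrix(data[zyg == g, cols, drop = FALSE])
    M <- M[stats::complete.cases(M), , drop = FALSE]
    n <- nrow(M)
    if (n < max(min_pairs, 3)) {
      stop("group ", g, " has only ", n, " complete pairs (need at least ",
           max(min_pairs, 3), ")", call. = FALSE)
    }
    S <- stats::cov(M) * (n - 1) / n
    dimnames(S) <- list(cols, cols)
    out[[g]] <- list(S = S, n = n)
  }
  structure(out, class = "group_covariances")
}

#' Assemble group covariances from explicit matrices
#'
#' Convenience constructor used for noiseless "oracle" fits: supply the
#' MZ and DZ pair covariance matrices directly (e.g. exact model-implied
#' covariances) together with nominal sample sizes.
#'
#' @param S_mz,S_dz Symmetric `2p x 2p` pair covariance matrices.
#' @param n_mz,n_dz Nominal group sample sizes.
#' @param labels Measure labels (length `p`).
#' @return A `group_covariances` object.
#' @export
group_covariances_from_matrices <- function(S_mz, S_dz, n_mz, n_dz, labels) {
  stopifnot(nrow(S_mz) == ncol(S_mz), all(dim(S_mz) == dim(S_dz)),
            nrow(S_mz) == 2 * length(labels))
  if (max(abs(S_mz - t(S_mz))) > 1e-8 || max(abs(S_dz - t(S_dz))) > 1e-8) {
    stop("covariance matrices must be symmetric", call. = FALSE)
  }
  structure(list(labels = labels,
                 MZ = list(S = (S_mz + t(S_mz)) / 2, n = n_mz),
                 DZ = list(S = (S_dz + t(S_dz)) / 2, n = n_dz)),
            class = "group_covariances")
}

#' @export
print.group_covariances <- function(x, ...) {
  cat("Twin group covariances over", length(x$labels), "measure(s):",
      "MZ n =", x$MZ$n, ", DZ n =", x$DZ$n, "\n")
  invisible(x)
}

# -2 log-likelihood of one group's sample covariance under an implied
# covariance: n * (p log 2pi + log|Sigma| + tr(S Sigma^-1)). A non-positive-
# definite implied covariance gets a large smooth penalty so optimizers are
# pushed back into the feasible region; the returned value then carries
# attr(, "nonpd").
wishart_group_neg2ll <- function(S, n, sigma) {
  p <- nrow(S)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-10)) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    pen <- n * (p * (log(2 * pi) + 1) + 1e4 * (1 + sum(pmax(1e-8 - ev, 0))))
    attr(pen, "nonpd") <- TRUE
    return(pen)
  }
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  n * (p * log(2 * pi) + logdet + tr)
}

#' Multi-group Wishart -2 log-likelihood of a twin model
#'
#' Sums, over the MZ and DZ groups, the multivariate-normal covariance
#' likelihood of the sample covariance given the model-implied pair
#' covariance. Equals [saturated_neg2ll()] exactly when the implied
#' covariance reproduces the sample covariance in both groups; any other
#' implied structure gives a larger value.
#'
#' @param params A twin-model parameter object (see [implied_covariance()]).
#' @param data A `group_covariances` object (or a `twin_pairs` table, in
#'   which case `measures` must be supplied).
#' @param measures Measure labels, required when `data` is a raw table.
#' @return The -2 log-likelihood (lower is better). If the implied
#'   covariance is not positive definite the value is a large penalty and
#'   carries attribute `nonpd`.
#' @export
neg2ll <- function(params, data, measures = NULL) {
  if (!inherits(data, "group_covariances")) {
    if (is.null(measures)) {
      stop("supply measures to build group covariances from a raw table",
           call. = FALSE)
    }
    data <- group_covariances(data, measures)
  }
  val <- 0; nonpd <- FALSE
  for (g in c("MZ", "DZ")) {
    sg <- implied_covariance(params, g)
    v <- wishart_group_neg2ll(data[[g]]$S, data[[g]]$n, sg)
    if (isTRUE(attr(v, "nonpd"))) nonpd <- TRUE
    val <- val + as.numeric(v)
  }
  if (nonpd) attr(val, "nonpd") <- TRUE
  val
}

#' Saturated-model -2 log-likelihood
#'
#' The lower bound of [neg2ll()] over all covariance structures: each
#' group's implied covariance set equal to its sample covariance.
#'
#' @param data A `group_covariances` object.
#' @return The saturated -2 log-likelihood.
#' @export
saturated_neg2ll <- function(data) {
  stopifnot(inherits(data, "group_covariances"))
  val <- 0
  for (g in c("MZ", "DZ")) {
    S <- data[[g]]$S; n <- data[[g]]$n; p <- nrow(S)
    val <- val + n * (p * log(2 * pi) + determinant(S)$modulus[1] + p)
  }
  as.numeric(val)
}
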
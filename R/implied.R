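#' Per-component within-twin covariance matrices
#'
#' Internal generic that returns the covariance each latent source (A, C, E)
#' contributes to the vector of measures on a single twin.
#'
#' @param params A parameter object (`ace_params`, `cholesky_params`,
#'   `simplex_params` or `cpm_params`).
#' @return A list with elements `A`, `C`, `E`, each a `p x p` matrix.
#' @keywords internal
component_covariances <- function(params) UseMethod("component_covariances")

#' @export
component_covariances.ace_params <- function(params) {
  list(A = matrix(params$a2), C = matrix(params$c2), E = matrix(params$e2))
}

#' @export
component_covariances.cholesky_params <- function(params) {
  list(A = tcrossprod(params$L_A),
       C = tcrossprod(params$L_C),
       E = tcrossprod(params$L_E))
}

# Covariance of a latent first-order autoregression plus occasion-specific
# variance: var recursion V_t = beta_{t-1}^2 V_{t-1} + innov_t^2,
# cov(s, t) = V_s * prod(beta_s .. beta_{t-1}) for s < t.
simplex_component_cov <- function(comp) {
  p <- length(comp$beta) + 1L
  V <- numeric(p)
  V[1] <- comp$init_sd^2
  for (t in seq_len(p - 1L) + 1L) {
    V[t] <- comp$beta[t - 1L]^2 * V[t - 1L] + comp$innov_sd[t - 1L]^2
  }
  S <- diag(V, nrow = p)
  for (s in seq_len(p - 1L)) {
    acc <- V[s]
    for (t in (s + 1L):p) {
      acc <- acc * comp$beta[t - 1L]
      S[s, t] <- S[t, s] <- acc
    }
  }
  S + diag(comp$spec_sd^2, nrow = p)
}

#' @export
component_covariances.simplex_params <- function(params) {
  list(A = simplex_component_cov(params$A),
       C = simplex_component_cov(params$C),
       E = simplex_component_cov(params$E))
}

#' @export
component_covariances.cpm_params <- function(params) {
  ll <- tcrossprod(params$loadings)
  list(A = params$latent_a^2 * ll + diag(params$resid_a2),
       C = params$latent_c^2 * ll + diag(params$resid_c2),
       E = params$latent_e^2 * ll + diag(params$resid_e2))
}

# Phenotypic (within-twin) covariance implied by any parameter object.
implied_phenotypic_cov <- function(params) {
  comp <- component_covariances(params)
  comp$A + comp$C + comp$E
}

#' Model-implied twin-pair covariance matrix
#'
#' Builds the `2p x 2p` covariance of the stacked vector (twin 1 measures,
#' twin 2 measures) implied by a twin model. Within-twin blocks are
#' `Sigma_A + Sigma_C + Sigma_E`; cross-twin blocks weight the additive
#' genetic covariance by 1 for MZ pairs and 0.5 for DZ pairs (who share on
#' average half of their segregating genes), keep the shared-environment
#' covariance at weight 1 for both zygosities, and give the non-shared
#' environment weight 0.
#'
#' @param params A parameter object: [ace_params()], [cholesky_params()],
#'   [simplex_params()] or [cpm_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param labels Optional character vector of measure names used to label
#'   rows/columns (suffixed `_1` and `_2` for the two twins).
#' @return A symmetric positive semi-definite matrix of order `2p`.
#' @examples
#' implied_covariance(ace_params(0.6, 0.2, 0.2), "MZ")
#' @export
implied_covariance <- function(params, zygosity = c("MZ", "DZ"),
                               labels = NULL) {
  zygosity <- match.arg(zygosity)
  comp <- component_covariances(params)
  w <- if (zygosity == "MZ") 1 else 0.5
  within <- comp$A + comp$C + comp$E
  cross <- w * comp$A + comp$C
  sigma <- rbind(cbind(within, cross), cbind(cross, within))
  p <- nrow(within)
  if (!is.null(labels)) {
    stopifnot(length(labels) == p)
    dimnames(sigma) <- rep(list(c(paste0(labels, "_1"), paste0(labels, "_2"))), 2)
  }
  sigma
}
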
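#' Variance-component parameters for the univariate ACE model
#'
#' Bundles the standardized variance proportions attributed to additive
#' genetic (A), shared environmental (C) and non-shared environmental (E)
#' influences. The three proportions must be non-negative and sum to one.
#'
#' @param a2 Proportion of phenotypic variance due to additive genetic
#'   effects, in `[0, 1]`.
#' @param c2 Proportion due to environment shared by both members of a twin
#'   pair, in `[0, 1]`.
#' @param e2 Proportion due to environment unique to each twin (including
#'   measurement error), in `[0, 1]`.
#' @return An object of class `ace_params`.
#' @examples
#' ace_params(0.6, 0.2, 0.2)
#' @export
ace_params <- function(a2, c2, e2) {
  comp <- c(a2 = a2, c2 = c2, e2 = e2)
  if (any(!is.finite(comp))) {
    stop("ace_params: components must be finite", call. = FALSE)
  }
  if (any(comp < 0)) {
    stop("ace_params: invariant violated: each of a2, c2, e2 must be >= 0 (got ",
         paste(sprintf("%s=%g", names(comp)[comp < 0], comp[comp < 0]),
               collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(comp) - 1) > 1e-9) {
    stop("ace_params: invariant violated: a2 + c2 + e2 must equal 1 (got ",
         format(sum(comp), digits = 12), ")", call. = FALSE)
  }
  structure(list(a2 = a2, c2 = c2, e2 = e2), class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat("ACE variance proportions: a2 =", format(x$a2),
      " c2 =", format(x$c2), " e2 =", format(x$e2), "\n")
  invisible(x)
}

check_component_spec <- function(comp, n_occasions, name) {
  need <- c("init_sd", "beta", "innov_sd", "spec_sd")
  missing_fields <- setdiff(need, names(comp))
  if (length(missing_fields)) {
    stop("simplex_params: component ", name, " is missing field(s) ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (length(comp$init_sd) != 1 || !is.finite(comp$init_sd) || comp$init_sd < 0) {
    stop("simplex_params: ", name,
         "$init_sd must be a single non-negative number", call. = FALSE)
  }
  if (length(comp$beta) != n_occasions - 1 || any(!is.finite(comp$beta))) {
    stop("simplex_params: ", name, "$beta must have length n_occasions - 1",
         call. = FALSE)
  }
  if (length(comp$innov_sd) != n_occasions - 1 ||
      any(!is.finite(comp$innov_sd)) || any(comp$innov_sd < 0)) {
    stop("simplex_params: ", name,
         "$innov_sd must be non-negative with length n_occasions - 1",
         call. = FALSE)
  }
  spec <- comp$spec_sd
  if (length(spec) == max(n_occasions - 2, 0)) {
    spec <- c(0, spec, 0)  # interior occasions supplied
  }
  if (length(spec) != n_occasions || any(!is.finite(spec)) || any(spec < 0)) {
    stop("simplex_params: ", name,
         "$spec_sd must be non-negative with length n_occasions (or interior ",
         "occasions only)", call. = FALSE)
  }
  if (spec[1] != 0 || spec[n_occasions] != 0) {
    stop("simplex_params: invariant violated: occasion-specific sd must be 0 ",
         "at the first and last occasion (identification) for component ",
         name, call. = FALSE)
  }
  list(init_sd = comp$init_sd, beta = comp$beta,
       innov_sd = comp$innov_sd, spec_sd = spec)
}

#' Parameters of the longitudinal genetic simplex model
#'
#' The simplex model treats the A, C and E influences on a trait as latent
#' first-order autoregressions over measurement occasions: the latent score
#' at occasion `t` is transmitted to occasion `t + 1` through a path
#' coefficient (`beta`), new "innovation" variance enters at every occasion
#' after the first (`innov_sd`), and occasion-specific variance that is
#' neither inherited from the previous occasion nor passed on may load on
#' interior occasions (`spec_sd`; fixed to zero at the first and last
#' occasion, where it is not identified separately from the initial and
#' innovation variances).
#'
#' @param n_occasions Number of measurement occasions (at least 2).
#' @param A,C,E Lists with fields `init_sd` (scalar), `beta` (length
#'   `n_occasions - 1`), `innov_sd` (length `n_occasions - 1`, occasions
#'   `2..n`), and `spec_sd` (either full length `n_occasions` with zero
#'   first/last entries, or just the interior occasions).
#' @return An object of class `simplex_params`.
#' @seealso [achievement_simplex_params()] for the ready-made generating
#'   regime used throughout the examples.
#' @export
simplex_params <- function(n_occasions, A, C, E) {
  if (length(n_occasions) != 1 || n_occasions < 2 ||
      n_occasions != round(n_occasions)) {
    stop("simplex_params: n_occasions must be an integer >= 2", call. = FALSE)
  }
  out <- structure(
    list(n_occasions = as.integer(n_occasions),
         A = check_component_spec(A, n_occasions, "A"),
         C = check_component_spec(C, n_occasions, "C"),
         E = check_component_spec(E, n_occasions, "E")),
    class = "simplex_params")
  v <- diag(implied_phenotypic_cov(out))
  if (any(v <= 0)) {
    stop("simplex_params: invariant violated: implied total variance must be ",
         "> 0 at every occasion", call. = FALSE)
  }
  out
}

#' Parameters of the common pathway model
#'
#' A single latent factor with unit variance, itself decomposed into A, C
#' and E (squared path coefficients summing to one), loads on every
#' measurement occasion; the residual variance of each occasion gets its own
#' ACE decomposition.
#'
#' @param latent_a,latent_c,latent_e Path coefficients from the latent A, C
#'   and E influences to the common factor; their squares must sum to 1
#'   (the latent factor variance is fixed to one).
#' @param loadings Factor loading of each occasion on the common factor.
#' @param resid_a2,resid_c2,resid_e2 Non-negative residual A, C and E
#'   variances per occasion.
#' @return An object of class `cpm_params`.
#' @seealso [achievement_cpm_params()]
#' @export
cpm_params <- function(latent_a, latent_c, latent_e, loadings,
                       resid_a2, resid_c2, resid_e2) {
  s <- latent_a^2 + latent_c^2 + latent_e^2
  if (!is.finite(s) || abs(s - 1) > 1e-9) {
    stop("cpm_params: invariant violated: latent_a^2 + latent_c^2 + latent_e^2",
         " must equal 1 (latent factor variance fixed to 1); got ",
         format(s, digits = 12), call. = FALSE)
  }
  p <- length(loadings)
  if (p < 2 || any(!is.finite(loadings))) {
    stop("cpm_params: loadings must be finite with length >= 2", call. = FALSE)
  }
  for (nm in c("resid_a2", "resid_c2", "resid_e2")) {
    v <- get(nm)
    if (length(v) != p || any(!is.finite(v)) || any(v < 0)) {
      stop("cpm_params: invariant violated: ", nm,
           " must be non-negative with one entry per occasion", call. = FALSE)
    }
  }
  structure(list(latent_a = latent_a, latent_c = latent_c, latent_e = latent_e,
                 loadings = as.numeric(loadings),
                 resid_a2 = as.numeric(resid_a2),
                 resid_c2 = as.numeric(resid_c2),
                 resid_e2 = as.numeric(resid_e2)),
            class = "cpm_params")
}

#' Parameters of the multivariate Cholesky decomposition
#'
#' Each of the A, C and E covariance structures over `p` variables is
#' parameterized as `L %*% t(L)` with `L` lower triangular, which keeps the
#' implied covariance positive semi-definite for any real paths.
#'
#' @param L_A,L_C,L_E Lower-triangular `p x p` path matrices. Diagonal
#'   entries are taken non-negative (sign convention).
#' @return An object of class `cholesky_params`.
#' @export
cholesky_params <- function(L_A, L_C, L_E) {
  p <- nrow(L_A)
  for (nm in c("L_A", "L_C", "L_E")) {
    L <- get(nm)
    if (!is.matrix(L) || nrow(L) != p || ncol(L) != p || any(!is.finite(L))) {
      stop("cholesky_params: ", nm, " must be a finite ", p, "x", p, " matrix",
           call. = FALSE)
    }
    if (any(L[upper.tri(L)] != 0)) {
      stop("cholesky_params: ", nm, " must be lower triangular", call. = FALSE)
    }
    if (any(diag(L) < 0)) {
      stop("cholesky_params: invariant violated: diagonal of ", nm,
           " must be >= 0 (sign convention)", call. = FALSE)
    }
  }
  structure(list(L_A = L_A, L_C = L_C, L_E = L_E), class = "cholesky_params")
}

#' Generating regime for four-occasion achievement stability
#'
#' The default simplex parameter set used in the package's recovery
#' experiments. It encodes a highly heritable, highly stable achievement
#' series: genetic transmission paths 0.86, 0.84 and 0.86 between adjacent
#' occasions, per-occasion heritabilities 0.73, 0.70, 0.63 and 0.58 (with a
#' 3% occasion-specific genetic share at the third occasion), a shared
#' environment holding 20% of the variance at every occasion with high
#' transmission, and a purely occasion-specific non-shared environment
#' (transmission fixed at zero in the generating truth). Phenotypic variance
#' is 1 at every occasion, so paths are on the standardized scale.
#'
#' @return A [simplex_params()] object with 4 occasions.
#' @export
achievement_simplex_params <- function() {
  h2 <- c(0.73, 0.70, 0.63, 0.58)
  beta_a <- c(0.86, 0.84, 0.86)
  spec_a2 <- c(0, 0, 0.03 * h2[3], 0)         # 3% of h2 is occasion-specific
  lat <- numeric(4); innov_a2 <- numeric(3)
  lat[1] <- h2[1]
  for (t in 2:4) {
    lat[t] <- h2[t] - spec_a2[t]
    innov_a2[t - 1] <- lat[t] - beta_a[t - 1]^2 * lat[t - 1]
  }
  c2 <- 0.20
  beta_c <- rep(0.9, 3)
  innov_c2 <- rep(c2 * (1 - 0.9^2), 3)
  e2 <- 1 - h2 - c2
  simplex_params(
    4,
    A = list(init_sd = sqrt(h2[1]), beta = beta_a, innov_sd = sqrt(innov_a2),
             spec_sd = sqrt(spec_a2)),
    C = list(init_sd = sqrt(c2), beta = beta_c, innov_sd = sqrt(innov_c2),
             spec_sd = rep(0, 4)),
    E = list(init_sd = sqrt(e2[1]), beta = rep(0, 3),
             innov_sd = sqrt(e2[2:4]), spec_sd = rep(0, 4)))
}

#' Generating regime for the common pathway model of stable achievement
#'
#' Default common pathway parameter set for recovery experiments: the latent
#' stability factor is 70% additive genetic, 24% shared environmental and 6%
#' non-shared environmental; every occasion loads 0.85 on the factor and the
#' residual variance (0.2775 per occasion, giving unit total variance) is
#' split 30/15/55 between residual A, C and E, reflecting a largely
#' occasion-specific non-shared environment.
#'
#' @return A [cpm_params()] object with 4 occasions.
#' @export
achievement_cpm_params <- function() {
  resid <- 1 - 0.85^2
  cpm_params(latent_a = sqrt(0.70), latent_c = sqrt(0.24),
             latent_e = sqrt(0.06), loadings = rep(0.85, 4),
             resid_a2 = rep(0.30 * resid, 4),
             resid_c2 = rep(0.15 * resid, 4),
             resid_e2 = rep(0.55 * resid, 4))
}
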
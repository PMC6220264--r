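# Shared fixtures, all built in code.

measures4 <- paste0("ach_t", 1:4)

# Achievement-like simplex regime with every free fitting parameter in the
# interior of its space (both interior occasion-specific genetic paths
# strictly positive), used for noiseless-inversion oracle tests where
# boundary parameters would sit on a quartic-flat profile.
interior_simplex_params <- function() {
  h2 <- c(0.73, 0.70, 0.63, 0.58)
  beta_a <- c(0.86, 0.84, 0.86)
  spec_a2 <- c(0, 0.02, 0.0189, 0)
  lat <- numeric(4); innov_a2 <- numeric(3)
  lat[1] <- h2[1]
  for (t in 2:4) {
    lat[t] <- h2[t] - spec_a2[t]
    innov_a2[t - 1] <- lat[t] - beta_a[t - 1]^2 * lat[t - 1]
  }
  c2 <- 0.20
  e2 <- 1 - h2 - c2
  simplex_params(
    4,
    A = list(init_sd = sqrt(h2[1]), beta = beta_a,
             innov_sd = sqrt(innov_a2), spec_sd = sqrt(spec_a2)),
    C = list(init_sd = sqrt(c2), beta = rep(0.9, 3),
             innov_sd = rep(sqrt(c2 * (1 - 0.81)), 3), spec_sd = rep(0, 4)),
    E = list(init_sd = sqrt(e2[1]), beta = rep(0.3, 3),
             innov_sd = sqrt(e2[2:4] - 0.09 * e2[1:3]), spec_sd = rep(0, 4)))
}

# expected sampling standard error of each cell of a Wishart sample
# covariance with population covariance S and n observations
cov_cell_se <- function(S, n) {
  sqrt((outer(diag(S), diag(S)) + S^2) / n)
}

# noiseless group covariances implied by a parameter object
oracle_gcov <- function(params, labels, n_mz = 1000, n_dz = 1000) {
  group_covariances_from_matrices(
    implied_covariance(params, "MZ"), implied_covariance(params, "DZ"),
    n_mz, n_dz, labels)
}

# fixed-seed ancestry-style noise principal components used as a baseline
run_seeded_pcs <- function(n, k, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, paste0("PC", 1:k)))
}

# group covariances drawn from the Wishart sampling distribution of the
# implied covariance (stochastic data without building a pair table)
wishart_gcov <- function(params, labels, n_mz, n_dz) {
  S_mz <- stats::rWishart(1, n_mz, implied_covariance(params, "MZ") / n_mz)[, , 1]
  S_dz <- stats::rWishart(1, n_dz, implied_covariance(params, "DZ") / n_dz)[, , 1]
  group_covariances_from_matrices(S_mz, S_dz, n_mz, n_dz, labels)
}
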
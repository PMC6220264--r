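test_that("noiseless inversion: univariate ACE recovers generating paths to
           optimizer tolerance", {
  truth <- ace_params(0.6, 0.2, 0.2)
  gc <- oracle_gcov(truth, "ach", 1000, 1000)
  fit <- fit_univariate_ace(gc, "ach", restarts = 3)
  expect_lt(max(abs(coef(fit) - sqrt(c(0.6, 0.2, 0.2)))), 1e-4)
  expect_lt(fit$minimum - saturated_neg2ll(gc), 1e-6)
  expect_equal(sum(fit$derived$standardized), 1, tolerance = 1e-6)
})

test_that("noiseless inversion: bivariate Cholesky recovers paths and the
           implied genetic correlation", {
  L_A <- matrix(c(0.77, 0.62, 0, 0.46), 2)
  L_C <- matrix(c(0.45, 0.22, 0, 0.30), 2)
  L_E <- matrix(c(0.45, 0.13, 0, 0.43), 2)
  truth <- cholesky_params(L_A, L_C, L_E)
  gc <- oracle_gcov(truth, c("ks1", "ks2"), 1000, 1000)
  fit <- fit_bivariate_cholesky(gc, c("ks1", "ks2"), restarts = 3)
  expect_lt(max(abs(coef(fit) -
                      c(L_A[lower.tri(L_A, TRUE)], L_C[lower.tri(L_C, TRUE)],
                        L_E[lower.tri(L_E, TRUE)]))), 1e-4)
  SA <- tcrossprod(L_A)
  expect_equal(fit$derived$rG[1, 2], SA[1, 2] / sqrt(SA[1, 1] * SA[2, 2]),
               tolerance = 1e-4)
  expect_equal(sum(fit$derived$shares), 1, tolerance = 1e-8)
})

test_that("noiseless inversion: simplex recovers an interior generating set
           to optimizer tolerance", {
  truth <- interior_simplex_params()
  gc <- oracle_gcov(truth, measures4, 1000, 1000)
  fit <- fit_simplex(gc, measures4, restarts = 4)
  est <- coef(fit)
  expect_lt(max(abs(est[c("A_beta_12", "A_beta_23", "A_beta_34")] -
                      truth$A$beta)), 1e-4)
  expect_lt(max(abs(est[c("A_spec_2", "A_spec_3")] -
                      truth$A$spec_sd[2:3])), 1e-4)
  expect_lt(abs(est["A_init"] - truth$A$init_sd), 1e-4)
  expect_lt(max(abs(est[paste0("A_innov_", 2:4)] - truth$A$innov_sd)), 1e-4)
  expect_lt(max(abs(est[paste0("E_beta_", c(12, 23, 34))] - truth$E$beta)),
            1e-3)
  expect_lt(fit$minimum - saturated_neg2ll(gc), 1e-6)
  occ <- fit$derived$occasion
  expect_equal(occ$h2 + occ$c2 + occ$e2, rep(1, 4), tolerance = 1e-6)
})

test_that("noiseless inversion: common pathway recovers latent decomposition,
           loadings and residuals", {
  truth <- achievement_cpm_params()
  gc <- oracle_gcov(truth, measures4, 1000, 1000)
  fit <- fit_common_pathway(gc, measures4, restarts = 3)
  expect_lt(max(abs(fit$derived$latent - c(0.70, 0.24, 0.06))), 1e-4)
  est_params <- fit$params
  expect_lt(max(abs(est_params$loadings - truth$loadings)), 1e-4)
  expect_lt(max(abs(est_params$resid_a2 - truth$resid_a2)), 1e-4)
  expect_lt(max(abs(est_params$resid_e2 - truth$resid_e2)), 1e-4)
  expect_equal(sum(fit$derived$latent), 1, tolerance = 1e-10)
  occ <- fit$derived$occasion
  expect_equal(occ$A + occ$C + occ$E, rep(1, 4), tolerance = 1e-6)
})

test_that("simplex fitted to data without cross-occasion covariance drives
           the transmission paths to zero", {
  comp <- list(init_sd = 0.7, beta = c(0, 0, 0), innov_sd = rep(0.7, 3),
               spec_sd = rep(0, 4))
  ecomp <- list(init_sd = 0.55, beta = c(0, 0, 0), innov_sd = rep(0.55, 3),
                spec_sd = rep(0, 4))
  truth <- simplex_params(4, comp,
                          list(init_sd = 0.45, beta = c(0, 0, 0),
                               innov_sd = rep(0.45, 3), spec_sd = rep(0, 4)),
                          ecomp)
  gc <- oracle_gcov(truth, measures4, 2000, 2000)
  fit <- fit_simplex(gc, measures4, restarts = 3)
  expect_lt(max(abs(coef(fit)[sprintf("A_beta_%d%d", 1:3, 2:4)])), 0.02)
})

test_that("falconer arithmetic matches its definition and flags bounds", {
  f <- falconer_estimates(0.8, 0.5)
  expect_equal(c(f$a2, f$c2, f$e2), c(0.6, 0.2, 0.2))
  expect_false(f$out_of_bounds)
  f2 <- falconer_estimates(0.4, 0.4)
  expect_equal(c(f2$a2, f2$c2, f2$e2), c(0, 0.4, 0.6))
  f3 <- falconer_estimates(1.0, 0.5)
  expect_equal(c(f3$a2, f3$c2, f3$e2), c(1, 0, 0))
  f4 <- falconer_estimates(0.5, 0.1)   # a2 = 0.8 > rMZ, c2 negative
  expect_true(f4$out_of_bounds)
  expect_error(falconer_estimates(1.2, 0.5), "\\[-1, 1\\]")
})

test_that("intraclass correlations match a brute-force double-entry oracle
           and hit their limiting values", {
  x1 <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.8, 0.0, -0.7, 1.5, -2.0)
  x2 <- c(0.9, -0.2, 0.5, 1.4, -1.3, 0.2, 0.4, -0.9, 1.1, -1.5)
  df <- data.frame(family_id = 1:10, zygosity = rep(c("MZ", "DZ"), 5),
                   sex1 = "F", sex2 = "F", ach_1 = x1, ach_2 = x2)
  r <- intraclass_correlations(df, "ach")
  brute <- function(a, b) {
    v1 <- c(a, b); v2 <- c(b, a)
    m1 <- mean(v1); m2 <- mean(v2)
    sum((v1 - m1) * (v2 - m2)) /
      sqrt(sum((v1 - m1)^2) * sum((v2 - m2)^2))
  }
  mz <- df$zygosity == "MZ"
  expect_equal(unname(r["MZ"]), brute(x1[mz], x2[mz]), tolerance = 1e-12)
  expect_equal(unname(r["DZ"]), brute(x1[!mz], x2[!mz]), tolerance = 1e-12)

  ident <- data.frame(family_id = 1:8, zygosity = rep(c("MZ", "DZ"), 4),
                      ach_1 = 1:8, ach_2 = 1:8)
  expect_equal(unname(intraclass_correlations(ident, "ach")),
               c(1, 1))
  expect_error(intraclass_correlations(df[df$zygosity == "MZ", ], "ach"),
               "DZ")
})

test_that("ML and Falconer univariate estimates agree at large n", {
  tw <- simulate_ace(50000, 50000, ace_params(0.6, 0.2, 0.2), seed = 21)
  fit <- fit_univariate_ace(tw, "ach", restarts = 3)
  fal <- fit$derived$falconer
  expect_lt(abs(fit$derived$standardized["a2"] - fal$a2), 0.02)
  expect_lt(abs(fit$derived$standardized["c2"] - fal$c2), 0.02)
  expect_lt(abs(fit$derived$standardized["e2"] - fal$e2), 0.02)
})

test_that("twins simulated with equal MZ and DZ correlations yield a near-zero
           genetic estimate", {
  tw <- simulate_ace(3000, 3000, ace_params(0, 0.5, 0.5), seed = 22)
  fit <- fit_univariate_ace(tw, "ach", restarts = 3)
  expect_lt(fit$derived$standardized["a2"], 0.05)
})

test_that("bivariate genetic share is recovered inside the band it was
           generated in", {
  # h2 = 0.6 at both ages, rG = 0.8, plus C and E covariance such that the
  # genetic share of the phenotypic correlation is 0.75
  S_A <- 0.6 * matrix(c(1, 0.8, 0.8, 1), 2)
  S_C <- 0.2 * matrix(c(1, 0.5, 0.5, 1), 2)
  S_E <- 0.2 * matrix(c(1, 0.3, 0.3, 1), 2)
  truth <- cholesky_params(t(chol(S_A)), t(chol(S_C)), t(chol(S_E)))
  gen_share <- S_A[1, 2] / (S_A[1, 2] + S_C[1, 2] + S_E[1, 2])
  set.seed(23)
  gc <- wishart_gcov(truth, c("ks1", "ks2"), 4000, 4000)
  fit <- fit_bivariate_cholesky(gc, c("ks1", "ks2"), restarts = 3)
  expect_lt(abs(fit$derived$shares["A"] - gen_share), 0.05)
  expect_gt(gen_share, 0.63); expect_lt(gen_share, 0.79)
})

test_that("independent measures give a genetic correlation whose confidence
           interval covers zero", {
  S <- diag(2)
  truth <- cholesky_params(t(chol(0.6 * S)), t(chol(0.2 * S)),
                           t(chol(0.2 * S)))
  set.seed(24)
  gc <- wishart_gcov(truth, c("m1", "m2"), 1500, 1500)
  fit <- fit_bivariate_cholesky(gc, c("m1", "m2"), restarts = 3)
  ci <- confint(fit, "a_21")
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("profile likelihood CI matches the closed form on a quadratic
           deviance", {
  toy <- structure(list(objective = function(p) (p - 1)^2,
                        par = c(theta = 1), minimum = 0,
                        se = c(theta = 1)), class = "twinfit")
  ci <- likelihood_ci(toy, "theta")
  expect_equal(unname(ci), 1 + c(-1, 1) * sqrt(stats::qchisq(0.95, 1)),
               tolerance = 1e-4)
})

test_that("profile CIs bracket the estimate on a real fit", {
  tw <- simulate_ace(1500, 1500, ace_params(0.6, 0.2, 0.2), seed = 25)
  fit <- fit_univariate_ace(tw, "ach", restarts = 3)
  ci <- likelihood_ci(fit, "a")
  expect_true(ci["lower"] < coef(fit)["a"] && coef(fit)["a"] < ci["upper"])
  expect_true(all(is.finite(ci)))
})

test_that("profile CIs at a null genetic effect cover zero at roughly the
           nominal rate", {
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    tw <- simulate_ace(400, 400, ace_params(0, 0.4, 0.6), seed = 3000 + r)
    fit <- fit_univariate_ace(tw, "ach", restarts = 2)
    ci <- likelihood_ci(fit, "a")
    if (!anyNA(ci) && ci["lower"] <= 0 && ci["upper"] >= 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("model comparison: identical fits give a zero statistic and unit
           p-value", {
  tw <- simulate_ace(800, 800, ace_params(0.6, 0.2, 0.2), seed = 26)
  f1 <- fit_univariate_ace(tw, "ach", restarts = 2)
  f2 <- fit_univariate_ace(tw, "ach", restarts = 2)
  cmp <- compare_models(f1, f2)
  expect_lt(abs(cmp$lrt), 1e-6)
  expect_equal(cmp$df, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_models(f2, fit_univariate_ace(
    simulate_ace(800, 800, ace_params(0.6, 0.2, 0.2), seed = 27),
    "ach", restarts = 2)), "identical data")
})

test_that("dropping a truly-zero shared-environment path is calibrated and
           dropping a strong transmission path is decisively rejected", {
  # null calibration: the c path enters through its square, so under the
  # null the LRT is a 50:50 mixture of 0 and chi-square(1); p-values are
  # stochastically >= uniform but small p-values keep their nominal rate
  ps <- vapply(seq_len(40), function(r) {
    tw <- simulate_ace(400, 400, ace_params(0.5, 0, 0.5), seed = 4000 + r)
    full <- fit_univariate_ace(tw, "ach", restarts = 2)
    nested <- fit_univariate_ace(tw, "ach", restarts = 2, fix = c(c = 0))
    compare_models(full, nested)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps), 0.45)

  tw <- simulate_simplex(1000, 1000, achievement_simplex_params(), seed = 28)
  full <- fit_simplex(tw, measures4, restarts = 3)
  nested <- fit_simplex(tw, measures4, restarts = 3,
                        fix = c(A_beta_12 = 0))
  cmp <- compare_models(full, nested)
  expect_equal(cmp$df, 1)
  expect_lt(cmp$p, 0.001)
})

test_that("simplex replicates show negligible bias in the transmission
           paths and the CPM latent decomposition", {
  n_rep <- 8
  sbias <- matrix(NA_real_, n_rep, 3)
  cbias <- matrix(NA_real_, n_rep, 2)
  sp <- achievement_simplex_params()
  cp <- achievement_cpm_params()
  for (r in seq_len(n_rep)) {
    tw <- simulate_simplex(5000, 5000, sp, seed = 5000 + r)
    f <- fit_simplex(tw, measures4, restarts = 3)
    sbias[r, ] <- coef(f)[sprintf("A_beta_%d%d", 1:3, 2:4)] - sp$A$beta
    tw2 <- simulate_common_pathway(5000, 5000, cp, seed = 6000 + r)
    f2 <- fit_common_pathway(tw2, measures4, restarts = 3)
    cbias[r, ] <- f2$derived$latent[c("a2", "c2")] - c(0.70, 0.24)
  }
  expect_lt(max(abs(colMeans(sbias))), 0.02)
  expect_lt(max(abs(colMeans(cbias))), 0.02)
})

test_that("fit preconditions are enforced", {
  tw <- simulate_simplex(50, 50, achievement_simplex_params(), seed = 29)
  expect_error(fit_simplex(tw, measures4[1:2]), "3 occasions")
  expect_error(fit_simplex(tw, measures4, min_pairs = 200), "complete pairs")
  expect_error(fit_common_pathway(tw, measures4[1:2]), "3 occasions")
})
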
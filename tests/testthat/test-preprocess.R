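test_that("residualize reduces to z-scoring when covariates carry no signal", {
  set.seed(101)
  y <- rnorm(300, mean = 5, sd = 2)
  # orthogonalize the covariate against y so the OLS slope is exactly zero
  x <- stats::resid(stats::lm(rnorm(300) ~ y))
  out <- residualize(y, x)
  expect_equal(out, drop(scale(y)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("residualize flags a phenotype explained exactly by covariates", {
  age <- runif(100, 6, 8)
  expect_warning(out <- residualize(2 + 3 * age, age), "exactly")
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_equal(unname(out), rep(0, 100), ignore_attr = TRUE)
})

test_that("residualize removes group mean differences exactly and is
           idempotent", {
  set.seed(102)
  sex <- rbinom(500, 1, 0.5)
  y <- 0.8 * sex + rnorm(500)
  out <- residualize(y, cbind(sex = sex))
  expect_lt(abs(mean(out[sex == 1]) - mean(out[sex == 0])), 1e-10)
  twice <- residualize(out, cbind(sex = sex))
  expect_equal(twice, out, tolerance = 1e-10)
})

test_that("residualize errors name rank-deficient covariate columns and
           preserves missingness", {
  set.seed(103)
  y <- rnorm(50); y[c(3, 10)] <- NA
  x <- cbind(age = rnorm(50))
  out <- residualize(y, x)
  expect_true(all(is.na(out[c(3, 10)])))
  expect_false(anyNA(out[-c(3, 10)]))
  expect_error(residualize(y, cbind(age = x[, 1], age2 = 2 * x[, 1])),
               "age2")
  expect_error(residualize(rep(NA_real_, 10), rnorm(10)), "missing")
  expect_error(residualize(rep(1, 50), x), "constant")
})

test_that("residualize can estimate on a subset and apply to all rows", {
  set.seed(104)
  x <- rnorm(400)
  y <- 1 + 0.5 * x + rnorm(400)
  sub <- sample(400, 200)
  out <- residualize(y, x, fit_subset = sub)
  # residuals stay uncorrelated with the covariate in the fitting subset
  expect_lt(abs(stats::cor(out[sub], x[sub])), 0.02)
  expect_equal(length(out), 400)
})

test_that("van der Waerden transform maps ranks to normal quantiles", {
  out <- vdw_transform(c(10, 25, 17))
  expect_equal(out[2], stats::qnorm(0.75))
  expect_equal(out[3], 0)
  expect_lt(abs(out[1] - (-0.6745)), 1e-3)
})

test_that("van der Waerden transform is monotone-invariant, rank-preserving
           and handles ties by mid-rank", {
  set.seed(105)
  x <- rnorm(50)
  expect_equal(vdw_transform(x), vdw_transform(exp(x)), tolerance = 1e-12)
  mono <- sort(x)
  expect_true(all(diff(vdw_transform(mono)) > 0))
  tied <- c(1, 2, 2, 3)
  out <- vdw_transform(tied)
  expect_equal(out[2], out[3])
  expect_equal(out[2], stats::qnorm(2.5 / 5))
  expect_error(vdw_transform(rep(1, 10)), "identical")
  expect_error(vdw_transform(c(1, 2, NA, NA)), "3 non-missing")
})

test_that("transforms are permutation-equivariant and preserve missingness", {
  set.seed(106)
  y <- rnorm(80); y[c(5, 9)] <- NA
  x <- rnorm(80)
  perm <- sample(80)
  expect_equal(vdw_transform(y)[perm], vdw_transform(y[perm]))
  expect_equal(residualize(y, x)[perm], residualize(y[perm], x[perm]),
               tolerance = 1e-12)
  expect_identical(is.na(vdw_transform(y)), is.na(y))
})

test_that("composite_mean averages standardized components and honours
           min_available", {
  set.seed(107)
  a <- as.numeric(scale(rnorm(100)))
  expect_equal(composite_mean(list(a, a)), a, tolerance = 1e-12)

  b <- rnorm(100); b[1] <- NA
  comp <- composite_mean(list(a, b), min_available = 1)
  expect_equal(comp[1], a[1])          # falls back to the available source
  b2 <- b; a2 <- a; a2[2] <- NA; b2[2] <- NA
  comp2 <- composite_mean(list(a2, b2))
  expect_true(is.na(comp2[2]))
  comp3 <- composite_mean(list(a2, b2), min_available = 2)
  expect_true(all(is.na(comp3[1:2])))
  expect_error(composite_mean(list()), "non-empty")
})

test_that("eta-squared from the sex-by-zygosity ANOVA behaves at the null,
           at saturation and at a constructed 1% effect", {
  set.seed(108)
  n <- 5000
  sex <- factor(sample(c("M", "F"), n, TRUE))
  zyg <- factor(sample(c("MZ", "DZ"), n, TRUE))
  expect_lt(variance_explained_by_groups(rnorm(n), sex, zyg), 0.005)
  expect_equal(
    variance_explained_by_groups(as.numeric(sex), sex, zyg), 1)
  # sex effect sized to explain 1% of variance
  y <- 0.2 * (as.numeric(sex) - 1.5) + sqrt(1 - 0.01) * rnorm(n)
  expect_lt(abs(variance_explained_by_groups(y, sex, zyg) - 0.01), 0.005)
  expect_error(variance_explained_by_groups(rnorm(10),
                                            factor(rep("F", 10)),
                                            factor(rep(c("MZ", "DZ"), 5))),
               "sex")
})

test_that("regressing out g leaves residuals exactly uncorrelated with g", {
  set.seed(109)
  g <- rnorm(500)
  phenos <- list(p1 = 0.6 * g + rnorm(500), p2 = rnorm(500))
  out <- regress_out_g(phenos, g)
  expect_lt(abs(stats::cor(out$p1, g)), 1e-10)
  expect_lt(abs(stats::cor(out$p2, g)), 1e-10)
  # a phenotype orthogonal to g is returned (near) z-scored
  z <- stats::resid(stats::lm(rnorm(500) ~ g))
  expect_equal(regress_out_g(z, g), drop(scale(z)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_warning(regress_out_g(g, g), "exactly")
  expect_error(regress_out_g(phenos, rep(1, 500)), "non-constant")
})

test_that("controlling for a g that shares the stable genetic factor lowers
           heritability but leaves transmission paths near truth", {
  params <- achievement_simplex_params()
  tw <- simulate_simplex(3000, 3000, params, seed = 110)
  # g proxies the stable factor through the first-occasion phenotype
  run_g <- function(col) 0.6 * tw[[col]] + 0.8 * rnorm(nrow(tw))
  set.seed(111)
  g1 <- run_g("ach_t1_1"); g2 <- run_g("ach_t1_2")
  for (m in measures4) {
    tw[[paste0(m, "_1")]] <- regress_out_g(tw[[paste0(m, "_1")]], g1)
    tw[[paste0(m, "_2")]] <- regress_out_g(tw[[paste0(m, "_2")]], g2)
  }
  fit <- fit_simplex(tw, measures4, restarts = 3)
  betas <- coef(fit)[sprintf("A_beta_%d%d", 1:3, 2:4)]
  expect_lt(max(abs(betas - params$A$beta)), 0.1)
  h2 <- fit$derived$occasion$h2
  expect_lt(h2[1], 0.73)   # controlling for g removes stable genetic variance
})
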
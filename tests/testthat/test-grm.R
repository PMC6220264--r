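test_that("GRM matches the naive standardized double-loop on a small panel", {
  panel <- simulate_genotypes(30, 60, seed = 31)
  grm <- compute_grm(panel)
  X <- panel$dosages
  p <- colMeans(X) / 2
  G_naive <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    G_naive[i, j] <- mean((X[i, ] - 2 * p) * (X[j, ] - 2 * p) /
                            (2 * p * (1 - p)))
  }
  expect_equal(unname(grm$G), G_naive, tolerance = 1e-10)
})

test_that("a duplicated individual has off-diagonal relatedness equal to the
           diagonal", {
  panel <- simulate_genotypes(20, 200, seed = 32)
  panel$dosages <- rbind(panel$dosages, panel$dosages[1, ])
  panel$sample_ids <- c(panel$sample_ids, "dup1")
  rownames(panel$dosages) <- panel$sample_ids
  grm <- suppressWarnings(compute_grm(panel))
  expect_equal(grm$G[1, 21], grm$G[1, 1], tolerance = 1e-10)
  expect_equal(grm$G[1, 21], grm$G[21, 21], tolerance = 1e-10)
})

test_that("the GRM diagonal centres on 1 under HWE and complementary
           genotypes give negative relatedness", {
  panel <- simulate_genotypes(500, 5000, seed = 33)
  grm <- compute_grm(panel)
  expect_lt(abs(mean(diag(grm$G)) - 1), 0.05)

  comp <- list(dosages = rbind(a = c(0, 2, 0, 2, 0, 2),
                               b = c(2, 0, 2, 0, 2, 0),
                               c = c(0, 2, 2, 0, 0, 2),
                               d = c(2, 0, 0, 2, 2, 0)),
               sample_ids = c("a", "b", "c", "d"),
               snp_ids = paste0("s", 1:6))
  G <- compute_grm(comp)$G
  expect_lt(G["a", "b"], 0)
})

test_that("monomorphic SNPs are dropped with a warning or rejected in strict
           mode", {
  panel <- simulate_genotypes(50, 20, seed = 34)
  panel$dosages[, 3] <- 2
  expect_warning(grm <- compute_grm(panel), "monomorphic")
  expect_equal(grm$n_snps, 19)
  expect_error(compute_grm(panel, strict_monomorphic = TRUE), "snp000003")
})

test_that("missing dosages are mean-imputed before GRM construction", {
  panel <- simulate_genotypes(40, 100, seed = 35)
  panel$dosages[cbind(1:10, 1:10)] <- NA
  grm <- compute_grm(panel)
  expect_false(anyNA(grm$G))
})

test_that("relatedness pruning retains everyone when no pair exceeds the
           cutoff and drops exactly one member of a duplicate pair", {
  panel <- simulate_genotypes(100, 4000, seed = 36)
  grm <- compute_grm(panel)
  keep <- prune_related(grm, cutoff = 0.2)   # noise SD ~ 0.016, far below
  expect_equal(length(keep), 100)

  panel$dosages[2, ] <- panel$dosages[1, ]   # make ids 1 and 2 duplicates
  grm2 <- compute_grm(panel)
  keep2 <- prune_related(grm2, cutoff = 0.2)
  expect_equal(length(keep2), 99)
  expect_equal(sum(c("id00001", "id00002") %in% keep2), 1)
})

test_that("pruning matches an independent exhaustive application of the
           rule", {
  panel <- simulate_genotypes(500, 800, seed = 37)
  grm <- compute_grm(panel)
  cutoff <- 0.06
  keep <- prune_related(grm, cutoff)
  # independent check: scan pairs in id order, dropping the later member
  ok <- rep(TRUE, 500)
  G <- grm$G
  for (i in 1:499) {
    if (!ok[i]) next
    for (j in (i + 1):500) {
      if (ok[j] && G[i, j] > cutoff) ok[j] <- FALSE
    }
  }
  expect_identical(keep, grm$sample_ids[ok], ignore_attr = TRUE)
  sub <- grm$G[keep, keep]
  diag(sub) <- 0
  expect_lte(max(sub), cutoff)
})

test_that("GRM principal components recover constructed stratification and
           satisfy the eigen identity", {
  set.seed(38)
  n <- 200; m <- 800
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5)
  shift <- pmin(pmax(p1 + runif(m, -0.2, 0.2), 0.05), 0.95)
  dos <- matrix(0L, n, m)
  for (k in seq_len(m)) {
    dos[, k] <- rbinom(n, 2, ifelse(pop == 0, p1[k], shift[k]))
  }
  panel <- list(dosages = dos, sample_ids = sprintf("i%03d", 1:n),
                snp_ids = sprintf("s%04d", 1:m))
  rownames(panel$dosages) <- panel$sample_ids
  grm <- suppressWarnings(compute_grm(panel))
  pcs <- grm_pca(grm, 2)
  expect_gt(abs(stats::cor(pcs[, 1], pop)), 0.9)

  v <- attr(pcs, "vectors")[, 1]
  lam <- attr(pcs, "eigenvalues")[1]
  expect_lt(max(abs(grm$G %*% v - lam * v)), 1e-8)
  expect_error(grm_pca(grm, 200), "smaller")

  # a homogeneous panel has no comparably dominant eigenvalue
  hom <- compute_grm(simulate_genotypes(200, 800, seed = 39))
  ev <- eigen(hom$G, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[1] / ev[2], 2)
})

test_that("GRM round-trips through the GCTA text convention", {
  panel <- simulate_genotypes(25, 300, seed = 40)
  grm <- suppressWarnings(compute_grm(panel))
  prefix <- file.path(tempdir(), "test_grm")
  write_grm_gcta(grm, prefix)
  back <- read_grm_gcta(prefix)
  expect_equal(back$G, grm$G, tolerance = 1e-12)
  expect_equal(back$sample_ids, grm$sample_ids)
  expect_equal(back$n_snps, grm$n_snps)
  unlink(paste0(prefix, c(".grm.gz", ".grm.id")))
})

test_that("genotype panels round-trip through the tab-separated format", {
  panel <- simulate_genotypes(15, 40, seed = 41)
  path <- file.path(tempdir(), "panel.tsv")
  write_genotype_panel(panel, path)
  back <- read_genotype_panel(path)
  expect_equal(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$snp_ids, panel$snp_ids)
  expect_equal(back$sample_ids, panel$sample_ids)
  unlink(path)
})
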
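# Genotype-panel and polygenic-score cohort simulators. Panels are drawn in
# Hardy-Weinberg equilibrium with no linkage disequilibrium between SNPs.

#' Simulate a biallelic genotype panel in Hardy-Weinberg equilibrium
#'
#' Per-SNP effect-allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]` and dosages as `Binomial(2, p_k)`.
#'
#' @param n Number of individuals (>= 1).
#' @param m Number of SNPs (>= 1).
#' @param maf_low,maf_high Bounds for the effect-allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return A `genotype_panel`: list with `dosages` (`n x m` matrix of
#'   0/1/2), `allele_freqs` (the generating frequencies), `snp_ids`,
#'   `sample_ids`, and counted/other allele codes (`a1`, `a2`).
#' @examples
#' panel <- simulate_genotypes(50, 100, seed = 1)
#' dim(panel$dosages)
#' @export
simulate_genotypes <- function(n, m, maf_low = 0.05, maf_high = 0.5,
                               seed = NULL) {
  if (n < 1 || m < 1) stop("n and m must be at least 1", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("degenerate MAF bounds: need 0 < maf_low <= maf_high <= 0.5",
         call. = FALSE)
  }
  run_seeded(seed, {
    p <- stats::runif(m, maf_low, maf_high)
    dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    snp_ids <- sprintf("snp%06d", seq_len(m))
    sample_ids <- sprintf("id%05d", seq_len(n))
    dimnames(dos) <- list(sample_ids, snp_ids)
    structure(list(dosages = dos, allele_freqs = p, snp_ids = snp_ids,
                   sample_ids = sample_ids,
                   a1 = rep("A", m), a2 = rep("G", m), seed = seed),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", length(x$sample_ids), "individuals x",
      length(x$snp_ids), "SNPs (HWE, no LD)\n")
  invisible(x)
}

#' Simulate an additive polygenic phenotype from a genotype panel
#'
#' A subset of `n_causal` SNPs receives standard-normal effects on the
#' standardized dosage scale; the aggregate genetic value is rescaled to
#' sample variance exactly `h2_snp` and independent Gaussian noise with
#' sample variance `1 - h2_snp` is added, so the generating decomposition
#' explains exactly `h2_snp` of the variance.
#'
#' @param panel A `genotype_panel`.
#' @param h2_snp SNP heritability in `[0, 1)`.
#' @param n_causal Number of causal SNPs (defaults to all).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector with attributes `genetic_values`,
#'   `effects` (per-allele effects on the raw dosage scale, zero for
#'   non-causal SNPs) and `causal_idx`.
#' @examples
#' panel <- simulate_genotypes(200, 500, seed = 1)
#' y <- simulate_snp_phenotype(panel, 0.3, seed = 2)
#' var(attr(y, "genetic_values")) / var(y)
#' @export
simulate_snp_phenotype <- function(panel, h2_snp, n_causal = NULL,
                                   seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.finite(h2_snp) || h2_snp < 0 || h2_snp >= 1) {
    stop("h2_snp must lie in [0, 1)", call. = FALSE)
  }
  m <- length(panel$snp_ids); n <- length(panel$sample_ids)
  if (is.null(n_causal)) n_causal <- m
  if (n_causal < 1 || n_causal > m) {
    stop("n_causal must be between 1 and the number of SNPs", call. = FALSE)
  }
  run_seeded(seed, {
    noise <- stats::rnorm(n)
    noise <- drop(scale(noise)) * sqrt(1 - h2_snp)
    eff_raw <- rep(0, m)
    if (h2_snp > 0) {
      causal <- sort(sample.int(m, n_causal))
      b <- stats::rnorm(n_causal)
      p <- colMeans(panel$dosages[, causal, drop = FALSE]) / 2
      sdk <- sqrt(2 * p * (1 - p))
      sdk[sdk == 0] <- Inf  # monomorphic in sample: no contribution
      eff_raw[causal] <- b / sdk
      g_raw <- drop(panel$dosages[, causal, drop = FALSE] %*% eff_raw[causal])
      if (stats::sd(g_raw) == 0) {
        stop("all causal SNPs are monomorphic in the sample", call. = FALSE)
      }
      scl <- sqrt(h2_snp) / stats::sd(g_raw)
      g <- (g_raw - mean(g_raw)) * scl
      eff_raw <- eff_raw * scl
    } else {
      causal <- integer(0)
      g <- rep(0, n)
    }
    y <- g + noise
    attr(y, "genetic_values") <- g
    attr(y, "effects") <- eff_raw
    attr(y, "causal_idx") <- causal
    names(y) <- panel$sample_ids
    y
  })
}

#' Simulate a longitudinal polygenic-score prediction cohort
#'
#' Generates one fixed score per individual and one achievement variable
#' per schedule entry such that the population R-squared of the score on
#' achievement at occasion `t` equals `r2_schedule[t]`. All occasions share
#' a stable latent component (variance `stable_var`), so prediction by the
#' score is carried forward by earlier achievement and the age-specific
#' incremental prediction beyond all earlier occasions is small (below 1%
#' of variance at the default settings).
#'
#' @param n Cohort size.
#' @param r2_schedule Target score R-squared per occasion, each in `[0, 1)`.
#' @param stable_var Variance of the stable component shared by all
#'   occasions; `r2_schedule + stable_var` must stay below 1.
#' @param seed Optional integer seed.
#' @return A list with `score` (length-`n` vector) and `achievement`
#'   (`n x length(r2_schedule)` matrix, columns `occ1 ...`), plus the
#'   generating schedule.
#' @examples
#' cohort <- simulate_gps_cohort(1000, seed = 1)
#' round(cor(cohort$score, cohort$achievement)^2, 3)
#' @export
simulate_gps_cohort <- function(n, r2_schedule = c(0.04, 0.06, 0.08, 0.10),
                                stable_var = 0.78, seed = NULL) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (any(!is.finite(r2_schedule)) || any(r2_schedule < 0) ||
      any(r2_schedule >= 1)) {
    stop("invalid schedule: each R-squared must lie in [0, 1)", call. = FALSE)
  }
  if (stable_var < 0 || any(r2_schedule + stable_var >= 1)) {
    stop("invalid schedule: r2_schedule + stable_var must stay below 1",
         call. = FALSE)
  }
  p <- length(r2_schedule)
  run_seeded(seed, {
    s <- stats::rnorm(n)
    u <- stats::rnorm(n)
    ach <- matrix(0, n, p, dimnames = list(NULL, paste0("occ", seq_len(p))))
    for (t in seq_len(p)) {
      ach[, t] <- sqrt(r2_schedule[t]) * s + sqrt(stable_var) * u +
        sqrt(1 - r2_schedule[t] - stable_var) * stats::rnorm(n)
    }
    list(score = s, achievement = ach, r2_schedule = r2_schedule,
         stable_var = stable_var, seed = seed)
  })
}
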
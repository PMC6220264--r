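# Twin-cohort simulators. Latent A/C/E scores are drawn directly rather than
# via genotypes: A innovations are shared between MZ co-twins and correlated
# 0.5 for DZ co-twins (common + segregating split), C innovations are fully
# shared, E innovations are independent. Because every model here is linear
# in its innovations, the cross-twin covariance of each component is exactly
# the within-twin covariance times the sharing weight.

run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop("seed must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# n x 2 matrix of standard-normal pair scores with cross-twin correlation
# 1 ("full"), 0.5 ("half") or 0 ("none").
draw_pair_scores <- function(n, share) {
  switch(share,
    full = { z <- stats::rnorm(n); cbind(z, z) },
    half = {
      zc <- stats::rnorm(n) * sqrt(0.5)
      cbind(zc + sqrt(0.5) * stats::rnorm(n),
            zc + sqrt(0.5) * stats::rnorm(n))
    },
    none = cbind(stats::rnorm(n), stats::rnorm(n)),
    stop("unknown sharing structure: ", share))
}

component_share <- function(component, zygosity) {
  if (component == "E") return("none")
  if (component == "C") return("full")
  if (zygosity == "MZ") "full" else "half"
}

# n x 2 x T array: one component's contribution to the phenotype series of a
# pair, including occasion-specific variance.
sim_simplex_component <- function(n, comp, share) {
  p <- length(comp$beta) + 1L
  out <- array(0, c(n, 2L, p))
  lat <- comp$init_sd * draw_pair_scores(n, share)
  out[, , 1L] <- lat
  for (t in seq_len(p - 1L) + 1L) {
    lat <- comp$beta[t - 1L] * lat +
      comp$innov_sd[t - 1L] * draw_pair_scores(n, share)
    out[, , t] <- lat
  }
  for (t in seq_len(p)) {
    if (comp$spec_sd[t] > 0) {
      out[, , t] <- out[, , t] + comp$spec_sd[t] * draw_pair_scores(n, share)
    }
  }
  out
}

assign_pair_sexes <- function(n, zygosity) {
  if (zygosity == "MZ") {
    s <- ifelse(stats::runif(n) < 0.5, "F", "M")
    cbind(s, s)
  } else {
    cbind(ifelse(stats::runif(n) < 0.5, "F", "M"),
          ifelse(stats::runif(n) < 0.5, "F", "M"))
  }
}

assemble_twin_table <- function(pheno_mz, pheno_dz, measures, ages = NULL) {
  n_mz <- dim(pheno_mz)[1]; n_dz <- dim(pheno_dz)[1]
  p <- length(measures)
  sex_mz <- assign_pair_sexes(n_mz, "MZ")
  sex_dz <- assign_pair_sexes(n_dz, "DZ")
  zyg_dz <- ifelse(sex_dz[, 1] == sex_dz[, 2], "DZ", "DZO")
  df <- data.frame(
    family_id = sprintf("fam%05d", seq_len(n_mz + n_dz)),
    zygosity = c(rep("MZ", n_mz), zyg_dz),
    sex1 = c(sex_mz[, 1], sex_dz[, 1]),
    sex2 = c(sex_mz[, 2], sex_dz[, 2]),
    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    df[[paste0(measures[j], "_1")]] <- c(pheno_mz[, 1, j], pheno_dz[, 1, j])
    df[[paste0(measures[j], "_2")]] <- c(pheno_mz[, 2, j], pheno_dz[, 2, j])
  }
  if (!is.null(ages)) {
    for (j in seq_len(p)) {
      df[[paste0("age_", measures[j])]] <-
        round(ages[j] + stats::runif(n_mz + n_dz, -0.5, 0.5), 2)
    }
  }
  df
}

apply_missingness <- function(df, measures, rate) {
  if (rate <= 0) return(df)
  cols <- c(paste0(measures, "_1"), paste0(measures, "_2"))
  for (cl in cols) {
    df[[cl]][stats::runif(nrow(df)) < rate] <- NA_real_
  }
  df
}

finish_sim <- function(df, generator, seed, params, measures, mean, sd) {
  attr(df, "sim_meta") <- list(generator = generator, seed = seed,
                               params = unclass(params), measures = measures,
                               mean = mean, sd = sd)
  attr(df, "measures") <- measures
  class(df) <- c("twin_pairs", "data.frame")
  df
}

#' Simulate single-occasion MZ/DZ twin pairs under the ACE model
#'
#' Draws pairs whose phenotypic covariance follows the classical twin
#' expectations: with unit variance, the expected MZ co-twin covariance is
#' `a2 + c2` and the DZ co-twin covariance is `0.5 * a2 + c2`.
#'
#' @param n_mz,n_dz Number of MZ and DZ pairs (each at least 1). DZ pairs
#'   are a mix of same-sex (`DZ`) and opposite-sex (`DZO`) pairs; the
#'   generative model treats them identically.
#' @param params An [ace_params()] object.
#' @param seed Optional integer seed; with a fixed seed the output table is
#'   bit-identical across calls. The caller's RNG state is restored on exit.
#' @param mean,sd Location and scale applied to the standardized phenotype,
#'   so raw output need not arrive pre-standardized.
#' @param label Measure label; twin columns are `<label>_1` and `<label>_2`.
#' @return A `twin_pairs` data frame (one row per pair) with columns
#'   `family_id`, `zygosity`, `sex1`, `sex2`, the phenotype pair and an
#'   `age_<label>` column; generating parameters and seed are kept in the
#'   `sim_meta` attribute.
#' @examples
#' tw <- simulate_ace(200, 200, ace_params(0.6, 0.2, 0.2), seed = 1)
#' head(tw)
#' @export
simulate_ace <- function(n_mz, n_dz, params, seed = NULL, mean = 0, sd = 1,
                         label = "ach") {
  stopifnot(inherits(params, "ace_params"))
  if (n_mz < 1 || n_dz < 1) {
    stop("n_mz and n_dz must each be at least 1", call. = FALSE)
  }
  a <- sqrt(params$a2); cc <- sqrt(params$c2); e <- sqrt(params$e2)
  run_seeded(seed, {
    sim_group <- function(n, zyg) {
      ph <- a * draw_pair_scores(n, component_share("A", zyg)) +
        cc * draw_pair_scores(n, component_share("C", zyg)) +
        e * draw_pair_scores(n, component_share("E", zyg))
      array(mean + sd * ph, c(n, 2L, 1L))
    }
    df <- assemble_twin_table(sim_group(n_mz, "MZ"), sim_group(n_dz, "DZ"),
                              label, ages = 10)
    finish_sim(df, "simulate_ace", seed, params, label, mean, sd)
  })
}

#' Simulate longitudinal twin pairs under the genetic simplex model
#'
#' Generates multi-occasion pairs whose population covariance (within twin,
#' across twins, across occasions) equals the simplex-implied covariance
#' from [implied_covariance()]. Age-to-age phenotypic correlations decay
#' with lag, the signature of a simplex structure.
#'
#' @inheritParams simulate_ace
#' @param params A [simplex_params()] object.
#' @param missing_rate Optional probability that any single phenotype cell is
#'   missing (missing at random); default 0.
#' @param ages Nominal assessment ages used for the `age_*` columns.
#' @return A `twin_pairs` data frame with measures `<label>_t1 ..
#'   <label>_t<n>`, each with `_1`/`_2` twin columns.
#' @examples
#' tw <- simulate_simplex(300, 300, achievement_simplex_params(), seed = 1)
#' names(tw)
#' @export
simulate_simplex <- function(n_mz, n_dz, params, seed = NULL, mean = 0,
                             sd = 1, label = "ach", missing_rate = 0,
                             ages = NULL) {
  stopifnot(inherits(params, "simplex_params"))
  if (n_mz < 1 || n_dz < 1) {
    stop("n_mz and n_dz must each be at least 1", call. = FALSE)
  }
  p <- params$n_occasions
  measures <- paste0(label, "_t", seq_len(p))
  if (is.null(ages)) ages <- c(7, 11, 14, 16, seq(18, by = 2,
                                                  length.out = max(0, p - 4)))[seq_len(p)]
  run_seeded(seed, {
    sim_group <- function(n, zyg) {
      ph <- sim_simplex_component(n, params$A, component_share("A", zyg)) +
        sim_simplex_component(n, params$C, component_share("C", zyg)) +
        sim_simplex_component(n, params$E, component_share("E", zyg))
      mean + sd * ph
    }
    df <- assemble_twin_table(sim_group(n_mz, "MZ"), sim_group(n_dz, "DZ"),
                              measures, ages = ages)
    df <- apply_missingness(df, measures, missing_rate)
    finish_sim(df, "simulate_simplex", seed, params, measures, mean, sd)
  })
}

#' Simulate longitudinal twin pairs under the common pathway model
#'
#' A latent stability factor (variance 1, decomposed into A, C and E) loads
#' on every occasion; occasion residuals get their own ACE decomposition.
#' The population pair covariance equals the CPM-implied covariance from
#' [implied_covariance()].
#'
#' @inheritParams simulate_simplex
#' @param params A [cpm_params()] object.
#' @examples
#' tw <- simulate_common_pathway(300, 300, achievement_cpm_params(), seed = 1)
#' @export
simulate_common_pathway <- function(n_mz, n_dz, params, seed = NULL,
                                    mean = 0, sd = 1, label = "ach",
                                    missing_rate = 0, ages = NULL) {
  stopifnot(inherits(params, "cpm_params"))
  if (n_mz < 1 || n_dz < 1) {
    stop("n_mz and n_dz must each be at least 1", call. = FALSE)
  }
  p <- length(params$loadings)
  measures <- paste0(label, "_t", seq_len(p))
  if (is.null(ages)) ages <- c(7, 11, 14, 16, seq(18, by = 2,
                                                  length.out = max(0, p - 4)))[seq_len(p)]
  run_seeded(seed, {
    sim_group <- function(n, zyg) {
      f <- params$latent_a * draw_pair_scores(n, component_share("A", zyg)) +
        params$latent_c * draw_pair_scores(n, component_share("C", zyg)) +
        params$latent_e * draw_pair_scores(n, component_share("E", zyg))
      ph <- array(0, c(n, 2L, p))
      for (t in seq_len(p)) {
        res <- sqrt(params$resid_a2[t]) *
          draw_pair_scores(n, component_share("A", zyg)) +
          sqrt(params$resid_c2[t]) *
            draw_pair_scores(n, component_share("C", zyg)) +
          sqrt(params$resid_e2[t]) *
            draw_pair_scores(n, component_share("E", zyg))
        ph[, , t] <- params$loadings[t] * f + res
      }
      mean + sd * ph
    }
    df <- assemble_twin_table(sim_group(n_mz, "MZ"), sim_group(n_dz, "DZ"),
                              measures, ages = ages)
    df <- apply_missingness(df, measures, missing_rate)
    finish_sim(df, "simulate_common_pathway", seed, params, measures, mean, sd)
  })
}
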
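# End-to-end orchestration: simulate (or read) -> preprocess -> fit ->
# report, driven by a single YAML or list configuration, with seed capture
# and paper-style summary tables.

# drop bespoke S3 classes (keeping data frames) so derived quantities
# serialize to JSON
strip_s3 <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), strip_s3)
  } else x
}

parse_sim_params <- function(model, spec) {
  if (is.null(spec) || identical(spec, "achievement")) {
    return(switch(model,
                  ace = ace_params(0.6, 0.2, 0.2),
                  simplex = achievement_simplex_params(),
                  cpm = achievement_cpm_params(),
                  stop("unknown simulation model: ", model, call. = FALSE)))
  }
  switch(model,
         ace = ace_params(spec$a2, spec$c2, spec$e2),
         simplex = simplex_params(spec$n_occasions, A = spec$A, C = spec$C,
                                  E = spec$E),
         cpm = cpm_params(spec$latent_a, spec$latent_c, spec$latent_e,
                          spec$loadings, spec$resid_a2, spec$resid_c2,
                          spec$resid_e2),
         stop("unknown simulation model: ", model, call. = FALSE))
}

#' Render fitted twin models as paper-style tables
#'
#' Produces a long table holding both views of each fit: raw path
#' estimates with confidence bounds, standardized variance components, and
#' (for simplex fits) the transmitted/innovation/occasion-specific genetic
#' shares. Fractions are also rendered as whole percentages, the precision
#' at which such results are conventionally reported; full precision stays
#' in the numeric column.
#'
#' @param fits A list of `twinfit` objects (possibly empty).
#' @return A data frame with columns `model`, `view` (`"path"`,
#'   `"standardized"` or `"share"`), `quantity`, `estimate`, `lower`,
#'   `upper`, `percent`.
#' @export
render_tables <- function(fits) {
  empty <- data.frame(model = character(0), view = character(0),
                      quantity = character(0), estimate = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      percent = character(0), stringsAsFactors = FALSE)
  if (length(fits) == 0) return(empty)
  rows <- list(empty)
  for (fit in fits) {
    stopifnot(inherits(fit, "twinfit"))
    rows[[length(rows) + 1]] <- data.frame(
      model = fit$model, view = "path", quantity = names(fit$par),
      estimate = unname(fit$par), lower = unname(fit$ci[, "lower"]),
      upper = unname(fit$ci[, "upper"]), percent = NA_character_,
      stringsAsFactors = FALSE)
    std <- std_rows_for(fit)
    if (!is.null(std)) rows[[length(rows) + 1]] <- std
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

std_rows_for <- function(fit) {
  mk <- function(view, quantity, value) {
    data.frame(model = fit$model, view = view, quantity = quantity,
               estimate = unname(value), lower = NA_real_, upper = NA_real_,
               percent = render_percent(value), stringsAsFactors = FALSE)
  }
  d <- fit$derived
  if (fit$model == "univariate_ace") {
    return(mk("standardized", names(d$standardized), d$standardized))
  }
  if (fit$model == "cholesky" && !is.null(d$shares)) {
    return(rbind(mk("standardized", c("rG", "rC", "rE", "rPh"),
                    c(d$rG[1, 2], d$rC[1, 2], d$rE[1, 2], d$rPh_12)),
                 mk("share", paste0("share_", names(d$shares)), d$shares)))
  }
  if (fit$model == "simplex") {
    occ <- d$occasion
    gs <- d$genetic_shares
    return(rbind(
      mk("standardized", sprintf("h2_occ%d", occ$occasion), occ$h2),
      mk("standardized", sprintf("c2_occ%d", occ$occasion), occ$c2),
      mk("standardized", sprintf("e2_occ%d", occ$occasion), occ$e2),
      mk("share", sprintf("transmitted_occ%d", gs$occasion), gs$transmitted),
      mk("share", sprintf("innovation_occ%d", gs$occasion), gs$innovation),
      mk("share", sprintf("specific_occ%d", gs$occasion), gs$specific)))
  }
  if (fit$model == "common_pathway") {
    return(mk("standardized", paste0("latent_", names(d$latent)), d$latent))
  }
  NULL
}

#' Render a fraction as a whole percentage
#'
#' @param x Numeric fraction(s).
#' @return Character vector like `"17%"` (`NA` stays `NA`).
#' @examples
#' render_percent(innovation_share(0.31, 0, 0.58))
#' @export
render_percent <- function(x) {
  ifelse(is.na(x), NA_character_, paste0(round(100 * x), "%"))
}

#' Run the full simulate/preprocess/fit/report pipeline from a config
#'
#' The configuration (YAML file or list) names either a simulation block or
#' an input CSV (exactly one), the measures, the models to fit and an
#' output directory. The run writes one JSON per fitted model, a combined
#' summary table (CSV), a provenance record with the seed and package
#' version, and a timestamped log. With a fixed seed the fit JSONs are
#' byte-identical across runs.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   fields: `output_dir`; exactly one of `simulate` (with `model`
#'   `"ace"`/`"simplex"`/`"cpm"`, `n_mz`, `n_dz`, optional `params`) or
#'   `input` (CSV path); `measures`; `models` (subset of `"ace"`,
#'   `"cholesky"`, `"simplex"`, `"cpm"`); optional `seed`, `restarts`,
#'   `preprocess` (logical: residualize on age/sex and apply the rank-based
#'   normal transform).
#' @return Invisibly, a list with the fitted models, the summary table and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must name output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage '", name, "' FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    stop("config must contain exactly one of 'simulate' or 'input'",
         call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  restarts <- if (is.null(config$restarts)) 10L else
    as.integer(config$restarts)
  log_line("pipeline start (seed ", seed, ")")

  data <- stage("data", {
    if (has_sim) {
      sim <- config$simulate
      params <- parse_sim_params(sim$model, sim$params)
      log_line("simulating ", sim$model, " cohort: ", sim$n_mz, " MZ + ",
               sim$n_dz, " DZ pairs")
      switch(sim$model,
             ace = simulate_ace(sim$n_mz, sim$n_dz, params, seed = seed),
             simplex = simulate_simplex(sim$n_mz, sim$n_dz, params,
                                        seed = seed),
             cpm = simulate_common_pathway(sim$n_mz, sim$n_dz, params,
                                           seed = seed))
    } else {
      log_line("reading ", config$input)
      read_twin_pairs(config$input)
    }
  })
  measures <- config$measures
  if (is.null(measures)) measures <- attr(data, "measures")
  if (is.null(measures)) stop("config must name measures", call. = FALSE)

  if (isTRUE(config$preprocess)) {
    data <- stage("preprocess", {
      log_line("preprocessing: residualize on age/sex, normal-scores ",
               "transform")
      preprocess_twin_measures(data, measures, seed = seed)
    })
  }

  fits <- stage("fit", {
    out <- list()
    for (model in config$models) {
      log_line("fitting ", model)
      out[[model]] <- switch(
        model,
        ace = fit_univariate_ace(data, measures[1], restarts = restarts,
                                 seed = seed),
        cholesky = fit_cholesky(data, measures, restarts = restarts,
                                seed = seed),
        simplex = fit_simplex(data, measures, restarts = restarts,
                              seed = seed, min_pairs = 30),
        cpm = fit_common_pathway(data, measures, restarts = restarts,
                                 seed = seed, min_pairs = 30),
        stop("unknown model: ", model, call. = FALSE))
    }
    out
  })

  paths <- stage("report", {
    fit_paths <- character(0)
    for (model in names(fits)) {
      f <- fits[[model]]
      payload <- list(model = f$model, measures = f$measures,
                      estimates = as.list(f$par), se = as.list(f$se),
                      ci = list(lower = unname(f$ci[, "lower"]),
                                upper = unname(f$ci[, "upper"])),
                      minus2ll = f$minimum, saturated = f$saturated,
                      n_params = f$n_params,
                      n_pairs = list(MZ = f$gcov$MZ$n, DZ = f$gcov$DZ$n),
                      convergence = f$convergence,
                      derived = strip_s3(f$derived), seed = seed)
      p <- file.path(out_dir, paste0("fit_", model, ".json"))
      jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "columns")
      fit_paths <- c(fit_paths, p)
    }
    tab <- render_tables(fits)
    tab_path <- file.path(out_dir, "summary_tables.csv")
    utils::write.csv(tab, tab_path, row.names = FALSE)
    prov <- list(package = "twinpath",
                 version = as.character(utils::packageVersion("twinpath")),
                 r_version = R.version.string, seed = seed,
                 config = config)
    prov_path <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(fits = fit_paths, tables = tab_path, provenance = prov_path,
         log = log_path)
  })
  log_line("pipeline done")
  invisible(list(fits = fits, tables = render_tables(fits), paths = paths))
}

#' Standard phenotype preparation for a twin-pair table
#'
#' Applies the canonical preparation to each measure: residualize on the
#' assessment age and the twin's sex (coefficients estimated on one
#' randomly selected twin per pair, then applied to both, so families are
#' not double-counted), then map onto a normal distribution with the
#' rank-based van der Waerden transform to correct skew.
#'
#' @param data A `twin_pairs` table.
#' @param measures Measure labels to prepare.
#' @param seed Seed for the random twin selection.
#' @return The table with the measure columns replaced by prepared values.
#' @export
preprocess_twin_measures <- function(data, measures, seed = 1) {
  n <- nrow(data)
  pick <- run_seeded(seed, stats::runif(n) < 0.5)
  for (m in measures) {
    age_col <- paste0("age_", m)
    age <- if (age_col %in% names(data)) data[[age_col]] else rep(0, n)
    long_y <- c(data[[paste0(m, "_1")]], data[[paste0(m, "_2")]])
    long_x <- cbind(age = c(age, age),
                    sex = as.numeric(c(data$sex1, data$sex2) == "M"))
    # rows of the randomly chosen twin (twin 1 where pick, else twin 2)
    fit_rows <- c(which(pick), n + which(!pick))
    res <- residualize(long_y, long_x, fit_subset = fit_rows)
    res <- vdw_transform(res)
    data[[paste0(m, "_1")]] <- res[seq_len(n)]
    data[[paste0(m, "_2")]] <- res[n + seq_len(n)]
  }
  data
}
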
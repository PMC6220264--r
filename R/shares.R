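# Correlation-based estimators, share arithmetic, profile-likelihood
# confidence intervals and likelihood-ratio model comparison.

#' Double-entry intraclass correlations by zygosity group
#'
#' The pairwise-symmetrized (double-entry) Pearson correlation of co-twin
#' phenotypes, computed separately for MZ and DZ pairs (opposite-sex DZ
#' pairs are pooled with same-sex DZ pairs).
#'
#' @param data A `twin_pairs` table.
#' @param measure Measure label.
#' @return Named vector `c(MZ = ..., DZ = ...)`.
#' @export
intraclass_correlations <- function(data, measure) {
  cols <- paste0(measure, c("_1", "_2"))
  if (!all(cols %in% names(data))) {
    stop("measure columns not found: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  zyg <- ifelse(data$zygosity == "MZ", "MZ", "DZ")
  vapply(c(MZ = "MZ", DZ = "DZ"), function(g) {
    M <- as.matrix(data[zyg == g, cols, drop = FALSE])
    M <- M[stats::complete.cases(M), , drop = FALSE]
    if (nrow(M) < 3) {
      stop("group ", g, " has fewer than 3 complete pairs", call. = FALSE)
    }
    stats::cor(c(M[, 1], M[, 2]), c(M[, 2], M[, 1]))
  }, numeric(1))
}

#' Falconer's correlation-based ACE estimates
#'
#' Heritability is roughly twice the difference between the MZ and DZ
#' correlations, the shared environment is the MZ correlation minus the
#' heritability, and the non-shared environment is one minus the MZ
#' correlation. Values are returned unclipped; estimates outside `[0, 1]`
#' set the `out_of_bounds` flag rather than raising an error.
#'
#' @param r_mz,r_dz Twin intraclass correlations, each in `[-1, 1]`.
#' @return A list with `a2`, `c2`, `e2` and logical `out_of_bounds`, of
#'   class `falconer_estimates`.
#' @examples
#' falconer_estimates(0.8, 0.5)  # a2 = 0.6, c2 = 0.2, e2 = 0.2
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  a2 <- 2 * (r_mz - r_dz)
  c2 <- r_mz - a2
  e2 <- 1 - r_mz
  structure(list(a2 = unname(a2), c2 = unname(c2), e2 = unname(e2),
                 out_of_bounds = any(c(a2, c2, e2) < 0 | c(a2, c2, e2) > 1)),
            class = "falconer_estimates")
}

#' @export
print.falconer_estimates <- function(x, ...) {
  cat(sprintf("Falconer estimates: a2 = %.3f, c2 = %.3f, e2 = %.3f%s\n",
              x$a2, x$c2, x$e2,
              if (x$out_of_bounds) "  [out of bounds]" else ""))
  invisible(x)
}

#' Share of heritability due to genetic innovation
#'
#' The proportion of an occasion's heritability accounted for by genetic
#' effects new at that occasion: the squared innovation path plus the
#' squared occasion-specific genetic path, divided by the occasion's total
#' heritability. The complement is the share transmitted from earlier
#' occasions.
#'
#' @param innov_path Genetic innovation path coefficient.
#' @param specific_path Occasion-specific genetic path coefficient.
#' @param h2 The occasion's heritability (> 0).
#' @return The innovation share (a fraction).
#' @examples
#' innovation_share(0.31, 0, 0.58)  # ~0.17
#' @export
innovation_share <- function(innov_path, specific_path, h2) {
  if (!is.finite(h2) || h2 <= 0) {
    stop("h2 must be positive", call. = FALSE)
  }
  (innov_path^2 + specific_path^2) / h2
}

#' Share of heritability transmitted from the previous occasion
#'
#' The previous occasion's heritability, carried through the squared
#' genetic transmission path, as a fraction of the current occasion's
#' heritability.
#'
#' @param h2_prev Heritability at the previous occasion.
#' @param beta Genetic transmission path between the occasions.
#' @param h2_curr Heritability at the current occasion (> 0).
#' @return The transmitted share (a fraction).
#' @examples
#' transmitted_share(0.70, 0.84, 0.63)  # ~0.78
#' transmitted_share(0.73, 0.86, 0.70)  # ~0.77
#' @export
transmitted_share <- function(h2_prev, beta, h2_curr) {
  if (!is.finite(h2_curr) || h2_curr <= 0) {
    stop("h2_curr must be positive", call. = FALSE)
  }
  h2_prev * beta^2 / h2_curr
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Finds the parameter values at which the profile -2 log-likelihood (the
#' objective re-minimized over all other parameters) rises by the
#' chi-square(1) critical value above its minimum — 3.84 for a 95% level.
#'
#' @param fit A `twinfit` object (converged).
#' @param param Parameter label (an entry of `names(coef(fit))`).
#' @param level Confidence level.
#' @param max_steps Number of expanding search steps per side before giving
#'   up and returning a one-sided interval.
#' @return Length-2 vector `c(lower, upper)` bracketing the estimate. A
#'   bound that could not be located within the search range is `NA` and
#'   noted in the `flags` attribute.
#' @export
likelihood_ci <- function(fit, param, level = 0.95, max_steps = 30) {
  stopifnot(inherits(fit, "twinfit"))
  idx <- match(param, names(fit$par))
  if (is.na(idx)) {
    stop("unknown parameter: ", param, call. = FALSE)
  }
  crit <- stats::qchisq(level, 1)
  target <- fit$minimum + crit
  est <- fit$par[idx]
  k <- length(fit$par)
  prof <- function(v) {
    if (k == 1) return(fit$objective(v))
    start <- fit$par[-idx]
    f <- function(other) {
      full <- numeric(k); full[idx] <- v; full[-idx] <- other
      fit$objective(full)
    }
    stats::optim(start, f, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))$value
  }
  se <- fit$se[idx]
  step <- if (is.finite(se) && se > 0) se else 0.25 * (abs(est) + 0.1)
  flags <- character(0)
  find_bound <- function(dir) {
    lo_v <- est; lo_f <- fit$minimum
    for (s in seq_len(max_steps)) {
      v <- est + dir * s * step
      fv <- prof(v)
      if (fv >= target) {
        r <- stats::uniroot(function(z) prof(z) - target,
                            lower = min(lo_v, v), upper = max(lo_v, v),
                            tol = 1e-6 * (abs(step) + 1))
        return(r$root)
      }
      lo_v <- v; lo_f <- fv
    }
    flags <<- c(flags, paste0(if (dir < 0) "lower" else "upper",
                              " bound not found within search range"))
    NA_real_
  }
  out <- c(lower = find_bound(-1), upper = find_bound(1))
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Likelihood-ratio comparison of nested twin-model fits
#'
#' @param fit_full,fit_nested `twinfit` objects fitted to identical group
#'   covariances, with the nested model a restriction of the full model.
#' @param tol Tolerance for a slightly negative likelihood-ratio statistic
#'   (numerical slack); a larger negative value signals an optimization
#'   failure and raises an error.
#' @return A list with `lrt`, `df` and `p` (chi-square with `df` degrees of
#'   freedom; `p = 1` when the models have equal dimension and fit).
#' @export
compare_models <- function(fit_full, fit_nested, tol = 1e-4) {
  stopifnot(inherits(fit_full, "twinfit"), inherits(fit_nested, "twinfit"))
  same_data <- isTRUE(all.equal(fit_full$gcov$MZ$S, fit_nested$gcov$MZ$S)) &&
    fit_full$gcov$MZ$n == fit_nested$gcov$MZ$n &&
    fit_full$gcov$DZ$n == fit_nested$gcov$DZ$n
  if (!same_data) {
    stop("models were not fitted to identical data", call. = FALSE)
  }
  lrt <- fit_nested$minimum - fit_full$minimum
  scale_tol <- tol * max(1, abs(fit_full$minimum))
  if (lrt < -scale_tol) {
    stop("negative likelihood-ratio statistic (", format(lrt, digits = 6),
         "): the full model fits worse than its restriction, which signals ",
         "an optimization failure", call. = FALSE)
  }
  lrt <- max(lrt, 0)
  df <- fit_full$n_params - fit_nested$n_params
  if (df < 0) {
    stop("fit_nested has more parameters than fit_full", call. = FALSE)
  }
  p <- if (df == 0) 1 else stats::pchisq(lrt, df, lower.tail = FALSE)
  list(lrt = lrt, df = df, p = p)
}
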
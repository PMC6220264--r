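# Maximum-likelihood fitting of twin covariance-structure models. All
# models are parameterized in path coefficients (variances enter as
# squares), which keeps every implied covariance positive semi-definite
# without box constraints; signs of standard-deviation-like paths are fixed
# non-negative after optimization. Optimization is quasi-Newton (BFGS on a
# per-pair-scaled objective) from a moment-informed start plus jittered
# random restarts.

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

fit_twin_engine <- function(gcov, model, labels, start, par_to_params,
                            normalize = identity, restarts = 10,
                            jitter = 0.1, seed = 1, grad_tol = 1e-4,
                            fail_tol = 0.05, fix = NULL) {
  if (!is.null(fix)) {
    if (!all(names(fix) %in% labels)) {
      stop("fix names unknown parameter(s): ",
           paste(setdiff(names(fix), labels), collapse = ", "),
           call. = FALSE)
    }
    fixed_idx <- match(names(fix), labels)
    free_idx <- setdiff(seq_along(labels), fixed_idx)
    if (length(free_idx) == 0) stop("no free parameters left", call. = FALSE)
    embed <- function(pf) {
      full <- numeric(length(labels))
      full[fixed_idx] <- fix
      full[free_idx] <- pf
      full
    }
    p2p_full <- par_to_params
    norm_full <- normalize
    par_to_params <- function(pf) p2p_full(embed(pf))
    normalize <- function(pf) norm_full(embed(pf))[free_idx]
    start <- start[free_idx]
    labels <- labels[free_idx]
  }
  N <- gcov$MZ$n + gcov$DZ$n
  obj_raw <- function(par) as.numeric(neg2ll(par_to_params(par), gcov))
  obj <- function(par) obj_raw(par) / N
  ctrl <- list(maxit = 2000, reltol = 1e-14)
  res <- run_seeded(seed, {
    starts <- list(start)
    if (restarts > 1) {
      for (i in seq_len(restarts - 1)) {
        starts[[i + 1]] <- start + stats::rnorm(length(start), 0, jitter)
      }
    }
    lapply(starts, function(s) {
      tryCatch(stats::optim(s, obj, method = "BFGS", control = ctrl),
               error = function(e) list(value = Inf, par = s))
    })
  })
  vals <- vapply(res, `[[`, numeric(1), "value")
  if (!any(is.finite(vals))) {
    stop("fit_", model, ": optimizer failed from every start", call. = FALSE)
  }
  best <- res[[which.min(vals)]]
  polish <- stats::optim(best$par, obj, method = "BFGS", control = ctrl,
                         hessian = TRUE)
  par <- normalize(polish$par)
  # sign normalization leaves the objective unchanged; re-evaluate to be safe
  minimum <- obj_raw(par)
  grad_norm <- sqrt(sum(num_grad(obj, par)^2))
  spread <- if (sum(is.finite(vals)) > 1) {
    sv <- sort(vals[is.finite(vals)])
    sv[2] - sv[1]
  } else 0
  converged <- grad_norm < grad_tol
  if (grad_norm > fail_tol) {
    stop("fit_", model, " did not converge: scaled gradient norm ",
         format(grad_norm, digits = 4), "; restart objective values: ",
         paste(format(vals * N, digits = 10), collapse = ", "),
         call. = FALSE)
  }
  H <- polish$hessian * N            # hessian of the raw -2lnL
  vc <- tryCatch(2 * solve(H), error = function(e) NULL)
  se <- if (!is.null(vc)) {
    d <- diag(vc); d[d < 0] <- NA_real_; sqrt(d)
  } else rep(NA_real_, length(par))
  names(par) <- names(se) <- labels
  ci <- cbind(lower = par - 1.96 * se, upper = par + 1.96 * se)
  rownames(ci) <- labels
  list(par = par, se = se, ci = ci, vcov = vc, minimum = minimum,
       objective = obj_raw, par_to_params = par_to_params, fix = fix,
       convergence = list(converged = converged, grad_norm = grad_norm,
                          restart_spread = spread, restarts = restarts))
}

new_twinfit <- function(engine, model, gcov, derived) {
  structure(
    c(engine,
      list(model = model, measures = gcov$labels, gcov = gcov,
           n_params = length(engine$par),
           params = engine$par_to_params(engine$par),
           saturated = saturated_neg2ll(gcov), derived = derived)),
    class = "twinfit")
}

icc_from_gcov <- function(gcov) {
  p <- length(gcov$labels)
  vapply(c("MZ", "DZ"), function(g) {
    S <- gcov[[g]]$S
    mean(vapply(seq_len(p), function(j) {
      S[j, j + p] / sqrt(S[j, j] * S[j + p, j + p])
    }, numeric(1)))
  }, numeric(1))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ---------------------------------------------------------------------------
# Univariate ACE

#' Fit the univariate ACE model to twin-pair data
#'
#' Maximum-likelihood decomposition of one measure's variance into additive
#' genetic (A), shared environmental (C) and non-shared environmental (E)
#' components, estimated from the MZ and DZ pair covariances by the
#' multi-group Wishart likelihood. Path coefficients `a`, `c`, `e` are
#' estimated; standardized components are their squares over the total.
#'
#' @param data A `twin_pairs` table or a `group_covariances` object.
#' @param measure Measure label (twin columns `<measure>_1`, `<measure>_2`).
#' @param min_pairs Minimum complete pairs required per group.
#' @param restarts Number of optimizer starts (first is moment-informed,
#'   the rest jittered around it).
#' @param jitter Standard deviation of the restart jitter.
#' @param seed Seed used only for the restart jitter; the caller's RNG
#'   state is restored.
#' @param fix Optional named numeric vector of parameters held fixed during
#'   estimation (e.g. `c(c = 0)` drops the shared-environment path),
#'   yielding a nested model for [compare_models()].
#' @return A `twinfit` object. `$derived$standardized` holds `a2`, `c2`,
#'   `e2` (summing to 1); `$derived$falconer` the correlation-based
#'   estimates for comparison.
#' @examples
#' tw <- simulate_ace(400, 400, ace_params(0.6, 0.2, 0.2), seed = 1)
#' fit <- fit_univariate_ace(tw, "ach", restarts = 3)
#' fit
#' @export
fit_univariate_ace <- function(data, measure, min_pairs = 30, restarts = 10,
                               jitter = 0.1, seed = 1, fix = NULL) {
  stopifnot(length(measure) == 1)
  gcov <- group_covariances(data, measure, min_pairs)
  icc <- icc_from_gcov(gcov)
  fal <- falconer_estimates(icc["MZ"], icc["DZ"])
  vbar <- mean(c(diag(gcov$MZ$S), diag(gcov$DZ$S)))
  start <- sqrt(clip(c(fal$a2, fal$c2, fal$e2), 0.05, 0.9) * vbar)
  par_to_params <- function(par) {
    structure(list(L_A = matrix(par[1]), L_C = matrix(par[2]),
                   L_E = matrix(par[3])), class = "cholesky_params")
  }
  eng <- fit_twin_engine(gcov, "univariate_ace", c("a", "c", "e"), start,
                         par_to_params, normalize = abs,
                         restarts = restarts, jitter = jitter, seed = seed,
                         fix = fix)
  comp <- component_covariances(eng$par_to_params(eng$par))
  tot <- comp$A[1] + comp$C[1] + comp$E[1]
  std <- c(a2 = comp$A[1], c2 = comp$C[1], e2 = comp$E[1]) / tot
  new_twinfit(eng, "univariate_ace", gcov,
              list(standardized = std, total_variance = tot,
                   falconer = fal, icc = icc))
}

# ---------------------------------------------------------------------------
# Cholesky

lower_tri_labels <- function(comp, p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  sprintf("%s_%d%d", tolower(comp), idx[, "row"], idx[, "col"])
}

fill_lower <- function(x, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- x
  L
}

# moment estimates of the per-component covariances, floored to PD
moment_component_covs <- function(gcov) {
  p <- length(gcov$labels)
  blocks <- lapply(c("MZ", "DZ"), function(g) {
    S <- gcov[[g]]$S
    W <- S[seq_len(p), seq_len(p)]
    X <- S[seq_len(p), p + seq_len(p)]
    list(W = W, X = (X + t(X)) / 2)
  })
  names(blocks) <- c("MZ", "DZ")
  W <- (blocks$MZ$W * gcov$MZ$n + blocks$DZ$W * gcov$DZ$n) /
    (gcov$MZ$n + gcov$DZ$n)
  A <- 2 * (blocks$MZ$X - blocks$DZ$X)
  C <- 2 * blocks$DZ$X - blocks$MZ$X
  E <- W - blocks$MZ$X
  floor_pd <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0.02 * mean(diag(W)))
    e$vectors %*% (lam * t(e$vectors))
  }
  list(A = floor_pd(A), C = floor_pd(C), E = floor_pd(E), W = W)
}

#' Fit a multivariate Cholesky ACE decomposition
#'
#' Decomposes the covariance among `p` measures into A, C and E structures,
#' each parameterized as a lower-triangular path matrix `L` with implied
#' component covariance `L %*% t(L)`.
#'
#' @inheritParams fit_univariate_ace
#' @param measures Character vector of 2 or more measure labels.
#' @return A `twinfit` object. `$derived` holds the component covariance
#'   matrices, the genetic/shared/non-shared correlations (`rG`, `rC`,
#'   `rE`), and for bivariate fits the share of the phenotypic correlation
#'   attributable to each component (`shares`, summing to 1; flagged `NaN`
#'   when the phenotypic correlation is near zero).
#' @export
fit_cholesky <- function(data, measures, min_pairs = 30, restarts = 10,
                         jitter = 0.1, seed = 1, fix = NULL) {
  p <- length(measures)
  stopifnot(p >= 2)
  gcov <- group_covariances(data, measures, min_pairs)
  mom <- moment_component_covs(gcov)
  start <- unlist(lapply(mom[c("A", "C", "E")], function(M) {
    t(chol(M))[lower.tri(M, diag = TRUE)]
  }), use.names = FALSE)
  labels <- c(lower_tri_labels("A", p), lower_tri_labels("C", p),
              lower_tri_labels("E", p))
  k <- p * (p + 1) / 2
  par_to_params <- function(par) {
    structure(list(L_A = fill_lower(par[seq_len(k)], p),
                   L_C = fill_lower(par[k + seq_len(k)], p),
                   L_E = fill_lower(par[2 * k + seq_len(k)], p)),
              class = "cholesky_params")
  }
  normalize <- function(par) {
    unlist(lapply(0:2, function(b) {
      L <- fill_lower(par[b * k + seq_len(k)], p)
      for (j in seq_len(p)) if (L[j, j] < 0) L[, j] <- -L[, j]
      L[lower.tri(L, diag = TRUE)]
    }), use.names = FALSE)
  }
  eng <- fit_twin_engine(gcov, "cholesky", labels, start, par_to_params,
                         normalize = normalize, restarts = restarts,
                         jitter = jitter, seed = seed, fix = fix)
  comp <- component_covariances(eng$par_to_params(eng$par))
  sigma_p <- comp$A + comp$C + comp$E
  corr_of <- function(M) {
    d <- sqrt(diag(M)); M / tcrossprod(d)
  }
  derived <- list(sigma = comp, rG = corr_of(comp$A), rC = corr_of(comp$C),
                  rE = corr_of(comp$E), rPh = corr_of(sigma_p),
                  standardized = vapply(comp, function(M) diag(M) / diag(sigma_p),
                                        numeric(p)))
  if (p == 2) {
    cov_ph <- sigma_p[1, 2]
    r_ph <- derived$rPh[1, 2]
    if (abs(r_ph) < 0.05) {
      shares <- c(A = NaN, C = NaN, E = NaN)
      attr(shares, "flag") <- "phenotypic correlation near zero"
    } else {
      shares <- c(A = comp$A[1, 2], C = comp$C[1, 2], E = comp$E[1, 2]) / cov_ph
    }
    derived$shares <- shares
    derived$rPh_12 <- r_ph
  }
  new_twinfit(eng, "cholesky", gcov, derived)
}

#' @rdname fit_cholesky
#' @export
fit_bivariate_cholesky <- function(data, measures, min_pairs = 30,
                                   restarts = 10, jitter = 0.1, seed = 1,
                                   fix = NULL) {
  stopifnot(length(measures) == 2)
  fit_cholesky(data, measures, min_pairs, restarts, jitter, seed, fix)
}

# ---------------------------------------------------------------------------
# Simplex

simplex_par_layout <- function(T_occ, specific) {
  comps <- c("A", "C", "E")
  layout <- list()
  labels <- character(0)
  pos <- 0L
  for (cm in comps) {
    n_spec <- if (cm %in% specific) T_occ - 2L else 0L
    idx <- list(init = pos + 1L,
                beta = pos + 1L + seq_len(T_occ - 1L),
                innov = pos + T_occ + seq_len(T_occ - 1L),
                spec = if (n_spec) pos + 2L * T_occ - 1L + seq_len(n_spec)
                       else integer(0))
    pos <- pos + 2L * T_occ - 1L + n_spec
    layout[[cm]] <- idx
    labels <- c(labels, paste0(cm, "_init"),
                sprintf("%s_beta_%d%d", cm, seq_len(T_occ - 1L),
                        seq_len(T_occ - 1L) + 1L),
                sprintf("%s_innov_%d", cm, seq_len(T_occ - 1L) + 1L),
                if (n_spec) sprintf("%s_spec_%d", cm, seq_len(n_spec) + 1L))
  }
  list(layout = layout, labels = labels, n = pos)
}

simplex_par_to_params <- function(layout, T_occ) {
  function(par) {
    comps <- lapply(layout, function(idx) {
      spec <- rep(0, T_occ)
      if (length(idx$spec)) spec[1L + seq_along(idx$spec)] <- par[idx$spec]
      list(init_sd = par[idx$init], beta = par[idx$beta],
           innov_sd = par[idx$innov], spec_sd = spec)
    })
    structure(list(n_occasions = T_occ, A = comps$A, C = comps$C,
                   E = comps$E), class = "simplex_params")
  }
}

#' Fit the longitudinal genetic simplex model
#'
#' Each of the A, C and E influences follows a latent first-order
#' autoregression over measurement occasions: an initial standard
#' deviation, transmission paths between adjacent occasions, innovation
#' standard deviations at every occasion after the first, and (for the
#' components named in `specific`) occasion-specific standard deviations at
#' interior occasions. Occasion-specific paths are fixed to zero at the
#' first occasion (confounded with the initial variance) and the last
#' occasion (confounded with the final innovation) for identification.
#'
#' @inheritParams fit_univariate_ace
#' @param measures Measure labels in occasion order (at least 3).
#' @param specific Components that receive free occasion-specific paths at
#'   interior occasions; default `"A"`. For a component whose transmission
#'   is near zero, occasion-specific and innovation variance are empirically
#'   confounded, so specifics for C and E are off by default.
#' @return A `twinfit` object. `$derived$occasion` tabulates per-occasion
#'   variance components and heritabilities; `$derived$genetic_shares`
#'   decomposes each occasion's genetic variance into transmitted,
#'   innovation and occasion-specific fractions.
#' @examples
#' \donttest{
#' tw <- simulate_simplex(500, 500, achievement_simplex_params(), seed = 1)
#' fit <- fit_simplex(tw, paste0("ach_t", 1:4), restarts = 3)
#' fit$derived$occasion
#' }
#' @export
fit_simplex <- function(data, measures, specific = "A", min_pairs = 200,
                        restarts = 10, jitter = 0.1, seed = 1, fix = NULL) {
  T_occ <- length(measures)
  if (T_occ < 3) {
    stop("the simplex model needs at least 3 occasions", call. = FALSE)
  }
  stopifnot(all(specific %in% c("A", "C", "E")))
  gcov <- group_covariances(data, measures, min_pairs)
  lay <- simplex_par_layout(T_occ, specific)
  par_to_params <- simplex_par_to_params(lay$layout, T_occ)

  # moment-informed start: per-occasion Falconer components and lag-1
  # phenotypic regression coefficients
  mom <- moment_component_covs(gcov)
  v <- diag(mom$W)
  comp_frac <- vapply(mom[c("A", "C", "E")],
                      function(M) clip(diag(M) / v, 0.05, 0.9), numeric(T_occ))
  beta_ph <- vapply(seq_len(T_occ - 1L), function(t) {
    clip(mom$W[t, t + 1L] / mom$W[t, t], 0.2, 0.95)
  }, numeric(1))
  start <- numeric(lay$n)
  for (cm in c("A", "C", "E")) {
    idx <- lay$layout[[cm]]
    cv <- comp_frac[, cm] * v
    start[idx$init] <- sqrt(cv[1])
    b0 <- if (cm == "E") rep(0.1, T_occ - 1L) else beta_ph
    start[idx$beta] <- b0
    start[idx$innov] <- sqrt(pmax(cv[-1L] - b0^2 * cv[-T_occ], 0.05 * v[-1L]))
    if (length(idx$spec)) start[idx$spec] <- sqrt(0.05 * v[2:(T_occ - 1L)])
  }
  normalize <- function(par) {
    for (idx in lay$layout) {
      par[c(idx$init, idx$innov, idx$spec)] <-
        abs(par[c(idx$init, idx$innov, idx$spec)])
    }
    par
  }
  eng <- fit_twin_engine(gcov, "simplex", lay$labels, start, par_to_params,
                         normalize = normalize, restarts = restarts,
                         jitter = jitter, seed = seed, fix = fix)
  params <- eng$par_to_params(eng$par)
  derived <- simplex_derived(params)
  new_twinfit(eng, "simplex", gcov, derived)
}

simplex_derived <- function(params) {
  T_occ <- params$n_occasions
  lat <- lapply(params[c("A", "C", "E")], function(comp) {
    V <- numeric(T_occ); V[1] <- comp$init_sd^2
    for (t in seq_len(T_occ - 1L) + 1L) {
      V[t] <- comp$beta[t - 1L]^2 * V[t - 1L] + comp$innov_sd[t - 1L]^2
    }
    V
  })
  tot <- lapply(c(A = "A", C = "C", E = "E"), function(cm) {
    lat[[cm]] + params[[cm]]$spec_sd^2
  })
  vP <- tot$A + tot$C + tot$E
  occ <- data.frame(occasion = seq_len(T_occ), var_A = tot$A, var_C = tot$C,
                    var_E = tot$E, var_P = vP, h2 = tot$A / vP,
                    c2 = tot$C / vP, e2 = tot$E / vP)
  gs <- data.frame(occasion = seq_len(T_occ - 1L) + 1L)
  a <- params$A
  trans <- a$beta^2 * lat$A[-T_occ]
  gs$transmitted <- ifelse(tot$A[-1L] > 1e-10, trans / tot$A[-1L], NaN)
  gs$innovation <- ifelse(tot$A[-1L] > 1e-10,
                          a$innov_sd^2 / tot$A[-1L], NaN)
  gs$specific <- ifelse(tot$A[-1L] > 1e-10,
                        a$spec_sd[-1L]^2 / tot$A[-1L], NaN)
  list(occasion = occ, genetic_shares = gs, latent_var = lat)
}

# ---------------------------------------------------------------------------
# Common pathway

#' Fit the common pathway model
#'
#' A single latent factor with unit variance, decomposed into A, C and E
#' (squared latent paths summing to one), loads on every occasion; each
#' occasion's residual variance receives its own ACE decomposition. The
#' latent heritability is the headline estimate of how much of the stable
#' variance across occasions is genetic. Internally the first loading is
#' fixed to 1 and the latent scale is free; reported quantities are
#' standardized, which reproduces the unit-latent-variance convention.
#' Residual variances enter as squared paths, so Heywood-style negative
#' residuals cannot occur.
#'
#' @inheritParams fit_simplex
#' @return A `twinfit` object. `$derived$latent` holds the standardized
#'   latent `a2`, `c2`, `e2` (summing to 1 exactly);
#'   `$derived$occasion` the per-occasion standardized decomposition into
#'   common and residual ACE parts.
#' @export
fit_common_pathway <- function(data, measures, min_pairs = 200,
                               restarts = 10, jitter = 0.1, seed = 1,
                               fix = NULL) {
  T_occ <- length(measures)
  if (T_occ < 3) {
    stop("the common pathway model needs at least 3 occasions", call. = FALSE)
  }
  gcov <- group_covariances(data, measures, min_pairs)
  labels <- c("x_a", "x_c", "x_e",
              sprintf("lambda_%d", seq_len(T_occ - 1L) + 1L),
              sprintf("res_a_%d", seq_len(T_occ)),
              sprintf("res_c_%d", seq_len(T_occ)),
              sprintf("res_e_%d", seq_len(T_occ)))
  par_to_params <- function(par) {
    s <- par[1]^2 + par[2]^2 + par[3]^2 + 1e-300
    lam <- sqrt(s) * c(1, par[3L + seq_len(T_occ - 1L)])
    structure(list(latent_a = par[1] / sqrt(s), latent_c = par[2] / sqrt(s),
                   latent_e = par[3] / sqrt(s), loadings = lam,
                   resid_a2 = par[3L + T_occ - 1L + seq_len(T_occ)]^2,
                   resid_c2 = par[3L + 2L * T_occ - 1L + seq_len(T_occ)]^2,
                   resid_e2 = par[3L + 3L * T_occ - 1L + seq_len(T_occ)]^2),
              class = "cpm_params")
  }
  # start from the leading principal axis of the pooled within covariance
  mom <- moment_component_covs(gcov)
  eW <- eigen(mom$W, symmetric = TRUE)
  lam_raw <- sqrt(eW$values[1]) * eW$vectors[, 1]
  if (lam_raw[1] < 0) lam_raw <- -lam_raw
  s0 <- lam_raw[1]^2
  resid0 <- pmax(diag(mom$W) - lam_raw^2, 0.05 * diag(mom$W))
  start <- c(sqrt(0.6 * s0), sqrt(0.3 * s0), sqrt(0.1 * s0),
             lam_raw[-1L] / lam_raw[1],
             sqrt(0.3 * resid0), sqrt(0.2 * resid0), sqrt(0.5 * resid0))
  normalize <- function(par) {
    par[c(1:3, 3L + (T_occ - 1L) + seq_len(3L * T_occ))] <-
      abs(par[c(1:3, 3L + (T_occ - 1L) + seq_len(3L * T_occ))])
    par
  }
  eng <- fit_twin_engine(gcov, "common_pathway", labels, start,
                         par_to_params, normalize = normalize,
                         restarts = restarts, jitter = jitter, seed = seed,
                         fix = fix)
  params <- eng$par_to_params(eng$par)
  latent <- c(a2 = unname(params$latent_a)^2, c2 = unname(params$latent_c)^2,
              e2 = unname(params$latent_e)^2)
  comp <- component_covariances(params)
  vP <- diag(comp$A + comp$C + comp$E)
  common_var <- params$loadings^2
  occ <- data.frame(
    occasion = seq_len(T_occ),
    common = common_var / vP,
    A = diag(comp$A) / vP, C = diag(comp$C) / vP, E = diag(comp$E) / vP,
    res_a2 = params$resid_a2 / vP, res_c2 = params$resid_c2 / vP,
    res_e2 = params$resid_e2 / vP)
  new_twinfit(eng, "common_pathway", gcov,
              list(latent = latent, occasion = occ))
}

# ---------------------------------------------------------------------------
# twinfit methods

#' @export
print.twinfit <- function(x, digits = 3, ...) {
  cat("Twin model fit:", x$model, "\n")
  cat("Measures:", paste(x$measures, collapse = ", "), "\n")
  cat(sprintf("Pairs: MZ %d, DZ %d; -2lnL = %.3f (saturated %.3f), %d parameters\n",
              x$gcov$MZ$n, x$gcov$DZ$n, x$minimum, x$saturated, x$n_params))
  conv <- x$convergence
  cat(sprintf("Converged: %s (scaled gradient norm %.2g, restart spread %.2g)\n",
              conv$converged, conv$grad_norm, conv$restart_spread))
  est <- cbind(estimate = x$par, se = x$se, x$ci)
  print(round(est, digits))
  invisible(x)
}

#' @export
summary.twinfit <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  if (!is.null(object$derived$standardized)) {
    cat("\nStandardized variance components:\n")
    print(round(object$derived$standardized, digits))
  }
  if (!is.null(object$derived$latent)) {
    cat("\nLatent factor ACE decomposition:\n")
    print(round(object$derived$latent, digits))
  }
  if (!is.null(object$derived$occasion)) {
    cat("\nPer-occasion decomposition:\n")
    print(round(as.data.frame(object$derived$occasion), digits))
  }
  invisible(object)
}

#' @export
coef.twinfit <- function(object, ...) object$par

#' @export
logLik.twinfit <- function(object, ...) {
  structure(-object$minimum / 2, df = object$n_params,
            nobs = object$gcov$MZ$n + object$gcov$DZ$n, class = "logLik")
}

#' @export
vcov.twinfit <- function(object, ...) object$vcov

#' @export
confint.twinfit <- function(object, parm = NULL, level = 0.95,
                            method = c("wald", "profile"), ...) {
  method <- match.arg(method)
  if (is.null(parm)) parm <- names(object$par)
  if (is.numeric(parm)) parm <- names(object$par)[parm]
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(object$par[parm] - z * object$se[parm],
                object$par[parm] + z * object$se[parm])
  } else {
    ci <- t(vapply(parm, function(p) likelihood_ci(object, p, level),
                   numeric(2)))
  }
  dimnames(ci) <- list(parm, c("lower", "upper"))
  ci
}
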
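# SNP heritability by restricted maximum likelihood on a GRM. The model is
# y = X beta + g + e with g ~ N(0, sigma2_g * G) and e ~ N(0, sigma2_e * I).
# A single eigendecomposition of G diagonalizes every V = sigma2_g * D +
# sigma2_e * I, so each iteration is O(n^2). Updates are average-information
# (AI) steps with an expectation-maximization fallback whenever an AI step
# would leave the parameter space.

#' Estimate SNP heritability by AI-REML on a GRM
#'
#' Fits the GRM-based mixed linear model by restricted maximum likelihood
#' with average-information updates (EM fallback on steps that would turn a
#' variance negative) and reports the SNP heritability
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` with a standard error from the
#' inverse AI matrix (delta method for `h2`). Intended for samples already
#' pruned of close relatives (see [prune_related()]).
#'
#' @param grm A `grm` object.
#' @param pheno Numeric phenotype vector aligned with `grm$sample_ids`.
#' @param covariates Optional matrix of fixed-effect covariates (an
#'   intercept is always included).
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param algorithm `"ai"` (default) or `"em"` for pure EM updates, whose
#'   restricted log-likelihood is non-decreasing.
#' @return A `greml` object with `sigma2_g`, `sigma2_e`, `h2_snp`, `se`
#'   (named: `sigma2_g`, `sigma2_e`, `h2`), `loglik`, `iterations`,
#'   `converged`, `boundary` and the log-likelihood `trajectory`.
#' @examples
#' \donttest{
#' panel <- simulate_genotypes(500, 1000, seed = 1)
#' y <- simulate_snp_phenotype(panel, 0.3, seed = 2)
#' fit <- reml_fit(compute_grm(panel), y)
#' fit
#' }
#' @export
reml_fit <- function(grm, pheno, covariates = NULL, max_iter = 100,
                     tol = 1e-6, algorithm = c("ai", "em")) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(pheno)
  n <- length(y)
  if (n != nrow(grm$G)) {
    stop("phenotype length does not match the GRM", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- ncol(X)
  if (n <= q + 2) stop("too few individuals for REML", call. = FALSE)
  keep <- is.finite(y) & rowSums(!is.finite(X)) == 0
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    grm <- subset_grm(grm, grm$sample_ids[keep])
    n <- length(y)
  }
  eg <- eigen(grm$G, symmetric = TRUE)
  d <- eg$values
  if (stats::sd(d) < 1e-8) {
    stop("GRM eigenvalues are (near) constant: genetic and residual ",
         "variance are not separately identifiable (is the GRM an ",
         "identity matrix?)", call. = FALSE)
  }
  yr <- drop(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)

  vp <- stats::var(y)
  theta <- c(g = vp / 2, e = vp / 2)
  floor_v <- 1e-8 * vp

  # returns Pv products and traces needed by the scores and AI matrix;
  # everything is diagonal in the rotated basis except the fixed-effect
  # projection
  reml_parts <- function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    vi <- 1 / v
    XtViX <- crossprod(Xr, vi * Xr)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    XtViy <- crossprod(Xr, vi * yr)
    beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
    Py <- vi * (yr - drop(Xr %*% beta))
    # tr(P M) for diagonal M (in rotated basis):
    # tr(Vi M) - tr((X'ViX)^-1 X'Vi M Vi X)
    tr_P <- function(mdiag) {
      B <- vi * mdiag * vi * Xr
      sum(vi * mdiag) - sum(chol2inv(ch) * crossprod(Xr, B))
    }
    loglik <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) +
                        sum(yr * Py))
    list(Py = Py, tr_PG = tr_P(d), tr_PI = tr_P(rep(1, n)),
         vi = vi, ch = ch, loglik = loglik)
  }

  project_P <- function(parts, w) {
    # P %*% w for a rotated vector w
    b <- chol2inv(parts$ch) %*% crossprod(Xr, parts$vi * w)
    parts$vi * (w - drop(Xr %*% b))
  }

  parts <- reml_parts(theta)
  if (is.null(parts)) stop("initial variance components infeasible",
                           call. = FALSE)
  traj <- parts$loglik
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    Py <- parts$Py
    GPy <- d * Py
    score <- 0.5 * c(sum(Py * GPy) - parts$tr_PG,
                     sum(Py * Py) - parts$tr_PI)
    PGPy <- project_P(parts, GPy)
    PPy <- project_P(parts, Py)
    AI <- 0.5 * matrix(c(sum(GPy * PGPy), sum(GPy * PPy),
                         sum(GPy * PPy), sum(Py * PPy)), 2, 2)
    em_step <- c(theta[1] + theta[1]^2 * (sum(Py * GPy) - parts$tr_PG) / n,
                 theta[2] + theta[2]^2 * (sum(Py * Py) - parts$tr_PI) / n)
    step <- if (algorithm == "em") NULL else
      tryCatch(solve(AI, score), error = function(e) NULL)
    # AI proposals that leave the parameter space are clamped to the floor
    # (a variance heading negative is a boundary solution, where EM crawls);
    # a proposal that worsens the restricted likelihood is halved back
    # toward the current point, with EM as the last resort
    proposals <- list()
    if (!is.null(step)) {
      for (h in 0:4) proposals <- c(proposals, list(theta + step / 2^h))
    }
    proposals <- c(proposals, list(em_step))
    theta_new <- NULL
    for (cand in proposals) {
      cand <- pmax(cand, floor_v)
      cand_parts <- reml_parts(cand)
      if (!is.null(cand_parts) &&
          (algorithm == "em" || cand_parts$loglik >= parts$loglik - 1e-8 ||
             identical(cand, pmax(em_step, floor_v)))) {
        theta_new <- cand
        parts_new <- cand_parts
        break
      }
    }
    if (is.null(theta_new)) break
    delta <- parts_new$loglik - parts$loglik
    theta <- theta_new
    parts <- parts_new
    traj <- c(traj, parts$loglik)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("REML did not converge after ", max_iter,
         " iterations; log-likelihood trajectory: ",
         paste(format(utils::tail(traj, 5), digits = 8), collapse = ", "),
         call. = FALSE)
  }
  vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sum(theta)
  h2 <- theta[1] / tot
  grad_h2 <- c(theta[2], -theta[1]) / tot^2
  se <- c(sigma2_g = sqrt(vc[1, 1]), sigma2_e = sqrt(vc[2, 2]),
          h2 = sqrt(drop(t(grad_h2) %*% vc %*% grad_h2)))
  boundary <- theta[1] <= floor_v * 1.01 || theta[2] <= floor_v * 1.01
  structure(list(sigma2_g = unname(theta[1]), sigma2_e = unname(theta[2]),
                 h2_snp = unname(h2), se = se, loglik = parts$loglik,
                 iterations = it, converged = converged,
                 boundary = boundary, trajectory = traj, n = n,
                 algorithm = algorithm),
            class = "greml")
}

#' @export
print.greml <- function(x, ...) {
  cat(sprintf("GREML fit (%s): n = %d, %d iterations%s\n",
              toupper(x$algorithm), x$n, x$iterations,
              if (x$boundary) " [boundary estimate]" else ""))
  cat(sprintf("  sigma2_g = %.4f (SE %.4f)\n", x$sigma2_g, x$se["sigma2_g"]))
  cat(sprintf("  sigma2_e = %.4f (SE %.4f)\n", x$sigma2_e, x$se["sigma2_e"]))
  cat(sprintf("  h2_SNP   = %.4f (SE %.4f)\n", x$h2_snp, x$se["h2"]))
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) print(object, ...)
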
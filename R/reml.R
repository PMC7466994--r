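# Spectral (eigendecomposition) REML for the one-random-component model
#   y = X b + u + e,  u ~ N(0, sigma_g2 * K),  e ~ N(0, sigma_e2 * I).
# The restricted likelihood is profiled down to the single ratio
# delta = sigma_e2 / sigma_g2 and maximised on a log grid followed by
# golden-section refinement; everything else is closed-form.

reml_profile <- function(xi, eta2, delta) {
  m <- length(xi)
  s <- sum(eta2 / (xi + delta))
  0.5 * (m * log(m / (2 * pi)) - m - m * log(s) - sum(log(xi + delta)))
}

#' Fit the null mixed model by spectral REML
#'
#' Estimates the variance components of `y = X b + u + e` with
#' `u ~ N(0, sigma_g2 K)` by restricted maximum likelihood: the
#' covariate-projected `K` is eigendecomposed once and the restricted
#' log-likelihood, profiled to the ratio `delta = sigma_e2 / sigma_g2`, is
#' maximised over a 100-point log grid on `[1e-5, 1e5]` with golden-section
#' refinement to 1e-6. The returned object caches the eigendecomposition of
#' `K` itself for downstream whitening (P3D association scans, BLUP).
#'
#' @param y Numeric response (population means).
#' @param K Covariance structure: a [kinship_matrix] or plain symmetric
#'   matrix conformable with `y`.
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @return A `null_mm` object: `sigma_g2`, `sigma_e2`, `delta`, `loglik`,
#'   `beta` (GLS fixed effects), and the cached spectral decomposition.
#' @export
fit_null_mm <- function(y, K, covariates = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$G
  n <- length(y)
  if (!is.numeric(y) || anyNA(y)) {
    stop_poolgp("`y` must be numeric with no missing values.", "poolgp_invalid_argument")
  }
  if (!is.matrix(K) || any(dim(K) != n)) {
    stop_poolgp("`K` must be an n x n matrix conformable with `y`.",
      "poolgp_invalid_argument")
  }
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(abs(eK$values), 1)) {
    stop_poolgp("`K` is not positive semidefinite within tolerance.", "poolgp_not_psd")
  }
  eK$values <- pmax(eK$values, 0)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrX <- qr(X)
  q <- qrX$rank
  if (q >= n) {
    stop_poolgp("More fixed effects than observations.", "poolgp_invalid_argument")
  }

  # Eigenvalues of K restricted to the orthogonal complement of X.
  Qc <- qr.Q(qrX, complete = TRUE)[, (q + 1):n, drop = FALSE]
  KP <- crossprod(Qc, K %*% Qc)
  eP <- eigen((KP + t(KP)) / 2, symmetric = TRUE)
  xi <- pmax(eP$values, 0)
  eta <- drop(crossprod(eP$vectors, crossprod(Qc, y)))
  eta2 <- eta^2

  if (sum(eta2) < 1e-300) {
    # Response in the column space of X: no residual variation to fit.
    delta <- 1e5
    sigma_g2 <- 0
    sigma_e2 <- 0
    ll <- Inf
  } else {
    log_grid <- seq(-5, 5, length.out = 100)
    ll_grid <- vapply(log_grid, function(ld) reml_profile(xi, eta2, 10^ld), numeric(1))
    best <- which.max(ll_grid)
    lo <- log_grid[max(1, best - 1)]
    hi <- log_grid[min(length(log_grid), best + 1)]
    opt <- optimize(function(ld) reml_profile(xi, eta2, 10^ld),
      interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    delta <- 10^opt$maximum
    ll <- opt$objective
    m <- length(xi)
    sigma_g2 <- sum(eta2 / (xi + delta)) / m
    sigma_e2 <- delta * sigma_g2
  }

  # GLS fixed effects at the REML variance components.
  d <- sigma_g2 * eK$values + sigma_e2
  d[d < 1e-12] <- 1e-12
  Uy <- crossprod(eK$vectors, y)
  UX <- crossprod(eK$vectors, X)
  w <- 1 / sqrt(d)
  fitb <- stats::lm.fit(UX * w, Uy * w)
  beta <- coef(fitb)

  structure(list(
    sigma_g2 = sigma_g2,
    sigma_e2 = sigma_e2,
    delta = delta,
    loglik = ll,
    beta = beta,
    X = X,
    y = y,
    n = n,
    q = q,
    eigen_K = eK,
    xi = xi,
    eta2 = eta2
  ), class = "null_mm")
}

#' @export
print.null_mm <- function(x, ...) {
  cat(sprintf(
    "<null_mm> n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, delta = %.4g\n",
    x$n, x$sigma_g2, x$sigma_e2, x$delta
  ))
  invisible(x)
}

#' @describeIn fit_null_mm One-row variance-component summary.
#' @param x,object A `null_mm` fit.
#' @param ... Ignored.
#' @method glance null_mm
#' @export
glance.null_mm <- function(x, ...) {
  tibble(
    n = x$n,
    sigma_g2 = x$sigma_g2,
    sigma_e2 = x$sigma_e2,
    delta = x$delta,
    loglik = x$loglik
  )
}

# Whitening transform from a null fit: returns function(v) -> H^{-1/2} v
# applied columnwise, using the cached eigendecomposition of K.
null_whitener <- function(null) {
  d <- null$sigma_g2 * null$eigen_K$values + null$sigma_e2
  d[d < 1e-12] <- 1e-12
  U <- null$eigen_K$vectors
  w <- 1 / sqrt(d)
  function(v) {
    if (is.null(dim(v))) {
      drop(crossprod(U, v)) * w
    } else {
      crossprod(U, v) * w
    }
  }
}
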
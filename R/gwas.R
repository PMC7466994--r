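#' Population-level association scan
#'
#' Tests each marker's allele frequency against population trait means under
#' one of four model specifications: `"naive"` (simple regression),
#' `"structure"` (cluster-membership covariates), `"kinship"` (mixed model
#' with the genomic relationship matrix as random-effect covariance) and
#' `"structure+kinship"`. Kinship models use the P3D shortcut by default:
#' variance components are estimated once under the null ([fit_null_mm()])
#' and each marker is then tested by GLS with those components fixed —
#' equivalently, OLS on data whitened by `H^{-1/2}` with
#' `H = sigma_g2 G + sigma_e2 I`. Two-sided t tests on `n - rank(X)`
#' residual degrees of freedom; Benjamini-Hochberg q-values; per-marker
#' variance explained with ([variance_explained()]) and without kinship.
#'
#' @param y Population trait means (named or in row order of `freqs`).
#' @param freqs A [freq_matrix] (no missing values) or numeric matrix.
#' @param model One of `"naive"`, `"structure"`, `"kinship"`,
#'   `"structure+kinship"`.
#' @param G [kinship_matrix] (required for kinship models).
#' @param clusters Factor/character of cluster labels (required for
#'   structure models); turned into one-hot covariates, reference dropped.
#' @param p3d If `FALSE`, refit the variance components by exact REML for
#'   every marker instead of fixing them at the null estimates (slow;
#'   validation use).
#' @return A `gwas_result`: per-marker tibble (`marker_id`, `scaffold`,
#'   `pos_bp`, `beta`, `se`, `p_value`, `q_value`, `r2_ols`, `r2_kinship`,
#'   `zero_variance`) with the null variance components as attributes.
#' @export
run_gwas <- function(y, freqs, model = c("kinship", "naive", "structure", "structure+kinship"),
                     G = NULL, clusters = NULL, p3d = TRUE) {
  model <- match.arg(model)
  X <- freq_values(freqs)
  if (anyNA(X)) {
    stop_poolgp("Frequencies contain missing values; impute first.",
      "poolgp_missing_values")
  }
  y <- align_y(y, rownames(X))
  n <- nrow(X)
  use_kinship <- model %in% c("kinship", "structure+kinship")
  use_structure <- model %in% c("structure", "structure+kinship")
  if (use_kinship && is.null(G)) {
    stop_poolgp("Kinship models require `G`.", "poolgp_invalid_argument")
  }
  if (use_structure && is.null(clusters)) {
    stop_poolgp("Structure models require `clusters`.", "poolgp_invalid_argument")
  }
  covariates <- if (use_structure) cluster_dummies(clusters, n) else NULL
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)

  null <- NULL
  if (use_kinship) {
    null <- fit_null_mm(y, G, covariates)
    wh <- null_whitener(null)
    yt <- wh(y)
    X0t <- wh(X0)
    Xt <- wh(X)
  } else {
    yt <- y
    X0t <- X0
    Xt <- X
  }

  if (use_kinship && !p3d) {
    res <- exact_scan(y, X, X0, covariates, G)
  } else {
    res <- whitened_scan(yt, Xt, X0t)
  }

  # Variance explained: OLS R2 on the raw scale; partial R2 on the whitened
  # scale when a kinship null is available (otherwise identical to OLS).
  r2o <- marker_r2_ols(y, X)
  r2k <- if (use_kinship) {
    marker_partial_r2(yt, Xt, X0t)
  } else {
    marker_partial_r2(y, X, matrix(1, n, 1))
  }

  tab <- tibble(
    marker_id = colnames(X),
    beta = unname(res$beta),
    se = unname(res$se),
    p_value = unname(res$p),
    q_value = unname(qvalues(res$p)),
    r2_ols = unname(r2o),
    r2_kinship = unname(r2k),
    zero_variance = unname(res$zero)
  )
  if (inherits(freqs, "freq_matrix")) {
    tab <- dplyr::left_join(tab, freqs$map, by = "marker_id") |>
      dplyr::relocate("scaffold", "pos_bp", .after = "marker_id")
  }
  structure(tab,
    model = model,
    n = n,
    sigma_g2 = if (use_kinship) null$sigma_g2 else NA_real_,
    sigma_e2 = if (use_kinship) null$sigma_e2 else NA_real_,
    delta = if (use_kinship) null$delta else NA_real_,
    null_fit = null,
    class = c("gwas_result", class(tab))
  )
}

cluster_dummies <- function(clusters, n) {
  f <- factor(clusters)
  if (length(f) != n) {
    stop_poolgp("`clusters` length must match the number of populations.",
      "poolgp_id_mismatch")
  }
  if (nlevels(f) < 2L) {
    return(NULL)
  }
  mm <- model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0("cluster_", levels(f)[-1])
  mm
}

# OLS scan of y on [X0, x_j] for every column x_j, via residualisation
# against X0. Works on whitened inputs for the GLS case.
whitened_scan <- function(y, X, X0) {
  n <- length(y)
  qr0 <- qr(X0)
  q <- qr0$rank
  ry <- qr.resid(qr0, y)
  RX <- qr.resid(qr0, X)
  sxx <- colSums(RX^2)
  sxy <- colSums(RX * ry)
  syy <- sum(ry^2)
  zero <- sxx < 1e-12 * max(sxx, 1)
  beta <- ifelse(zero, 0, sxy / sxx)
  df <- n - q - 1L
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(zero, NA_real_, sqrt(rss / df / sxx))
  tstat <- ifelse(zero, 0, beta / se)
  p <- ifelse(zero, 1, 2 * pt(-abs(tstat), df))
  list(beta = beta, se = se, p = p, zero = zero)
}

# Exact per-marker REML: refit variance components with the marker as an
# extra fixed effect, then GLS t-test at those components.
exact_scan <- function(y, X, X0, covariates, G) {
  Gm <- if (inherits(G, "kinship_matrix")) G$G else G
  n <- length(y)
  p <- ncol(X)
  beta <- se <- pval <- numeric(p)
  zero <- logical(p)
  for (j in seq_len(p)) {
    xj <- X[, j]
    if (sd(xj) < 1e-12) {
      zero[j] <- TRUE
      beta[j] <- 0
      pval[j] <- 1
      se[j] <- NA_real_
      next
    }
    nullj <- fit_null_mm(y, Gm, cbind(covariates, marker = xj))
    wh <- null_whitener(nullj)
    sc <- whitened_scan(wh(y), wh(matrix(xj, ncol = 1)), wh(X0))
    beta[j] <- sc$beta
    se[j] <- sc$se
    pval[j] <- sc$p
  }
  list(beta = beta, se = se, p = pval, zero = zero)
}

marker_r2_ols <- function(y, X) {
  sds <- apply(X, 2, sd)
  out <- rep(0, ncol(X))
  ok <- sds > 0 & sd(y) > 0
  if (any(ok)) {
    out[ok] <- drop(cor(y, X[, ok, drop = FALSE]))^2
  }
  out
}

marker_partial_r2 <- function(yt, Xt, X0t) {
  qr0 <- qr(X0t)
  ry <- qr.resid(qr0, yt)
  RX <- qr.resid(qr0, Xt)
  sxx <- colSums(RX^2)
  syy <- sum(ry^2)
  sxy <- colSums(RX * ry)
  out <- rep(0, ncol(Xt))
  ok <- sxx > 1e-12 * max(sxx, 1) & syy > 0
  out[ok] <- (sxy[ok]^2 / sxx[ok]) / syy
  pmin(pmax(out, 0), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values with the usual monotonicity enforcement,
#' as implemented by `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_poolgp("p-values must lie in [0, 1].", "poolgp_invalid_argument")
  }
  p.adjust(p, method = "BH")
}

#' Significant markers at an FDR threshold
#'
#' Markers with `q_value` strictly below `q_max` (default 10%), ordered by
#' ascending p-value.
#'
#' @param result A `gwas_result`.
#' @param q_max FDR threshold (default 0.10).
#' @return Character vector of marker ids (possibly empty).
#' @export
significant <- function(result, q_max = 0.10) {
  stopifnot(inherits(result, "gwas_result"))
  q_max <- assert_fraction(q_max, "q_max", lo_open = TRUE)
  hits <- result[result$q_value < q_max, c("marker_id", "p_value")]
  hits$marker_id[order(hits$p_value)]
}

#' Variance explained by one marker, with and without kinship
#'
#' `r2_ols` is the squared Pearson correlation between the trait and the
#' marker frequency. `r2_kinship` is the partial R-squared of the marker on
#' data whitened by the null-model `H^{-1/2}` — the share of the
#' structure-adjusted trait variation the marker accounts for. As the
#' kinship signal vanishes (`delta -> Inf`) the two coincide.
#'
#' @param y Population trait means.
#' @param x Marker frequency vector.
#' @param null Optional `null_mm` fit from [fit_null_mm()]; without it only
#'   the OLS version is meaningful and both entries coincide.
#' @return One-row tibble: `r2_ols`, `r2_kinship`.
#' @export
variance_explained <- function(y, x, null = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (sd(x) == 0) {
    return(tibble(r2_ols = 0, r2_kinship = 0))
  }
  r2o <- cor(y, x)^2
  if (is.null(null)) {
    return(tibble(r2_ols = r2o, r2_kinship = r2o))
  }
  wh <- null_whitener(null)
  X0t <- wh(null$X)
  r2k <- marker_partial_r2(wh(y), wh(matrix(x, ncol = 1)), X0t)
  tibble(r2_ols = r2o, r2_kinship = r2k)
}

#' Markers unlinked at a correlation threshold
#'
#' A marker is "unlinked at t" when the largest absolute Pearson correlation
#' between its frequency column and every other listed marker's column is
#' strictly below `t` — the pooled-data analogue of pruning a significant
#' SNP list for redundancy.
#'
#' @param markers Character vector of marker ids to examine.
#' @param freqs A [freq_matrix] or numeric matrix containing them.
#' @param r_threshold Correlation threshold in `(0, 1]`.
#' @return A list: `n_unlinked` and `marker_ids` (the unlinked subset, in
#'   input order).
#' @export
prune_by_correlation <- function(markers, freqs, r_threshold) {
  X <- freq_values(freqs)
  missing_m <- setdiff(markers, colnames(X))
  if (length(missing_m)) {
    stop_poolgp(paste0("Unknown markers: ", paste(head(missing_m, 5), collapse = ", ")),
      "poolgp_id_mismatch")
  }
  r_threshold <- assert_fraction(r_threshold, "r_threshold", lo_open = TRUE)
  if (length(markers) == 1L) {
    return(list(n_unlinked = 1L, marker_ids = markers))
  }
  C <- abs(cor(X[, markers, drop = FALSE]))
  diag(C) <- 0
  unlinked <- markers[apply(C, 1, max) < r_threshold]
  list(n_unlinked = length(unlinked), marker_ids = unlinked)
}

#' Forward stepwise multi-marker regression
#'
#' Builds a multiple regression of the trait on significant markers, added
#' in ascending p-value order; a marker stays in the model only if it lowers
#' the AIC. Candidates beyond `n - 2` (by rank) are dropped to keep the
#' model estimable. The final model's coefficients and total R-squared
#' quantify the phenotypic variance jointly explained by the detected,
#' non-redundant markers.
#'
#' @param y Population trait means.
#' @param markers Candidate marker ids, most significant first (e.g. from
#'   [significant()]).
#' @param freqs A [freq_matrix] or numeric matrix.
#' @return A `stepwise_model`: `selected` (ordered ids), `coefficients`,
#'   `r_squared`, `aic`, `n_candidates`.
#' @export
stepwise_model <- function(y, markers, freqs) {
  X <- freq_values(freqs)
  y <- align_y(y, rownames(X))
  if (length(markers) < 1L) {
    stop_poolgp("Need at least one candidate marker.", "poolgp_invalid_argument")
  }
  n <- length(y)
  if (length(markers) > n - 2L) {
    markers <- markers[seq_len(n - 2L)]
  }
  selected <- character(0)
  current <- lm(y ~ 1)
  current_aic <- AIC(current)
  dat <- data.frame(y = y)
  for (m in markers) {
    dat[[make.names(m)]] <- X[, m]
    trial_terms <- make.names(c(selected, m))
    trial <- lm(stats::reformulate(trial_terms, "y"), data = dat)
    trial_aic <- AIC(trial)
    if (trial_aic < current_aic - 1e-9) {
      selected <- c(selected, m)
      current <- trial
      current_aic <- trial_aic
    }
  }
  r2 <- if (length(selected)) summary(current)$r.squared else 0
  structure(list(
    selected = selected,
    coefficients = coef(current),
    r_squared = r2,
    aic = current_aic,
    n_candidates = length(markers)
  ), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf(
    "<stepwise_model> %d of %d candidates kept; R2 = %.3f\n",
    length(x$selected), x$n_candidates, x$r_squared
  ))
  invisible(x)
}

#' @describeIn stepwise_model Coefficient table of the final model.
#' @param x A `stepwise_model`.
#' @param ... Ignored.
#' @method tidy stepwise_model
#' @export
tidy.stepwise_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn stepwise_model One-row summary (`n_selected`, `r_squared`, `aic`).
#' @method glance stepwise_model
#' @export
glance.stepwise_model <- function(x, ...) {
  tibble(n_selected = length(x$selected), r_squared = x$r_squared, aic = x$aic)
}

#' @describeIn run_gwas Manhattan plot (-log10 p by position, faceted by
#'   scaffold would be unreadable at scale, so scaffolds are concatenated);
#'   markers significant at `q < 0.10` are highlighted.
#' @param object A `gwas_result`.
#' @param q_max Highlight threshold.
#' @param ... Ignored.
#' @method autoplot gwas_result
#' @export
autoplot.gwas_result <- function(object, q_max = 0.10, ...) {
  df <- as_tibble(object)
  if (!"scaffold" %in% names(df)) {
    df$scaffold <- "all"
    df$pos_bp <- seq_len(nrow(df))
  }
  df <- df |>
    dplyr::arrange(.data$scaffold, .data$pos_bp) |>
    dplyr::mutate(
      index = dplyr::row_number(),
      sig = .data$q_value < q_max,
      parity = (as.integer(factor(.data$scaffold)) %% 2) == 0
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$parity), size = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$sig),
      colour = "red", size = 1.2
    ) +
    ggplot2::scale_colour_manual(values = c("grey40", "grey70")) +
    ggplot2::labs(x = "marker index (scaffold order)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @describeIn run_gwas One-row scan summary: model, n, variance components,
#'   number of significant markers at 10% FDR.
#' @param x A `gwas_result`.
#' @method glance gwas_result
#' @export
glance.gwas_result <- function(x, ...) {
  tibble(
    model = attr(x, "model"),
    n = attr(x, "n"),
    p_markers = nrow(x),
    sigma_g2 = attr(x, "sigma_g2"),
    sigma_e2 = attr(x, "sigma_e2"),
    delta = attr(x, "delta"),
    n_significant = sum(x$q_value < 0.10)
  )
}
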
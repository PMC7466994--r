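#' Calibration-set container
#'
#' @param pop_ids Selected population ids (size k, unique).
#' @param method Method tag: `"genetic"`, `"spatial"`, `"clustgeo"`,
#'   `"cdmean"` or `"random"`.
#' @param params Named list of method parameters (linkage, alpha, lambda,
#'   iterations, seed, ...).
#' @return A `calibration_set`.
#' @export
calibration_set <- function(pop_ids, method, params = list()) {
  if (anyDuplicated(pop_ids)) {
    stop_poolgp("Calibration set has duplicated populations.", "poolgp_invalid_argument")
  }
  structure(list(pop_ids = pop_ids, method = method, params = params),
    class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d populations, method '%s'\n",
    length(x$pop_ids), x$method))
  invisible(x)
}

#' Stratified calibration-set selection by hierarchical clustering
#'
#' Clusters populations into `k` groups by Ward agglomeration on a distance
#' matrix (genetic or spatial), then selects from each group the population
#' with the lowest average distance to the other members of its group
#' (ties broken by lexicographic population id; singleton groups contribute
#' their only member).
#'
#' @param D A [dist_matrix] (genetic Euclidean or spatial meters).
#' @param k Calibration-set size, `1 <= k <= n`.
#' @param linkage `hclust` linkage (default `"ward.D2"`).
#' @return A [calibration_set] with a method tag inferred from the distance
#'   units (`"genetic"` for Euclidean-genetic, `"spatial"` for meters).
#' @export
select_by_clustering <- function(D, k, linkage = "ward.D2") {
  M <- unclass(D)
  n <- nrow(M)
  k <- assert_count(k, "k", min = 1L)
  if (k > n) {
    stop_poolgp("`k` cannot exceed the number of populations.",
      "poolgp_invalid_argument")
  }
  groups <- if (k == n) {
    setNames(seq_len(n), rownames(M))
  } else {
    cutree(hclust(as.dist(M), method = linkage), k = k)
  }
  chosen <- group_representatives(M, groups)
  method <- switch(attr(D, "units") %||% "custom",
    "meters" = "spatial",
    "euclidean-genetic" = "genetic",
    "custom"
  )
  calibration_set(chosen, method, list(linkage = linkage, k = k))
}

group_representatives <- function(M, groups) {
  ids <- rownames(M)
  vapply(sort(unique(groups)), function(g) {
    members <- ids[groups == g]
    if (length(members) == 1L) {
      return(members)
    }
    sub <- M[members, members, drop = FALSE]
    avg <- rowSums(sub) / (length(members) - 1)
    members[order(avg, members)][1]
  }, character(1))
}

#' Spatially constrained genetic clustering selection
#'
#' Ward-type agglomeration on the blend of a genetic and a spatial
#' dissimilarity: each matrix is normalized by its maximum and the merge
#' criterion weights their pseudo-inertias by `1 - alpha` and `alpha`.
#' Because Ward's criterion is additive in squared dissimilarities, this is
#' Ward clustering of `d = sqrt((1 - alpha) d_gen*^2 + alpha d_geo*^2)`.
#' Representatives are picked as in [select_by_clustering()], using the
#' blended dissimilarity. `alpha = 0` reduces exactly to genetic clustering,
#' `alpha = 1` to spatial clustering.
#'
#' @param D_gen,D_geo [dist_matrix] objects with matching ids.
#' @param k Calibration-set size.
#' @param alpha Mixing parameter in `[0, 1]` (default 0.5).
#' @return A [calibration_set] tagged `"clustgeo"`.
#' @export
select_clustgeo <- function(D_gen, D_geo, k, alpha = 0.5) {
  Mg <- unclass(D_gen)
  Ms <- unclass(D_geo)
  if (!identical(rownames(Mg), rownames(Ms))) {
    stop_poolgp("Genetic and spatial distance ids do not match.", "poolgp_id_mismatch")
  }
  alpha <- assert_fraction(alpha, "alpha")
  k <- assert_count(k, "k", min = 1L)
  n <- nrow(Mg)
  if (k > n) {
    stop_poolgp("`k` cannot exceed the number of populations.",
      "poolgp_invalid_argument")
  }
  Mg_n <- Mg / max(Mg)
  Ms_n <- Ms / max(Ms)
  M <- sqrt((1 - alpha) * Mg_n^2 + alpha * Ms_n^2)
  groups <- if (k == n) {
    setNames(seq_len(n), rownames(M))
  } else {
    cutree(hclust(as.dist(M), method = "ward.D2"), k = k)
  }
  chosen <- group_representatives(M, groups)
  calibration_set(chosen, "clustgeo", list(alpha = alpha, k = k))
}

# CDmean of a candidate calibration set: mean over non-selected populations
# of the coefficient of determination of their genotypic BLUP.
cdmean_value <- function(G, Ginv, sel_idx, lambda) {
  n <- nrow(G)
  k <- length(sel_idx)
  # Z'MZ for Z the k x n incidence of calibration records and
  # M = I_k - 11'/k: diagonal 1 on selected minus 1/k on selected pairs.
  ZMZ <- matrix(0, n, n)
  ZMZ[sel_idx, sel_idx] <- -1 / k
  diag(ZMZ)[sel_idx] <- diag(ZMZ)[sel_idx] + 1
  A <- ZMZ + lambda * Ginv
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    stop_poolgp("CDmean system is singular even after ridge stabilization.",
      "poolgp_degenerate")
  }
  cd <- (diag(G) - lambda * diag(Ainv)) / diag(G)
  mean(cd[-sel_idx])
}

#' CDmean exchange optimization of the calibration set
#'
#' Maximises the mean coefficient of determination (CD) of the genotypic
#' BLUPs of the non-phenotyped populations:
#' `CD_i = [G - lambda (Z'MZ + lambda G^-)^{-1}]_ii / G_ii`, averaged over
#' populations outside the calibration set, where `Z` is the selection
#' incidence, `M` projects out the intercept on calibration records,
#' `lambda = sigma_e^2 / sigma_g^2`, and `G^-` is a ridge-stabilized inverse
#' (`ridge = 1e-6 * mean(diag(G))`, needed because a pooled-frequency G is
#' often rank-deficient). Starting from a random `k`-subset, each iteration
#' proposes swapping one selected with one non-selected population and
#' accepts the swap only if CDmean improves.
#'
#' @param G A [kinship_matrix].
#' @param k Calibration-set size (`k < n`).
#' @param lambda Variance ratio `sigma_e^2 / sigma_g^2`; `1` corresponds to
#'   an assumed heritability of 0.5.
#' @param n_iter Exchange iterations (default 1000).
#' @param seed Integer seed (initial subset and proposal stream).
#' @return A [calibration_set] tagged `"cdmean"`, with `cdmean` (final
#'   criterion) and `trajectory` (accepted CDmean values, strictly
#'   increasing) in `params`.
#' @export
select_cdmean <- function(G, k, lambda = 1, n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(G, "kinship_matrix"))
  Gm <- G$G
  n <- nrow(Gm)
  k <- assert_count(k, "k", min = 2L)
  if (k >= n) {
    stop_poolgp("`k` must be smaller than the number of populations.",
      "poolgp_invalid_argument")
  }
  if (!is.numeric(lambda) || lambda <= 0) {
    stop_poolgp("`lambda` must be positive.", "poolgp_invalid_argument")
  }
  n_iter <- assert_count(n_iter, "n_iter", min = 1L)
  ridge <- 1e-6 * mean(diag(Gm))
  Ginv <- solve(Gm + ridge * diag(n))
  with_seed(seed, {
    sel <- sort(sample.int(n, k))
    current <- cdmean_value(Gm, Ginv, sel, lambda)
    trajectory <- current
    for (it in seq_len(n_iter)) {
      out_pool <- setdiff(seq_len(n), sel)
      swap_out <- sel[sample.int(k, 1)]
      swap_in <- out_pool[sample.int(length(out_pool), 1)]
      cand <- sort(c(setdiff(sel, swap_out), swap_in))
      val <- cdmean_value(Gm, Ginv, cand, lambda)
      if (val > current) {
        sel <- cand
        current <- val
        trajectory <- c(trajectory, val)
      }
    }
    calibration_set(rownames(Gm)[sel], "cdmean",
      list(lambda = lambda, n_iter = n_iter, seed = seed,
        cdmean = current, trajectory = trajectory, k = k))
  })
}

#' Random calibration set
#'
#' @param pop_ids All candidate population ids.
#' @param k Set size.
#' @param seed Integer seed.
#' @return A [calibration_set] tagged `"random"`.
#' @export
select_random <- function(pop_ids, k, seed = 1L) {
  k <- assert_count(k, "k", min = 1L)
  if (k > length(pop_ids)) {
    stop_poolgp("`k` cannot exceed the number of populations.",
      "poolgp_invalid_argument")
  }
  with_seed(seed, calibration_set(sample(pop_ids, k), "random", list(seed = seed, k = k)))
}

#' Performance score of an optimized calibration set
#'
#' `(OptPA - MinPA) / (MaxPA - MinPA)`, where MinPA and MaxPA are the
#' minimum and maximum predictive abilities over random same-size
#' calibration sets. A score of 0.5 means the optimized set sits exactly at
#' the midpoint of the random envelope; scores above 1 (optimized set beats
#' every random draw) and below 0 are possible and reported as-is.
#'
#' @param opt_pa Predictive ability of the optimized set.
#' @param min_pa,max_pa Envelope bounds (`max_pa > min_pa`).
#' @return The score (a bare number).
#' @examples
#' performance(0.4, 0.2, 0.6) # midpoint: 0.5
#' @export
performance <- function(opt_pa, min_pa, max_pa) {
  if (!is.numeric(opt_pa) || !is.numeric(min_pa) || !is.numeric(max_pa) ||
      anyNA(c(opt_pa, min_pa, max_pa))) {
    stop_poolgp("Predictive abilities must be numeric.", "poolgp_invalid_argument")
  }
  if (max_pa <= min_pa) {
    stop_poolgp("Score undefined: `max_pa` must exceed `min_pa`.",
      "poolgp_undefined_score")
  }
  (opt_pa - min_pa) / (max_pa - min_pa)
}

#' Evaluate a calibration set against its random envelope
#'
#' Trains RR-BLUP on the calibration set, predicts every non-selected
#' population and records the Pearson predictive ability (OptPA). The same
#' protocol is applied to `n_random` seeded random sets of the same size to
#' obtain the MinPA/MaxPA envelope, and the [performance()] score is
#' reported.
#'
#' @param freqs A [freq_matrix] (no missing values) or numeric matrix.
#' @param y Population means (named or row order).
#' @param set A [calibration_set] (size < n).
#' @param n_random Number of random same-size sets (default 100).
#' @param seed Integer seed for the random sets.
#' @return A one-row tibble (class `performance_score`): `method`, `k`,
#'   `opt_pa`, `min_pa`, `max_pa`, `score`, with the random predictive
#'   abilities in attribute `random_pa`.
#' @export
evaluate_calibration <- function(freqs, y, set, n_random = 100L, seed = 1L) {
  stopifnot(inherits(set, "calibration_set"))
  Z <- freq_values(freqs)
  y <- align_y(y, rownames(Z))
  names(y) <- rownames(Z)
  n_random <- assert_count(n_random, "n_random", min = 2L)
  all_pops <- rownames(Z)
  if (!all(set$pop_ids %in% all_pops)) {
    stop_poolgp("Calibration set contains unknown populations.", "poolgp_id_mismatch")
  }
  k <- length(set$pop_ids)
  if (k >= length(all_pops)) {
    stop_poolgp("Calibration set must leave at least one validation population.",
      "poolgp_invalid_argument")
  }
  pa_of <- function(train_ids) {
    val_ids <- setdiff(all_pops, train_ids)
    fit <- fit_rrblup(Z[train_ids, , drop = FALSE], y[train_ids])
    pred <- predict(fit, Z[val_ids, , drop = FALSE])
    if (sd(pred) == 0 || sd(y[val_ids]) == 0) {
      return(NA_real_)
    }
    cor(y[val_ids], pred)
  }
  opt_pa <- pa_of(set$pop_ids)
  seeds <- derive_seeds(seed, n_random)
  random_pa <- vapply(seeds, function(s) {
    pa_of(with_seed(s, sample(all_pops, k)))
  }, numeric(1))
  min_pa <- min(random_pa, na.rm = TRUE)
  max_pa <- max(random_pa, na.rm = TRUE)
  out <- tibble(
    method = set$method,
    k = k,
    opt_pa = opt_pa,
    min_pa = min_pa,
    max_pa = max_pa,
    score = if (is.na(opt_pa)) NA_real_ else performance(opt_pa, min_pa, max_pa)
  )
  structure(out, random_pa = random_pa,
    class = c("performance_score", class(out)))
}

#' Build the GWAS-informed marker set on calibration data
#'
#' Runs a kinship-only association scan on the calibration populations,
#' traverses markers by ascending p-value and adds each as a fixed effect to
#' a multiple regression of the trait only when the nested-model F-test
#' improves the fit at 5%; the set is capped at the calibration size to
#' avoid overfitting. Only calibration data are touched — no validation
#' leakage.
#'
#' @param freqs_cal Calibration-rows [freq_matrix] or matrix.
#' @param y_cal Calibration population means.
#' @param G_cal [kinship_matrix] of the calibration populations.
#' @param p_enter F-test entry threshold (default 0.05).
#' @param max_markers Cap on the set size (default: calibration size).
#' @return Ordered character vector of marker ids (possibly empty).
#' @export
build_gwas_set <- function(freqs_cal, y_cal, G_cal, p_enter = 0.05,
                           max_markers = NULL) {
  Z <- freq_values(freqs_cal)
  y <- align_y(y_cal, rownames(Z))
  n <- length(y)
  max_markers <- if (is.null(max_markers)) n else assert_count(max_markers, "max_markers", 1L)
  max_markers <- min(max_markers, n - 2L)
  scan <- run_gwas(y, freqs_cal, model = "kinship", G = G_cal)
  ord <- order(scan$p_value)
  candidates <- scan$marker_id[ord]

  selected <- character(0)
  dat <- data.frame(y = y)
  current <- lm(y ~ 1, data = dat)
  for (m in candidates) {
    if (length(selected) >= max_markers) break
    if (n - length(selected) - 3L < 1L) break
    dat[[make.names(m)]] <- Z[, m]
    trial <- lm(stats::reformulate(make.names(c(selected, m)), "y"), data = dat)
    cmp <- anova(current, trial)
    pv <- cmp$`Pr(>F)`[2]
    if (!is.na(pv) && pv < p_enter) {
      selected <- c(selected, m)
      current <- trial
    }
  }
  selected
}

#' Predictive-ability curve over growing marker sets
#'
#' Traces validation predictive ability as markers are added one by one to
#' an RR-BLUP model trained on the calibration set, under two regimes:
#' *GWAS-first* — the GWAS-set markers (in significance order) first, then
#' randomly drawn others up to `max_random`; and *random-first* — randomly
#' drawn markers from the start. For each regime the smallest marker count
#' whose predictive ability reaches 95% of that regime's maximum
#' (`min_markers_95`) is reported.
#'
#' @param freqs A [freq_matrix] (no missing values) or numeric matrix
#'   covering calibration and validation populations.
#' @param y Population means.
#' @param calibration,validation Disjoint character vectors of population ids.
#' @param gwas_set Ordered marker ids from [build_gwas_set()].
#' @param max_random Random markers appended after the seed set (default
#'   2000; capped at availability with a warning).
#' @param seed Integer seed for the random marker draws.
#' @return A `marker_curve`: tibble (`regime`, `n_markers`, `pa`) with
#'   attribute `min_markers_95` (tibble per regime) and `gwas_set`.
#' @export
marker_curve <- function(freqs, y, calibration, validation, gwas_set,
                         max_random = 2000L, seed = 1L) {
  Z <- freq_values(freqs)
  y <- align_y(y, rownames(Z))
  names(y) <- rownames(Z)
  if (length(intersect(calibration, validation)) > 0L) {
    stop_poolgp("Calibration and validation sets must be disjoint.",
      "poolgp_invalid_argument")
  }
  max_random <- assert_count(max_random, "max_random", min = 0L)
  Zc_all <- Z[calibration, , drop = FALSE]
  Zv_all <- Z[validation, , drop = FALSE]
  yc <- y[calibration]
  yv <- y[validation]

  pool <- setdiff(colnames(Z), gwas_set)
  n_rand_gwas <- min(max_random, length(pool))
  if (n_rand_gwas < max_random) {
    warning("`max_random` exceeds available markers; capped at ", n_rand_gwas)
  }
  seeds <- derive_seeds(seed, 2L)
  rand_after <- with_seed(seeds[1], sample(pool, n_rand_gwas))
  order_gwas <- c(gwas_set, rand_after)
  n_rand_only <- min(length(gwas_set) + max_random, ncol(Z))
  order_rand <- with_seed(seeds[2], sample(colnames(Z), n_rand_only))

  curve <- dplyr::bind_rows(
    regime_curve(Zc_all, yc, Zv_all, yv, order_gwas, "gwas_first"),
    regime_curve(Zc_all, yc, Zv_all, yv, order_rand, "random_first")
  )
  m95 <- curve |>
    dplyr::group_by(.data$regime) |>
    dplyr::summarise(
      max_pa = max(.data$pa, na.rm = TRUE),
      min_markers_95 = .data$n_markers[which(.data$pa >= 0.95 * max(.data$pa, na.rm = TRUE))[1]],
      .groups = "drop"
    )
  structure(curve,
    min_markers_95 = m95,
    gwas_set = gwas_set,
    class = c("marker_curve", class(curve))
  )
}

# PA at each prefix of `marker_order`, with incremental updates of the
# calibration relationship matrix and the validation cross-products. Uses a
# lean intercept-only REML path (one eigendecomposition per size).
regime_curve <- function(Zc, yc, Zv, yv, marker_order, regime) {
  n_cal <- nrow(Zc)
  n_sizes <- length(marker_order)
  K <- matrix(0, n_cal, n_cal)
  Cv <- matrix(0, nrow(Zv), n_cal)
  pa <- numeric(n_sizes)
  ones <- rep(1, n_cal)
  for (k in seq_len(n_sizes)) {
    m <- marker_order[k]
    centre <- mean(Zc[, m])
    zc <- Zc[, m] - centre
    zv <- Zv[, m] - centre
    K <- K + tcrossprod(zc)
    Cv <- Cv + tcrossprod(zv, zc)
    if (all(abs(K) < 1e-14)) {
      pa[k] <- NA_real_
      next
    }
    # Intercept-only spectral REML on the centred responses: the projection
    # orthogonal to the intercept is just double centring of K. The constant
    # eigendirection (eigenvalue 0, identified by its overlap with 1) is the
    # one direction excluded from the restricted likelihood.
    rm_k <- rowMeans(K)
    Kc <- K - outer(rm_k, rep(1, n_cal)) - outer(rep(1, n_cal), rm_k) + mean(K)
    eP <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
    ones_dir <- which.max(abs(colSums(eP$vectors)))
    xi <- pmax(eP$values[-ones_dir], 0)
    eta2 <- drop(crossprod(eP$vectors[, -ones_dir, drop = FALSE],
      yc - mean(yc)))^2
    if (sum(eta2) < 1e-300) {
      pa[k] <- NA_real_
      next
    }
    log_grid <- seq(-5, 5, length.out = 100)
    ll <- vapply(log_grid, function(ld) reml_profile(xi, eta2, 10^ld), numeric(1))
    best <- which.max(ll)
    opt <- optimize(function(ld) reml_profile(xi, eta2, 10^ld),
      interval = c(log_grid[max(1, best - 1)], log_grid[min(100, best + 1)]),
      maximum = TRUE, tol = 1e-6)
    delta <- 10^opt$maximum
    Hc <- chol(K + delta * diag(n_cal))
    Hi_y <- backsolve(Hc, forwardsolve(t(Hc), yc))
    Hi_1 <- backsolve(Hc, forwardsolve(t(Hc), ones))
    mu <- sum(Hi_y) / sum(Hi_1)
    alpha <- backsolve(Hc, forwardsolve(t(Hc), yc - mu))
    pred <- drop(mu + Cv %*% alpha)
    pa[k] <- if (sd(pred) == 0 || sd(yv) == 0) NA_real_ else cor(yv, pred)
  }
  tibble(regime = regime, n_markers = seq_len(n_sizes), pa = pa)
}

#' @describeIn marker_curve Predictive ability vs marker count for both
#'   regimes, with the 95%-of-max thresholds marked.
#' @param object A `marker_curve`.
#' @param ... Ignored.
#' @method autoplot marker_curve
#' @export
autoplot.marker_curve <- function(object, ...) {
  m95 <- attr(object, "min_markers_95")
  ggplot2::ggplot(as_tibble(object),
    ggplot2::aes(x = .data$n_markers, y = .data$pa, colour = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = m95,
      ggplot2::aes(xintercept = .data$min_markers_95, colour = .data$regime),
      linetype = 2, show.legend = FALSE
    ) +
    ggplot2::labs(x = "markers in model", y = "predictive ability") +
    ggplot2::theme_minimal()
}
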
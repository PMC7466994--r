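#' Great-circle distance matrix between population origins
#'
#' Haversine distances in meters between collection sites, on a sphere of
#' radius 6,371,008.8 m.
#'
#' @param panel Population panel (tibble with `pop_id`, `lon`, `lat`).
#' @return A [dist_matrix] in meters, ids in panel order.
#' @examples
#' panel <- generate_panel(4, seed = 1)
#' geo_distances(panel)
#' @export
geo_distances <- function(panel) {
  check_panel(panel)
  xy <- as.matrix(panel[, c("lon", "lat")])
  D <- geosphere::distm(xy, fun = geosphere::distHaversine)
  # distm's haversine uses r = 6378137; rescale to the mean Earth radius.
  D <- D * (6371008.8 / 6378137)
  dimnames(D) <- list(panel$pop_id, panel$pop_id)
  D[abs(D) < 1e-9] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dist_matrix(D, "meters")
}

#' Euclidean genetic or phenotypic distance matrix
#'
#' @param x A [freq_matrix] (genetic distance on imputed frequencies) or a
#'   numeric matrix / data frame of per-population trait values with
#'   population rownames (phenotypic distance).
#' @return A [dist_matrix] tagged `"euclidean-genetic"` or
#'   `"euclidean-phenotypic"`.
#' @export
euclidean_distances <- function(x) {
  if (inherits(x, "freq_matrix")) {
    values <- impute_missing(x)$values
    units <- "euclidean-genetic"
  } else {
    values <- as.matrix(x)
    if (is.null(rownames(values))) {
      stop_poolgp("Trait matrix must carry population rownames.",
        "poolgp_invalid_argument")
    }
    units <- "euclidean-phenotypic"
  }
  D <- as.matrix(stats::dist(values))
  dist_matrix(D, units)
}

#' Moran's I spatial autocorrelation with analytic significance
#'
#' Computes Moran's index
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' for per-population values under a spatial weight matrix, with its
#' expectation `E[I] = -1/(n-1)`, randomization standard deviation and
#' two-sided normal-approximation p-value. The computation is delegated to
#' `ape::Moran.I`. Nominally I ranges from -1 (perfect dispersion) to +1
#' (perfect autocorrelation); the raw statistic is reported unclamped.
#'
#' @param values Numeric vector of per-population values (non-constant).
#' @param weights Non-negative `n x n` weight matrix with zero diagonal.
#'   Defaults are built by [inverse_distance_weights()].
#'
#' The weights enter the formula as given (no row normalization), so the
#' statistic agrees with the textbook definition; the randomization variance
#' is the Cliff-Ord moment formula and needs `n >= 4` (below that `sd` and
#' `p_value` are `NA`).
#'
#' @return A one-row tibble: `observed`, `expected`, `sd`, `p_value`, `n`.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' morans_i(c(1, 5), w) # the n = 2 perfect-dispersion extreme: I = -1
#' @export
morans_i <- function(values, weights) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop_poolgp("`values` must be numeric, length >= 2, no NA.",
      "poolgp_invalid_argument")
  }
  n <- length(values)
  if (!is.matrix(weights) || any(dim(weights) != n) || any(weights < 0) ||
      any(abs(diag(weights)) > 0)) {
    stop_poolgp("`weights` must be a non-negative n x n matrix with zero diagonal.",
      "poolgp_invalid_argument")
  }
  if (sd(values) == 0) {
    stop_poolgp("Moran's I is undefined for constant values.",
      "poolgp_undefined_statistic")
  }
  z <- values - mean(values)
  s0 <- sum(weights)
  obs <- (n / s0) * drop(crossprod(z, weights %*% z)) / sum(z^2)
  expected <- -1 / (n - 1)
  if (n >= 4L) {
    s1 <- 0.5 * sum((weights + t(weights))^2)
    s2 <- sum((rowSums(weights) + colSums(weights))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
      b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - expected^2
    sd_i <- sqrt(max(var_i, 0))
    p <- 2 * pnorm(-abs((obs - expected) / sd_i))
  } else {
    sd_i <- NA_real_
    p <- NA_real_
  }
  tibble(observed = obs, expected = expected, sd = sd_i, p_value = p, n = n)
}

#' Inverse-distance spatial weights
#'
#' The customary weighting for Moran's I over irregularly spaced sites:
#' `w_ij = 1 / d_ij` with a zero diagonal.
#'
#' @param D A [dist_matrix] (or plain symmetric distance matrix).
#' @return Weight matrix of the same dimension.
#' @export
inverse_distance_weights <- function(D) {
  W <- 1 / unclass(D)
  W[!is.finite(W)] <- 0
  diag(W) <- 0
  W
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-tailed (greater) permutation p-value obtained by jointly permuting the
#' rows and columns of the second matrix:
#' `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)`.
#'
#' @param D1,D2 [dist_matrix] objects (or plain symmetric matrices) with
#'   matching ids.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble: `r`, `p_value`, `n_perm`, `n`.
#' @examples
#' panel <- generate_panel(8, seed = 3)
#' D <- geo_distances(panel)
#' mantel(D, D, n_perm = 99, seed = 1)$r # identical matrices: r = 1
#' @export
mantel <- function(D1, D2, n_perm = 500L, seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm", min = 1L)
  M1 <- unclass(D1)
  M2 <- unclass(D2)
  if (!all(dim(M1) == dim(M2))) {
    stop_poolgp("Distance matrices must have equal dimension.", "poolgp_id_mismatch")
  }
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2))) {
    stop_poolgp("Distance matrix ids do not match.", "poolgp_id_mismatch")
  }
  n <- nrow(M1)
  if (n < 4L) {
    stop_poolgp("Mantel test needs at least 4 ids.", "poolgp_invalid_argument")
  }
  lower <- lower.tri(M1)
  v1 <- M1[lower]
  r_obs <- cor(v1, M2[lower])
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      cor(v1, M2[idx, idx][lower])
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  tibble(r = r_obs, p_value = p, n_perm = n_perm, n = n)
}

#' Spatial-structure summary for a set of traits
#'
#' Per-trait Moran's I (inverse-distance weights over the panel's
#' great-circle distances) plus the three Mantel correlations the analysis
#' of a spatially collected panel turns on: phenotypic~geographic,
#' phenotypic~genetic and genetic~geographic distance.
#'
#' @param means Tibble of adjusted means: `pop_id`, `trait`, `mean`.
#' @param panel Population panel.
#' @param freqs A [freq_matrix] for the genetic distances.
#' @param n_perm Mantel permutations (default 500).
#' @param seed Integer seed.
#' @return A list of tibbles: `moran` (per trait) and `mantel` (per trait
#'   and comparison, plus one genetic~geographic row with `trait = NA`).
#' @export
spatial_summary <- function(means, panel, freqs, n_perm = 500L, seed = 1L) {
  check_panel(panel)
  stopifnot(all(c("pop_id", "trait", "mean") %in% names(means)))
  D_geo <- geo_distances(panel)
  W <- inverse_distance_weights(D_geo)
  D_gen <- euclidean_distances(freqs[panel$pop_id, ])
  seeds <- derive_seeds(seed, 2L * length(unique(means$trait)) + 1L)

  traits <- unique(means$trait)
  moran <- purrr::map_dfr(traits, function(tr) {
    x <- means$mean[means$trait == tr][match(panel$pop_id, means$pop_id[means$trait == tr])]
    dplyr::mutate(morans_i(x, W), trait = tr, .before = 1)
  })
  mantel_rows <- purrr::imap_dfr(traits, function(tr, k) {
    x <- means$mean[means$trait == tr][match(panel$pop_id, means$pop_id[means$trait == tr])]
    D_ph <- euclidean_distances(matrix(x, dimnames = list(panel$pop_id, tr)))
    dplyr::bind_rows(
      dplyr::mutate(mantel(D_ph, D_geo, n_perm, seeds[2 * k - 1]),
        trait = tr, comparison = "phenotypic~geographic", .before = 1),
      dplyr::mutate(mantel(D_ph, D_gen, n_perm, seeds[2 * k]),
        trait = tr, comparison = "phenotypic~genetic", .before = 1)
    )
  })
  gg <- dplyr::mutate(mantel(D_gen, D_geo, n_perm, seeds[length(seeds)]),
    trait = NA_character_, comparison = "genetic~geographic", .before = 1)
  list(moran = moran, mantel = dplyr::bind_rows(mantel_rows, gg))
}
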
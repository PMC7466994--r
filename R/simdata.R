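#' Generate a panel of population collection sites
#'
#' Draws collection coordinates for a set of natural populations uniformly at
#' random inside a longitude/latitude rectangle, the way a genebank
#' collection samples a species' range.
#'
#' @param n_pops Number of populations (>= 2).
#' @param bbox Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees; default is a Europe-like window.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A tibble with columns `pop_id`, `lon`, `lat`, `is_cultivar`
#'   (all `FALSE`; cultivar rows can be appended by the caller).
#' @examples
#' generate_panel(5, seed = 1)
#' @export
generate_panel <- function(n_pops, bbox = c(-10, 25, 36, 60), seed = 1L) {
  n_pops <- assert_count(n_pops, "n_pops", min = 2L)
  if (length(bbox) != 4L || !all(is.finite(bbox)) ||
      bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop_poolgp("`bbox` must be c(lon_min, lon_max, lat_min, lat_max) with positive extent.",
      "poolgp_invalid_argument")
  }
  if (bbox[1] < -180 || bbox[2] > 180 || bbox[3] < -90 || bbox[4] > 90) {
    stop_poolgp("`bbox` must lie within [-180, 180] x [-90, 90].",
      "poolgp_invalid_argument")
  }
  with_seed(seed, {
    tibble(
      pop_id = sprintf("pop_%03d", seq_len(n_pops)),
      lon = runif(n_pops, bbox[1], bbox[2]),
      lat = runif(n_pops, bbox[3], bbox[4]),
      is_cultivar = FALSE
    )
  })
}

check_panel <- function(panel) {
  needed <- c("pop_id", "lon", "lat")
  if (!is.data.frame(panel) || !all(needed %in% names(panel))) {
    stop_poolgp("`panel` must have columns pop_id, lon, lat.",
      "poolgp_invalid_argument")
  }
  if (nrow(panel) < 2L || anyDuplicated(panel$pop_id)) {
    stop_poolgp("`panel` needs >= 2 populations with unique ids.",
      "poolgp_invalid_argument")
  }
  if (!all(is.finite(panel$lon)) || !all(is.finite(panel$lat))) {
    stop_poolgp("Panel coordinates must be finite.", "poolgp_invalid_argument")
  }
  invisible(panel)
}

#' Simulate spatially structured population allele frequencies
#'
#' Generates an allele-frequency matrix with the three structural features of
#' pooled genotyping data from a wild collection: (i) isolation by distance —
#' a Gaussian process on the logit scale whose covariance between two
#' populations decays exponentially with their great-circle distance; (ii) a
#' rare-allele-skewed frequency spectrum, from Beta-distributed ancestral
#' frequencies folded to the minor allele; and (iii) within-scaffold
#' correlation between nearby markers, from a latent field that evolves as an
#' exponentially decaying (AR(1)-in-position) process along each scaffold.
#' Marker positions are drawn in pairs around shared sites so that both
#' sub-100-bp and multi-kb marker pairs occur, as in reduced-representation
#' sequencing.
#'
#' @param panel Population panel (tibble with `pop_id`, `lon`, `lat`).
#' @param n_scaffolds,markers_per_scaffold Marker map dimensions.
#' @param ibd_range_km Range (km) of the exponential spatial covariance;
#'   `0` disables spatial structure. The default reproduces a
#'   genetic-vs-geographic Mantel correlation near 0.44 at collection scale.
#' @param within_scaffold_corr Decay length (bp) of the within-scaffold
#'   frequency correlation; `0` makes markers independent.
#' @param maf_shape Shape of the `Beta(maf_shape, 1)` ancestral-frequency
#'   distribution; values below 1 skew the spectrum toward rare alleles.
#' @param seed Integer seed.
#' @param scaffold_bp Scaffold length (bp) positions are drawn from.
#' @param sigma_logit Marginal standard deviation of the logit-scale field.
#' @param nugget Fraction of logit-scale variance that is population-specific
#'   noise rather than spatially structured signal.
#' @return A [freq_matrix] with attribute `ibd_range_km`.
#' @examples
#' panel <- generate_panel(20, seed = 1)
#' fq <- simulate_frequencies(panel, n_scaffolds = 4, markers_per_scaffold = 10, seed = 1)
#' fq
#' @export
simulate_frequencies <- function(panel, n_scaffolds = 40, markers_per_scaffold = 50,
                                 ibd_range_km = 250, within_scaffold_corr = 10000,
                                 maf_shape = 0.35, seed = 1L,
                                 scaffold_bp = 100000L, sigma_logit = 1.1,
                                 nugget = 0.15) {
  check_panel(panel)
  n_scaffolds <- assert_count(n_scaffolds, "n_scaffolds", min = 1L)
  markers_per_scaffold <- assert_count(markers_per_scaffold, "markers_per_scaffold", min = 1L)
  if (!is.numeric(ibd_range_km) || ibd_range_km < 0) {
    stop_poolgp("`ibd_range_km` must be >= 0.", "poolgp_invalid_argument")
  }
  if (!is.numeric(within_scaffold_corr) || within_scaffold_corr < 0) {
    stop_poolgp("`within_scaffold_corr` must be >= 0.", "poolgp_invalid_argument")
  }
  nugget <- assert_fraction(nugget, "nugget")

  n <- nrow(panel)
  p <- n_scaffolds * markers_per_scaffold

  # Population covariance of the latent field: exponential distance decay
  # plus a nugget, scaled to unit marginal variance.
  if (ibd_range_km > 0) {
    d_km <- geo_distances(panel) / 1000
    C <- (1 - nugget) * exp(-unclass(d_km) / ibd_range_km) + nugget * diag(n)
  } else {
    C <- diag(n)
  }
  R <- chol(C + 1e-8 * diag(n)) # upper triangular, C ~= t(R) %*% R

  with_seed(seed, {
    map <- purrr::map_dfr(seq_len(n_scaffolds), function(s) {
      m <- markers_per_scaffold
      n_sites <- ceiling(m / 2)
      sites <- sort(sample.int(scaffold_bp, n_sites))
      pos <- sites[ceiling(seq_len(m) / 2)]
      twin <- seq_len(m) %% 2 == 0
      pos[twin] <- pos[twin] + sample(1:80, sum(twin), replace = TRUE)
      tibble(
        scaffold = sprintf("scaffold_%04d", s),
        pos_bp = sort(as.integer(pos))
      )
    })
    map$marker_id <- sprintf("snp_%05d", seq_len(p))

    # Ancestral frequencies: rare-allele-skewed, folded to the minor allele,
    # with the labelled (alternative) allele flipped at random.
    q0 <- rbeta(p, maf_shape, 1)
    p0 <- pmin(q0, 1 - q0)
    p0 <- pmin(pmax(p0, 0.01), 0.5)
    flip <- runif(p) < 0.5
    p0[flip] <- 1 - p0[flip]

    draw_field <- function() drop(crossprod(R, rnorm(n)))

    values <- matrix(NA_real_, n, p,
      dimnames = list(panel$pop_id, map$marker_id)
    )
    idx <- 0L
    for (s in seq_len(n_scaffolds)) {
      rows <- which(map$scaffold == sprintf("scaffold_%04d", s))
      pos <- map$pos_bp[rows]
      f <- draw_field()
      for (k in seq_along(rows)) {
        if (k > 1L) {
          rho <- if (within_scaffold_corr > 0) {
            exp(-(pos[k] - pos[k - 1]) / within_scaffold_corr)
          } else {
            0
          }
          f <- rho * f + sqrt(max(0, 1 - rho^2)) * draw_field()
        }
        idx <- idx + 1L
        values[, idx] <- plogis(qlogis(p0[idx]) + sigma_logit * f)
      }
    }
    out <- freq_matrix(values, map)
    attr(out, "ibd_range_km") <- ibd_range_km
    out
  })
}

#' Simulate QTL-driven phenotypes in a balanced multi-environment trial
#'
#' Samples `n_qtl` markers as additive QTL, builds a standardized population
#' genetic value `g_i = sum_q a_q x_iq`, and generates plot-level records
#' `value = mu + g_i + env_j + (g x env)_ij + block_jr + e_ijr` in a balanced
#' complete-block design. The interaction and residual variances are chosen
#' so that the multi-environment broad-sense heritability indicator
#' `H2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2/J + sigma_e^2/(J R))` equals
#' `h2_pop` in expectation, with `gxe_share` of the non-genetic part of that
#' denominator attributed to the interaction.
#'
#' @param freqs A [freq_matrix]; missing entries are mean-imputed for the
#'   genetic values.
#' @param n_qtl Number of QTL (0 gives a pure-noise trait).
#' @param effect_dist `"gaussian"` (polygenic) or `"exponential"`
#'   (few large effects) QTL effect distribution.
#' @param h2_pop Target heritability indicator in `[0, 1]`.
#' @param n_envs,n_blocks Environments and complete blocks per environment.
#' @param gxe_share Fraction of the non-genetic variance of population means
#'   due to genotype-by-environment interaction (ignored when `n_envs == 1`).
#' @param seed Integer seed.
#' @param trait Trait label used in the records.
#' @param mu Grand mean of the trait.
#' @return A list with `records` (tibble: `pop_id`, `env`, `block`, `trait`,
#'   `value`) and `truth` (a `sim_truth` list: `qtl_marker_ids`,
#'   `qtl_effects`, `g` — the named true genetic values — `h2_pop`,
#'   `sigma_g2`, `sigma_ge2`, `sigma_e2`, `ibd_range_km`).
#' @examples
#' panel <- generate_panel(12, seed = 2)
#' fq <- simulate_frequencies(panel, 4, 10, seed = 2)
#' sim <- simulate_phenotypes(fq, n_qtl = 3, h2_pop = 0.8, seed = 2)
#' head(sim$records)
#' @export
simulate_phenotypes <- function(freqs, n_qtl = 50, effect_dist = c("gaussian", "exponential"),
                                h2_pop = 0.7, n_envs = 3, n_blocks = 3,
                                gxe_share = 0.3, seed = 1L,
                                trait = "trait_1", mu = 10) {
  stopifnot(inherits(freqs, "freq_matrix"))
  effect_dist <- match.arg(effect_dist)
  n_qtl <- assert_count(n_qtl, "n_qtl", min = 0L)
  if (n_qtl > ncol(freqs$values)) {
    stop_poolgp("`n_qtl` exceeds the number of markers.", "poolgp_invalid_argument")
  }
  h2_pop <- assert_fraction(h2_pop, "h2_pop")
  n_envs <- assert_count(n_envs, "n_envs", min = 1L)
  n_blocks <- assert_count(n_blocks, "n_blocks", min = 2L)
  gxe_share <- assert_fraction(gxe_share, "gxe_share")

  X <- freqs$values
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- cm[miss[, 2]]
  }
  n <- nrow(X)
  J <- n_envs
  R <- n_blocks

  with_seed(seed, {
    if (n_qtl > 0L) {
      qtl_idx <- sort(sample.int(ncol(X), n_qtl))
      a <- switch(effect_dist,
        gaussian = rnorm(n_qtl),
        exponential = stats::rexp(n_qtl) * sample(c(-1, 1), n_qtl, replace = TRUE)
      )
      g_raw <- drop(X[, qtl_idx, drop = FALSE] %*% a)
      s <- sd(g_raw)
      if (s > 0) {
        g <- (g_raw - mean(g_raw)) / s
        a <- a / s
      } else {
        g <- rep(0, n)
      }
    } else {
      qtl_idx <- integer(0)
      a <- numeric(0)
      g <- rep(0, n)
    }
    sigma_g2 <- if (n_qtl > 0L && sd(g) > 0) 1 else 0

    # Non-genetic variance of a population mean sized so the H2 indicator
    # hits h2_pop; reference genetic variance 1 keeps the null trait noisy.
    T_den <- if (h2_pop > 0) (1 - h2_pop) / h2_pop else 1
    if (J > 1L) {
      sigma_ge2 <- gxe_share * T_den * J
      sigma_e2 <- (1 - gxe_share) * T_den * J * R
    } else {
      sigma_ge2 <- 0
      sigma_e2 <- T_den * R
    }

    envs <- sprintf("env_%d", seq_len(J))
    blocks <- sprintf("block_%d", seq_len(R))
    env_eff <- rnorm(J, sd = 1)
    blk_eff <- matrix(rnorm(J * R, sd = 0.5), J, R)
    ge_eff <- matrix(
      if (sigma_ge2 > 0) rnorm(n * J, sd = sqrt(sigma_ge2)) else 0, n, J
    )

    grid <- tidyr::expand_grid(
      pop_id = rownames(X), env = envs, block = blocks
    )
    i <- match(grid$pop_id, rownames(X))
    j <- match(grid$env, envs)
    r <- match(grid$block, blocks)
    grid$trait <- trait
    grid$value <- unname(mu + g[i] + env_eff[j] + ge_eff[cbind(i, j)] +
      blk_eff[cbind(j, r)] +
      rnorm(nrow(grid), sd = sqrt(sigma_e2)))

    truth <- structure(list(
      qtl_marker_ids = colnames(X)[qtl_idx],
      qtl_effects = a,
      g = setNames(g, rownames(X)),
      h2_pop = h2_pop,
      sigma_g2 = sigma_g2,
      sigma_ge2 = sigma_ge2,
      sigma_e2 = sigma_e2,
      ibd_range_km = attr(freqs, "ibd_range_km") %||% NA_real_
    ), class = "sim_truth")

    list(records = grid, truth = truth)
  })
}

#' Mask entries of a frequency matrix at random
#'
#' Introduces missing calls independently at a given rate, with per-marker
#' missingness capped at 33% so no marker loses more than a third of its
#' populations (matching the missing-data profile of pooled genotyping).
#'
#' @param freqs A [freq_matrix].
#' @param rate Target missing fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [freq_matrix] with `NA` at the masked cells.
#' @export
inject_missing <- function(freqs, rate, seed = 1L) {
  stopifnot(inherits(freqs, "freq_matrix"))
  rate <- assert_fraction(rate, "rate", hi = 1, hi_open = TRUE)
  if (rate == 0) {
    return(freqs)
  }
  values <- freqs$values
  n <- nrow(values)
  cap <- floor(0.33 * n)
  with_seed(seed, {
    mask <- matrix(runif(length(values)) < rate, n, ncol(values))
    over <- which(colSums(mask) > cap)
    for (j in over) {
      keep <- sample(which(mask[, j]), cap)
      mask[, j] <- FALSE
      mask[keep, j] <- TRUE
    }
    values[mask] <- NA_real_
    out <- freq_matrix(values, freqs$map)
    attr(out, "ibd_range_km") <- attr(freqs, "ibd_range_km")
    out
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d QTL, h2_pop = %.2f, sigma_ge2 = %.3g, sigma_e2 = %.3g\n",
    length(x$qtl_marker_ids), x$h2_pop, x$sigma_ge2, x$sigma_e2
  ))
  invisible(x)
}
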
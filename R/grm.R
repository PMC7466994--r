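#' Filter markers on minor allele frequency across populations
#'
#' Keeps a marker when its per-population minor allele frequency
#' `min(x, 1 - x)` strictly exceeds `maf_min` in at least `min_pops`
#' populations with a non-missing call. Missing calls simply do not count
#' toward the tally. Column order is preserved and the filter is idempotent.
#'
#' @param freqs A [freq_matrix].
#' @param maf_min MAF threshold (default 0.05).
#' @param min_pops Minimum number of qualifying populations (default 10).
#' @return The filtered [freq_matrix]; may have zero markers, in which case
#'   an empty-marker error is raised by the container (use the report from
#'   [filter_report()] to inspect what was dropped).
#' @export
filter_markers <- function(freqs, maf_min = 0.05, min_pops = 10L) {
  stopifnot(inherits(freqs, "freq_matrix"))
  maf_min <- assert_fraction(maf_min, "maf_min", hi = 0.5)
  min_pops <- assert_count(min_pops, "min_pops", min = 1L)
  keep <- marker_filter_mask(freqs, maf_min, min_pops)
  if (!any(keep)) {
    stop_poolgp("No markers pass the MAF filter.", "poolgp_empty_result")
  }
  out <- freqs[, keep]
  attr(out, "ibd_range_km") <- attr(freqs, "ibd_range_km")
  out
}

marker_filter_mask <- function(freqs, maf_min, min_pops) {
  X <- freqs$values
  maf <- pmin(X, 1 - X)
  colSums(!is.na(maf) & maf > maf_min) >= min_pops
}

#' Kept/dropped report for the MAF filter
#'
#' @inheritParams filter_markers
#' @return Tibble: `marker_id`, `n_qualifying` populations, `kept`.
#' @export
filter_report <- function(freqs, maf_min = 0.05, min_pops = 10L) {
  X <- freqs$values
  maf <- pmin(X, 1 - X)
  n_ok <- colSums(!is.na(maf) & maf > maf_min)
  tibble(
    marker_id = colnames(X),
    n_qualifying = as.integer(unname(n_ok)),
    kept = unname(n_ok >= min_pops)
  )
}

#' Mean-impute missing allele frequencies
#'
#' Each missing call is replaced by the mean frequency of the marker across
#' the populations with data, which leaves every column mean unchanged.
#'
#' @param freqs A [freq_matrix].
#' @return A [freq_matrix] with no missing values.
#' @export
impute_missing <- function(freqs) {
  stopifnot(inherits(freqs, "freq_matrix"))
  X <- freqs$values
  if (!anyNA(X)) {
    return(freqs)
  }
  n_ok <- colSums(!is.na(X))
  if (any(n_ok == 0L)) {
    stop_poolgp(
      sprintf("Marker '%s' has no non-missing value; cannot impute.",
        colnames(X)[which(n_ok == 0L)[1]]),
      "poolgp_all_missing"
    )
  }
  cm <- colMeans(X, na.rm = TRUE)
  miss <- which(is.na(X), arr.ind = TRUE)
  X[miss] <- cm[miss[, 2]]
  out <- freq_matrix(X, freqs$map)
  attr(out, "ibd_range_km") <- attr(freqs, "ibd_range_km")
  out
}

#' Pooled genomic relationship matrix G = MM'/K
#'
#' Computes the population-level genomic relationship matrix from allele
#' frequencies: `M` is the frequency matrix with each column centered by its
#' mean, and `K = 0.5 * sum_j xbar_j (1 - xbar_j)` is the
#' sum-of-genetic-variance scaling constant, so `G = M M' / K`.
#'
#' @param freqs A [freq_matrix] with no missing values (impute first).
#' @return A [kinship_matrix].
#' @examples
#' m <- matrix(c(0.2, 0.6), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' kinship(freq_matrix(m))$G # [[1/3, -1/3], [-1/3, 1/3]]
#' @export
kinship <- function(freqs) {
  stopifnot(inherits(freqs, "freq_matrix"))
  X <- freqs$values
  if (anyNA(X)) {
    stop_poolgp("Frequencies contain missing values; run impute_missing() first.",
      "poolgp_missing_values")
  }
  xbar <- colMeans(X)
  K <- 0.5 * sum(xbar * (1 - xbar))
  if (K <= 0) {
    stop_poolgp("All markers are fixed (K = 0); kinship undefined.",
      "poolgp_degenerate")
  }
  M <- sweep(X, 2, xbar)
  G <- tcrossprod(M) / K
  G <- (G + t(G)) / 2
  kinship_matrix(G, K)
}

#' Within-scaffold frequency-correlation decay
#'
#' For pairs of markers on the same scaffold, computes the squared Pearson
#' correlation of their frequency columns and bins it by bp distance —
#' the pooled-data surrogate for linkage-disequilibrium decay (individual
#' allele content, hence true LD, is unobservable from pools). Pairs are
#' subsampled per scaffold to keep the cost bounded.
#'
#' @param freqs A [freq_matrix] with a marker map.
#' @param max_pairs_per_scaffold Cap on sampled pairs per scaffold.
#' @param bins Numeric vector of bp bin edges.
#' @param seed Integer seed for the pair subsampling.
#' @param squared If `FALSE`, report mean absolute correlation instead of
#'   mean squared correlation.
#' @return Tibble: `bin_mid_bp`, `mean_r2` (or `mean_abs_r`), `n_pairs`.
#' @export
correlation_decay <- function(freqs, max_pairs_per_scaffold = 2000L,
                              bins = c(0, 100, 1000, 5000, 10000, 20000, 50000, 100000),
                              seed = 1L, squared = TRUE) {
  stopifnot(inherits(freqs, "freq_matrix"))
  max_pairs_per_scaffold <- assert_count(max_pairs_per_scaffold, "max_pairs_per_scaffold", 1L)
  X <- impute_missing(freqs)$values
  map <- freqs$map
  pairs <- with_seed(seed, {
    purrr::map_dfr(split(seq_len(nrow(map)), map$scaffold), function(idx) {
      m <- length(idx)
      if (m < 2L) {
        return(NULL)
      }
      all_pairs <- utils::combn(idx, 2L)
      if (ncol(all_pairs) > max_pairs_per_scaffold) {
        all_pairs <- all_pairs[, sample.int(ncol(all_pairs), max_pairs_per_scaffold),
          drop = FALSE]
      }
      tibble(i = all_pairs[1, ], j = all_pairs[2, ])
    })
  })
  if (nrow(pairs) == 0L) {
    return(tibble(bin_mid_bp = numeric(0), mean_r2 = numeric(0), n_pairs = integer(0)))
  }
  pairs$dist_bp <- abs(map$pos_bp[pairs$j] - map$pos_bp[pairs$i])
  sds <- apply(X, 2, sd)
  ok <- sds[pairs$i] > 0 & sds[pairs$j] > 0
  pairs <- pairs[ok, ]
  Xc <- scale(X)
  r <- colSums(Xc[, pairs$i, drop = FALSE] * Xc[, pairs$j, drop = FALSE]) / (nrow(X) - 1)
  pairs$stat <- if (squared) r^2 else abs(r)
  pairs$bin <- cut(pairs$dist_bp, breaks = bins, include.lowest = TRUE, right = FALSE)
  out <- pairs |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(stat = mean(.data$stat), n_pairs = dplyr::n(), .groups = "drop")
  mids <- (bins[-length(bins)] + bins[-1]) / 2
  out$bin_mid_bp <- mids[match(out$bin, levels(cut(0, bins, include.lowest = TRUE, right = FALSE)))]
  res <- tibble(
    bin_mid_bp = out$bin_mid_bp,
    n_pairs = as.integer(out$n_pairs)
  )
  if (squared) res$mean_r2 <- out$stat else res$mean_abs_r <- out$stat
  res <- res[, c("bin_mid_bp", setdiff(names(res), c("bin_mid_bp", "n_pairs")), "n_pairs")]
  class(res) <- c("poolgp_decay", class(res))
  res
}

#' @describeIn correlation_decay Decay-curve plot (mean statistic vs bp).
#' @param object A decay table from [correlation_decay()].
#' @param ... Ignored.
#' @method autoplot poolgp_decay
#' @export
autoplot.poolgp_decay <- function(object, ...) {
  stat <- if ("mean_r2" %in% names(object)) "mean_r2" else "mean_abs_r"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid_bp, y = .data[[stat]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "pairwise distance (bp)",
      y = if (stat == "mean_r2") "mean squared correlation" else "mean |correlation|"
    ) +
    ggplot2::theme_minimal()
}
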
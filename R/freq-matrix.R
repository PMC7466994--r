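#' Population-by-marker allele-frequency matrix
#'
#' The central container of the package: an `n` populations by `p` markers
#' numeric matrix of alternative-allele frequencies in `[0, 1]`, with `NA`
#' marking missing calls, plus a marker map giving each marker a scaffold and
#' a 1-based bp position. Population and marker identifiers live in the
#' matrix dimnames.
#'
#' @param values Numeric matrix with unique rownames (population ids) and
#'   unique colnames (marker ids); non-missing entries must lie in `[0, 1]`.
#' @param map Data frame with columns `marker_id`, `scaffold`, `pos_bp`
#'   covering every column of `values`. If omitted, all markers are placed on
#'   a single synthetic scaffold at consecutive positions.
#' @return An object of class `freq_matrix`: a list with elements `values`
#'   (the matrix) and `map` (a tibble, in column order of `values`).
#' @examples
#' m <- matrix(c(0.2, 0.6, 0.1, 0.9), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("m1", "m2"))
#' )
#' fq <- freq_matrix(m)
#' dim(fq)
#' @export
freq_matrix <- function(values, map = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_poolgp("`values` must be a numeric matrix.", "poolgp_invalid_argument")
  }
  if (nrow(values) < 2L || ncol(values) < 1L) {
    stop_poolgp("Need at least 2 populations and 1 marker.", "poolgp_invalid_argument")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_poolgp("`values` must carry population rownames and marker colnames.",
      "poolgp_invalid_argument")
  }
  if (anyDuplicated(rownames(values))) {
    stop_poolgp("Duplicated population ids.", "poolgp_format_error")
  }
  if (anyDuplicated(colnames(values))) {
    stop_poolgp("Duplicated marker ids.", "poolgp_format_error")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_poolgp(
      sprintf(
        "Frequency outside [0, 1] at population '%s', marker '%s'.",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
      ),
      "poolgp_format_error"
    )
  }
  if (is.null(map)) {
    map <- tibble(
      marker_id = colnames(values),
      scaffold = "scaffold_1",
      pos_bp = seq_len(ncol(values))
    )
  }
  map <- as_tibble(map)
  needed <- c("marker_id", "scaffold", "pos_bp")
  if (!all(needed %in% names(map))) {
    stop_poolgp("`map` must have columns marker_id, scaffold, pos_bp.",
      "poolgp_invalid_argument")
  }
  if (!all(colnames(values) %in% map$marker_id)) {
    stop_poolgp("Every marker must have a map entry.", "poolgp_format_error")
  }
  map <- map[match(colnames(values), map$marker_id), needed]
  if (any(map$pos_bp < 1 | map$pos_bp != floor(map$pos_bp))) {
    stop_poolgp("`pos_bp` must be 1-based integer positions.", "poolgp_format_error")
  }
  structure(list(values = values, map = map), class = "freq_matrix")
}

#' @export
dim.freq_matrix <- function(x) dim(x$values)

#' @export
dimnames.freq_matrix <- function(x) dimnames(x$values)

#' Population ids of a poolgp object
#' @param x A `freq_matrix`, `kinship_matrix` or similar container.
#' @return Character vector of population ids.
#' @export
pop_ids <- function(x) UseMethod("pop_ids")

#' @export
pop_ids.freq_matrix <- function(x) rownames(x$values)

#' @export
pop_ids.kinship_matrix <- function(x) rownames(x$G)

#' Marker ids of an allele-frequency matrix
#' @param x A `freq_matrix`.
#' @return Character vector of marker ids, in column order.
#' @export
marker_ids <- function(x) colnames(x$values)

#' Subset a frequency matrix by population and/or marker
#'
#' @param x A `freq_matrix`.
#' @param i,j Population / marker indices (integer, logical or character).
#' @param ... Ignored.
#' @return A `freq_matrix` restricted to the selection; the map follows.
#' @export
`[.freq_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  freq_matrix(x$values[i, j, drop = FALSE], x$map)
}

#' @export
print.freq_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf(
    "<freq_matrix> %d populations x %d markers (%d scaffolds, %.1f%% missing)\n",
    nrow(x$values), ncol(x$values), length(unique(x$map$scaffold)),
    100 * n_missing / length(x$values)
  ))
  invisible(x)
}

#' @describeIn freq_matrix Long-format view: one row per (population, marker)
#'   cell with its frequency, scaffold and position; missing cells keep `NA`.
#' @param x A `freq_matrix`.
#' @param ... Ignored.
#' @method tidy freq_matrix
#' @export
tidy.freq_matrix <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "pop_id") |>
    tidyr::pivot_longer(-"pop_id", names_to = "marker_id", values_to = "freq")
  dplyr::left_join(out, x$map, by = "marker_id")
}

#' Pooled genomic relationship (kinship) matrix
#'
#' Container for the population-level genomic relationship matrix
#' `G = M M' / K` where `M` is the column-centered frequency matrix and `K`
#' is the sum-of-genetic-variance scaling constant
#' `0.5 * sum_j xbar_j (1 - xbar_j)`.
#'
#' @param G Symmetric numeric matrix with population dimnames.
#' @param K Positive scaling constant used in the denominator.
#' @return An object of class `kinship_matrix` with elements `G` and `K`.
#' @seealso [kinship()]
#' @export
kinship_matrix <- function(G, K) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    stop_poolgp("`G` must be a square matrix.", "poolgp_invalid_argument")
  }
  if (max(abs(G - t(G))) > 1e-10) {
    stop_poolgp("`G` must be symmetric (tolerance 1e-10).", "poolgp_invalid_argument")
  }
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop_poolgp("`K` must be a positive scalar.", "poolgp_invalid_argument")
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop_poolgp("`G` is not positive semidefinite within tolerance.",
      "poolgp_not_psd")
  }
  structure(list(G = G, K = K), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf(
    "<kinship_matrix> %d populations, K = %.6g, trace = %.4g\n",
    nrow(x$G), x$K, sum(diag(x$G))
  ))
  invisible(x)
}

#' @describeIn kinship_matrix Long-format pairwise view (`pop_1`, `pop_2`,
#'   `relationship`), including the diagonal.
#' @param x A `kinship_matrix`.
#' @param ... Ignored.
#' @method tidy kinship_matrix
#' @export
tidy.kinship_matrix <- function(x, ...) {
  as_tibble(x$G, rownames = "pop_1") |>
    tidyr::pivot_longer(-"pop_1", names_to = "pop_2", values_to = "relationship")
}

#' Pairwise distance matrix with a units tag
#'
#' @param D Symmetric non-negative matrix with zero diagonal and id dimnames.
#' @param units One of `"meters"`, `"euclidean-genetic"`,
#'   `"euclidean-phenotypic"`, or another short tag.
#' @return A `dist_matrix`: the matrix with a `units` attribute.
#' @export
dist_matrix <- function(D, units) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop_poolgp("`D` must be square.", "poolgp_invalid_argument")
  }
  if (is.null(rownames(D))) {
    stop_poolgp("`D` must carry id dimnames.", "poolgp_invalid_argument")
  }
  if (max(abs(D - t(D))) > 1e-8 || any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    stop_poolgp("`D` must be symmetric, non-negative, zero-diagonal.",
      "poolgp_invalid_argument")
  }
  structure(D, units = units, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf(
    "<dist_matrix> %d ids, units = %s, max = %.4g\n",
    nrow(x), attr(x, "units"), max(x)
  ))
  invisible(x)
}
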
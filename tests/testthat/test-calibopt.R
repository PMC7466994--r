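test_that("cluster-stratified selection covers degenerate and separated cases", {
  fq <- fx_freqs(n = 20, seed = 301)
  D <- euclidean_distances(fq)

  # k = n selects everyone.
  all_set <- select_by_clustering(D, 20)
  expect_setequal(all_set$pop_ids, pop_ids(fq))
  expect_identical(all_set$method, "genetic")

  # k = 1 picks the population with global minimum average distance.
  one <- select_by_clustering(D, 1)
  avg <- rowSums(unclass(D)) / (nrow(D) - 1)
  expect_identical(one$pop_ids, names(which.min(avg)))

  expect_error(select_by_clustering(D, 21), class = "poolgp_invalid_argument")

  # Two well-separated clusters yield one representative from each.
  M <- matrix(0, 10, 10, dimnames = list(sprintf("q%02d", 1:10), sprintf("q%02d", 1:10)))
  M[1:5, 6:10] <- 100
  M[6:10, 1:5] <- 100
  M[1:5, 1:5] <- matrix(runif(25, 0.5, 1.5), 5)
  M[6:10, 6:10] <- matrix(runif(25, 0.5, 1.5), 5)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  sel <- select_by_clustering(dist_matrix(M, "euclidean-genetic"), 2)
  expect_length(intersect(sel$pop_ids, rownames(M)[1:5]), 1)
  expect_length(intersect(sel$pop_ids, rownames(M)[6:10]), 1)
})

test_that("spatially constrained clustering degenerates to its extremes", {
  panel <- fx_panel(n = 25, seed = 311)
  fq <- fx_freqs(n = 25, seed = 311)
  D_gen <- euclidean_distances(fq)
  D_geo <- geo_distances(panel)

  expect_identical(
    select_clustgeo(D_gen, D_geo, 6, alpha = 0)$pop_ids,
    unname(select_by_clustering(D_gen, 6)$pop_ids)
  )
  expect_identical(
    select_clustgeo(D_gen, D_geo, 6, alpha = 1)$pop_ids,
    unname(select_by_clustering(D_geo, 6)$pop_ids)
  )

  # When genetic and spatial structure coincide, the blend agrees with
  # either extreme.
  ang <- c(rep(0, 8), rep(pi, 9), rep(pi / 2, 8))
  pan2 <- tibble::tibble(
    pop_id = sprintf("r%02d", 1:25),
    lon = 3 * cos(ang) + runif(25, -0.05, 0.05),
    lat = 3 * sin(ang) + runif(25, -0.05, 0.05)
  )
  Dg <- geo_distances(pan2)
  Dg2 <- dist_matrix(unclass(Dg) * 2, "euclidean-genetic")
  part_mix <- select_clustgeo(Dg2, Dg, 3, alpha = 0.5)
  part_gen <- select_by_clustering(Dg2, 3)
  expect_setequal(part_mix$pop_ids, part_gen$pop_ids)

  bad <- unclass(D_geo)
  rownames(bad) <- colnames(bad) <- rev(rownames(bad))
  expect_error(select_clustgeo(D_gen, dist_matrix(bad, "meters"), 3),
    class = "poolgp_id_mismatch")
})

test_that("CDmean exchange improves monotonically and matches brute force at k = n-1", {
  fq <- fx_freqs(n = 30, seed = 321)
  G <- kinship(fq)

  set.seed(1)
  cs <- select_cdmean(G, 10, n_iter = 150, seed = 3)
  traj <- cs$params$trajectory
  expect_true(all(diff(traj) > 0))
  expect_equal(cs$params$cdmean, max(traj))

  # k = n - 1: hill-climbing must find the best single validation pop.
  Gm <- G$G
  ridge <- 1e-6 * mean(diag(Gm))
  Ginv <- solve(Gm + ridge * diag(30))
  brute <- vapply(seq_len(30), function(i) {
    poolgp:::cdmean_value(Gm, Ginv, setdiff(seq_len(30), i), 1)
  }, numeric(1))
  cs_big <- select_cdmean(G, 29, n_iter = 200, seed = 5)
  expect_equal(cs_big$params$cdmean, max(brute), tolerance = 1e-10)

  # Optimized CDmean beats the average of random same-size sets.
  rand_cd <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    poolgp:::cdmean_value(Gm, Ginv, sort(sample.int(30, 10)), 1)
  }, numeric(1))
  expect_gt(cs$params$cdmean, mean(rand_cd))
})

test_that("the performance score is the envelope-relative position", {
  expect_equal(performance(0.4, 0.2, 0.6), 0.5)
  expect_equal(performance(0.6, 0.2, 0.6), 1)
  expect_equal(performance(0.7, 0.2, 0.6), 1.25) # above 1 is permitted
  expect_equal(performance(0.1, 0.2, 0.6), -0.25)
  expect_error(performance(0.5, 0.6, 0.6), class = "poolgp_undefined_score")
})

test_that("calibration evaluation builds a coherent random envelope", {
  fq <- fx_freqs(n = 60, seed = 331)
  sim <- simulate_phenotypes(fq, n_qtl = 30, h2_pop = 0.9, seed = 331)
  y <- setNames(sim$truth$g + rnorm(60, sd = 0.4), pop_ids(fq))

  rs <- select_random(pop_ids(fq), 20, seed = 9)
  ev <- evaluate_calibration(fq, y, rs, n_random = 30, seed = 11)
  rand_pa <- attr(ev, "random_pa")
  expect_lte(ev$min_pa, median(rand_pa, na.rm = TRUE))
  expect_gte(ev$max_pa, median(rand_pa, na.rm = TRUE))
  # A random set scored against its own envelope lies in a sane band.
  expect_gte(ev$opt_pa, ev$min_pa - 0.25)
  expect_lte(ev$opt_pa, ev$max_pa + 0.25)

  # Scoring a set drawn by the same protocol as the envelope: the score of
  # each envelope member against the envelope is in [0, 1] by definition.
  scores <- (rand_pa - min(rand_pa)) / (max(rand_pa) - min(rand_pa))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("genetic and spatial selections overlap under strong IBD", {
  panel <- fx_panel(n = 60, seed = 341)
  fq <- simulate_frequencies(panel, 8, 25, ibd_range_km = 2000, seed = 341)
  D_gen <- euclidean_distances(fq)
  D_geo <- geo_distances(panel)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  k <- 15
  j_obs <- jacc(
    select_by_clustering(D_gen, k)$pop_ids,
    select_by_clustering(D_geo, k)$pop_ids
  )
  j_rand <- vapply(1:10, function(s) {
    jacc(
      select_random(pop_ids(fq), k, seed = 2 * s)$pop_ids,
      select_random(pop_ids(fq), k, seed = 2 * s + 1)$pop_ids
    )
  }, numeric(1))
  expect_gt(j_obs, mean(j_rand))
})

test_that("the GWAS set finds planted causal markers and resists noise", {
  fq <- fx_freqs(n = 60, seed = 351)
  G <- kinship(fq)

  # Monogenic noiseless: the QTL (or a same-scaffold proxy) leads the set.
  x <- fq$values[, 25]
  y1 <- 3 * x + 1
  gs <- build_gwas_set(fq, y1, G)
  expect_gte(length(gs), 1)
  qtl_scaffold <- fq$map$scaffold[25]
  expect_true(gs[1] == marker_ids(fq)[25] ||
    fq$map$scaffold[match(gs[1], fq$map$marker_id)] == qtl_scaffold)

  # Pure noise: few markers survive the 5% F-test entry rule.
  sizes <- vapply(1:5, function(s) {
    set.seed(3500 + s)
    length(build_gwas_set(fq, rnorm(60), G))
  }, numeric(1))
  expect_lte(mean(sizes) / ncol(fq$values), 0.10)

  # A duplicated top marker can never enter twice.
  vals <- fq$values
  vals[, 26] <- vals[, 25]
  fq_dup <- freq_matrix(vals, fq$map)
  gs_dup <- build_gwas_set(fq_dup, y1, kinship(fq_dup))
  expect_false(all(marker_ids(fq)[25:26] %in% gs_dup))
})

test_that("marker curves report min_markers_95 per regime", {
  fq <- fx_freqs(n = 80, seed = 361)
  x <- fq$values[, 40]
  y <- setNames(3 * x + 1 + rnorm(80, sd = 0.05), pop_ids(fq))
  cal <- pop_ids(fq)[1:60]
  val <- pop_ids(fq)[61:80]
  gs <- build_gwas_set(fq[cal, ], y[cal], kinship(fq[cal, ]))
  mc <- marker_curve(fq, y, cal, val, gs, max_random = 40, seed = 13)
  m95 <- attr(mc, "min_markers_95")

  # Monogenic: the GWAS-first regime needs exactly one marker.
  expect_equal(m95$min_markers_95[m95$regime == "gwas_first"], 1L)

  # The curve maximum is at least the single-marker value in both regimes.
  for (rg in c("gwas_first", "random_first")) {
    sub <- mc[mc$regime == rg, ]
    expect_gte(max(sub$pa, na.rm = TRUE), sub$pa[sub$n_markers == 1])
  }

  # Counts are strictly increasing within regime.
  expect_true(all(tapply(mc$n_markers, mc$regime, function(v) all(diff(v) == 1))))

  expect_error(marker_curve(fq, y, cal, cal[1:5], gs),
    class = "poolgp_invalid_argument")
})

test_that("selection procedures are deterministic and produce valid subsets", {
  fq <- fx_freqs(n = 40, seed = 371)
  G <- kinship(fq)
  D <- euclidean_distances(fq)
  a <- select_cdmean(G, 12, n_iter = 80, seed = 21)
  b <- select_cdmean(G, 12, n_iter = 80, seed = 21)
  expect_identical(a$pop_ids, b$pop_ids)
  expect_length(a$pop_ids, 12)
  expect_true(all(a$pop_ids %in% pop_ids(fq)))
  expect_identical(
    select_by_clustering(D, 9)$pop_ids,
    select_by_clustering(D, 9)$pop_ids
  )
})
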
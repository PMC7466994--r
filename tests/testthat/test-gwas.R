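test_that("spectral REML recovers the variance ratio and maximises the likelihood", {
  panel <- fx_panel(n = 120, seed = 41)
  fq <- fx_freqs(n = 120, n_scaffolds = 10, markers_per_scaffold = 30, seed = 41)
  G <- kinship(fq)
  L <- t(chol(G$G + 1e-6 * diag(nrow(G$G))))

  # delta recovery at sigma_g2 = sigma_e2 = 1.
  deltas <- vapply(1:20, function(s) {
    set.seed(900 + s)
    y <- drop(L %*% rnorm(120)) + rnorm(120)
    fit_null_mm(y, G)$delta
  }, numeric(1))
  expect_gt(mean(deltas >= 0.4 & deltas <= 2.5), 0.8)
  expect_true(median(deltas) > 0.5 && median(deltas) < 2)

  # Identity K: only the total variance is identified, and it equals var(y).
  set.seed(3)
  y <- rnorm(40, sd = 2)
  fit_i <- fit_null_mm(y, diag(40))
  expect_equal(fit_i$sigma_g2 + fit_i$sigma_e2, var(y), tolerance = 1e-6)

  # Returned delta beats a 1000-point brute-force log grid.
  set.seed(8)
  y2 <- drop(L %*% rnorm(120)) + rnorm(120)
  fit2 <- fit_null_mm(y2, G)
  ll_hat <- poolgp:::reml_profile(fit2$xi, fit2$eta2, fit2$delta)
  grid <- 10^seq(-5, 5, length.out = 1000)
  ll_grid <- vapply(grid, function(d) poolgp:::reml_profile(fit2$xi, fit2$eta2, d),
    numeric(1))
  expect_gte(ll_hat, max(ll_grid) - 1e-4)
})

test_that("a perfectly explanatory marker is found with R2 = 1 and p ~ 0", {
  fq <- fx_freqs(n = 40, seed = 51)
  x <- fq$values[, 17]
  y <- 2.5 * x + 1
  scan <- run_gwas(y, fq, model = "naive")
  j <- which(scan$marker_id == marker_ids(fq)[17])
  expect_equal(scan$r2_ols[j], 1, tolerance = 1e-10)
  expect_lt(scan$p_value[j], 1e-20)
  expect_equal(scan$beta[j], 2.5, tolerance = 1e-8)
})

test_that("kinship-model p-values match a dense GLS oracle", {
  panel <- fx_panel(n = 30, seed = 61)
  fq <- fx_freqs(n = 30, n_scaffolds = 5, markers_per_scaffold = 20, seed = 61)
  sim <- simulate_phenotypes(fq, n_qtl = 4, h2_pop = 0.8, seed = 61)
  y <- unname(tapply(sim$records$value, sim$records$pop_id, mean))[
    match(pop_ids(fq), sort(unique(sim$records$pop_id)))]
  G <- kinship(fq)
  scan <- run_gwas(y, fq, model = "kinship", G = G)
  H <- attr(scan, "sigma_g2") * G$G + attr(scan, "sigma_e2") * diag(30)
  X0 <- matrix(1, 30, 1)
  p_oracle <- vapply(seq_len(ncol(fq$values)), function(j) {
    oracle_gls_p(y, X0, fq$values[, j], H)
  }, numeric(1))
  expect_equal(scan$p_value, p_oracle, tolerance = 1e-8)
})

test_that("kinship GLS with an identity relationship reproduces plain OLS", {
  fq <- fx_freqs(n = 35, seed = 71)
  set.seed(71)
  y <- rnorm(35)
  naive <- run_gwas(y, fq, model = "naive")
  ident <- run_gwas(y, fq, model = "kinship", G = diag(35))
  expect_equal(ident$p_value, naive$p_value, tolerance = 1e-10)
  expect_equal(ident$beta, naive$beta, tolerance = 1e-10)
})

test_that("structure covariates are honoured and zero-variance markers flagged", {
  fq <- fx_freqs(n = 40, seed = 81)
  vals <- fq$values
  vals[, 5] <- 0.5 # constant marker
  fq2 <- freq_matrix(vals, fq$map)
  clusters <- rep(c("A", "B"), each = 20)
  set.seed(81)
  y <- ifelse(clusters == "A", 2, -2) + rnorm(40, sd = 0.5)
  scan <- run_gwas(y, fq2, model = "structure", clusters = clusters)
  expect_true(scan$zero_variance[5])
  expect_equal(scan$p_value[5], 1)
  expect_equal(scan$beta[5], 0)
  # After the cluster covariate, no marker should explain the cluster split.
  expect_gt(min(scan$q_value, na.rm = TRUE), 0.1)
})

test_that("P3D and exact per-marker REML agree in rank", {
  panel <- fx_panel(n = 30, seed = 91)
  fq <- fx_freqs(n = 30, n_scaffolds = 8, markers_per_scaffold = 25, seed = 91)
  sim <- simulate_phenotypes(fq, n_qtl = 6, h2_pop = 0.8, seed = 91)
  am <- adjusted_means(fit_model2(sim$records, "trait_1"))
  y <- setNames(am$mean, am$pop_id)[pop_ids(fq)]
  G <- kinship(fq)
  fast <- run_gwas(y, fq, model = "kinship", G = G, p3d = TRUE)
  slow <- run_gwas(y, fq, model = "kinship", G = G, p3d = FALSE)
  expect_gt(cor(fast$p_value, slow$p_value, method = "spearman"), 0.99)
})

test_that("q-values follow the Benjamini-Hochberg definition", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_error(qvalues(c(0.5, 1.2)), class = "poolgp_invalid_argument")

  set.seed(13)
  for (k in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- qvalues(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("the significance rule is a strict q threshold ordered by p", {
  fq <- fx_freqs(n = 40, seed = 101)
  tab <- run_gwas(rnorm(40), fq, model = "naive")
  tab$q_value <- rep(0.5, nrow(tab))
  expect_length(significant(tab), 0)
  tab$q_value <- rep(0, nrow(tab))
  expect_length(significant(tab), nrow(tab))
  tab$q_value <- c(0.05, rep(0.5, nrow(tab) - 1))
  tab$p_value <- seq_len(nrow(tab)) / nrow(tab)
  expect_identical(significant(tab), tab$marker_id[1])
  # Boundary: q exactly at the threshold is not significant.
  tab$q_value <- c(0.10, rep(0.5, nrow(tab) - 1))
  expect_length(significant(tab), 0)
})

test_that("variance explained: limits and structure-confounding contrast", {
  fq <- fx_freqs(n = 60, seed = 111)
  x <- fq$values[, 3]
  expect_equal(variance_explained(x, x)$r2_ols, 1)
  expect_equal(variance_explained(rnorm(60), rep(0.4, 60))$r2_ols, 0)

  # Vanishing-kinship limit: whitened partial R2 converges to OLS R2.
  set.seed(111)
  y <- 0.8 * x + rnorm(60, sd = 0.3)
  null_weak <- fit_null_mm(y, 1e-8 * kinship(fq)$G)
  ve <- variance_explained(y, x, null_weak)
  expect_equal(ve$r2_kinship, ve$r2_ols, tolerance = 1e-6)

  # Structure-tracking markers lose explanatory power once whitened.
  panel <- fx_panel(n = 100, seed = 115)
  fqs <- simulate_frequencies(panel, 10, 30, ibd_range_km = 2000, seed = 115)
  G <- kinship(fqs)
  # A purely structural trait: smooth in space, no single causal marker.
  y_str <- scale(panel$lat + panel$lon)[, 1] + rnorm(100, sd = 0.2)
  null_fit <- fit_null_mm(y_str, G)
  r2o <- apply(fqs$values, 2, function(xx) cor(y_str, xx)^2)
  top <- order(r2o, decreasing = TRUE)[1:20]
  ve_top <- purrr::map_dfr(top, function(j) {
    variance_explained(y_str, fqs$values[, j], null_fit)
  })
  expect_true(all(ve_top$r2_kinship <= ve_top$r2_ols + 1e-8))
})

test_that("redundancy pruning matches the double-loop definition", {
  fq <- fx_freqs(n = 40, n_scaffolds = 6, markers_per_scaffold = 10, seed = 121)
  ids <- marker_ids(fq)
  expect_identical(prune_by_correlation(ids[1], fq, 0.9)$marker_ids, ids[1])

  # A duplicated pair is never unlinked.
  vals <- fq$values
  vals[, 2] <- vals[, 1]
  fq_dup <- freq_matrix(vals, fq$map)
  pr <- prune_by_correlation(ids[1:4], fq_dup, 1)
  expect_false(ids[1] %in% pr$marker_ids)
  expect_false(ids[2] %in% pr$marker_ids)

  # O(m^2) oracle on a 50-marker set across thresholds.
  sub <- ids[1:50]
  X <- fq$values[, sub]
  for (t in c(0.1, 0.5, 0.9)) {
    oracle <- sub[vapply(seq_along(sub), function(i) {
      others <- setdiff(seq_along(sub), i)
      all(vapply(others, function(j) abs(cor(X[, i], X[, j])) < t, logical(1)))
    }, logical(1))]
    expect_identical(prune_by_correlation(sub, fq, t)$marker_ids, oracle)
  }
})

test_that("forward stepwise selection is AIC-greedy and truncates candidates", {
  fq <- fx_freqs(n = 50, seed = 131)
  ids <- marker_ids(fq)
  x1 <- fq$values[, 10]
  set.seed(131)
  y <- 2 * x1 + rnorm(50, sd = 0.3)

  # Single candidate: kept, with R2 equal to its simple-regression R2.
  sw1 <- stepwise_model(y, ids[10], fq)
  expect_identical(sw1$selected, ids[10])
  expect_equal(sw1$r_squared, cor(y, x1)^2, tolerance = 1e-10)

  # A duplicated candidate can never enter twice.
  vals <- fq$values
  vals[, 11] <- vals[, 10]
  fq_dup <- freq_matrix(vals, fq$map)
  sw2 <- stepwise_model(y, ids[c(10, 11)], fq_dup)
  expect_identical(sw2$selected, ids[10])

  # Two independent planted QTL both enter; joint R2 beats each single R2.
  x2 <- fq$values[, 30]
  set.seed(132)
  y2 <- 1.5 * x1 - 2 * x2 + rnorm(50, sd = 0.3)
  sw3 <- stepwise_model(y2, ids[c(10, 30)], fq)
  expect_setequal(sw3$selected, ids[c(10, 30)])
  expect_gt(sw3$r_squared, cor(y2, x1)^2)
  expect_gt(sw3$r_squared, cor(y2, x2)^2)

  # More candidates than populations: truncated to n - 2 by rank.
  sw4 <- stepwise_model(y2, ids, fq)
  expect_lte(sw4$n_candidates, 48)
})

test_that("kinship correction deflates structured-trait test statistics", {
  panel <- fx_panel(n = 100, seed = 141)
  fq <- simulate_frequencies(panel, 12, 30, ibd_range_km = 1500, seed = 141)
  G <- kinship(fq)
  ratios <- t(vapply(1:15, function(s) {
    sim <- simulate_phenotypes(fq, n_qtl = 200, h2_pop = 0.8, n_envs = 1,
      seed = 1400 + s)
    y <- sim$truth$g + rnorm(100, sd = 0.5)
    naive <- run_gwas(y, fq, model = "naive")
    kin <- run_gwas(y, fq, model = "kinship", G = G)
    infl <- function(p) median(qchisq(1 - p, 1)) / qchisq(0.5, 1)
    c(infl(naive$p_value), infl(kin$p_value))
  }, numeric(2)))
  # Naive scans are inflated on structured traits; kinship scans are not.
  expect_gt(mean(ratios[, 1] > ratios[, 2]), 0.8)
  expect_gt(median(ratios[, 1]), 1.2)
  expect_lt(abs(median(ratios[, 2]) - 1), 0.3)
})

test_that("q < 0.10 discoveries keep the false-discovery proportion in check", {
  fdp <- vapply(1:8, function(s) {
    panel <- generate_panel(150, seed = 1500 + s)
    fq <- simulate_frequencies(panel, 20, 50, within_scaffold_corr = 0,
      seed = 1500 + s)
    sim <- simulate_phenotypes(fq, n_qtl = 10, h2_pop = 0.9, n_envs = 1,
      effect_dist = "exponential", seed = 1500 + s)
    y <- setNames(sim$truth$g + rnorm(150, sd = sqrt(1 / 0.9 - 1)), pop_ids(fq))
    scan <- run_gwas(y, fq, model = "kinship", G = kinship(fq))
    hits <- significant(scan, 0.10)
    if (length(hits) == 0) {
      return(0)
    }
    mean(!hits %in% sim$truth$qtl_marker_ids)
  }, numeric(1))
  expect_lte(mean(fdp), 0.15)
})
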
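balanced_records <- function(n_pops, n_envs, n_blocks, f = function(g, e, b) 0,
                             trait = "t") {
  grid <- expand.grid(
    pop_id = sprintf("p%03d", seq_len(n_pops)),
    env = sprintf("e%d", seq_len(n_envs)),
    block = sprintf("b%d", seq_len(n_blocks)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$trait <- trait
  grid$value <- mapply(f,
    as.integer(factor(grid$pop_id)),
    as.integer(factor(grid$env)),
    as.integer(factor(grid$block))
  )
  tibble::as_tibble(grid)
}

test_that("model 1 is exact on zero-residual data", {
  pop_eff <- c(1, 4, -2, 0.5, 3)
  blk_eff <- c(0, 2, -1)
  rec <- balanced_records(5, 1, 3, function(g, e, b) 10 + pop_eff[g] + blk_eff[b])
  # anova warns that F-tests on an exact fit are unreliable; the components
  # and means are still exact, which is what this checks.
  fit <- suppressWarnings(fit_model1(rec, "t", "e1"))
  expect_equal(fit$sigma_e2, 0, tolerance = 1e-20)
  am <- adjusted_means(fit)
  raw <- tapply(rec$value, rec$pop_id, mean)
  expect_equal(am$mean, as.numeric(raw[am$pop_id]), tolerance = 1e-10)
})

test_that("model 1 rejects degenerate or unbalanced designs", {
  rec <- balanced_records(5, 1, 3, function(g, e, b) g + b)
  expect_error(fit_model1(rec[rec$pop_id == "p001", ], "t", "e1"),
    class = "poolgp_invalid_argument")
  expect_error(fit_model1(rec[-1, ], "t", "e1"), class = "poolgp_unsupported_design")
  dup <- rbind(rec, rec[1, ])
  expect_error(fit_model1(dup, "t", "e1"), class = "poolgp_unsupported_design")
})

test_that("adjusted means are LS-means: balanced identity, equivariance, oracle", {
  set.seed(5)
  rec <- balanced_records(5, 1, 3, function(g, e, b) g * 1.5 + b + rnorm(1))
  fit <- fit_model1(rec, "t", "e1")
  am <- adjusted_means(fit)

  # Balanced-design identity with raw means.
  raw <- tapply(rec$value, rec$pop_id, mean)
  expect_equal(am$mean, as.numeric(raw[am$pop_id]), tolerance = 1e-10)

  # Shift equivariance.
  rec_c <- dplyr::mutate(rec, value = value + 7.3)
  am_c <- adjusted_means(fit_model1(rec_c, "t", "e1"))
  expect_equal(am_c$mean, am$mean + 7.3, tolerance = 1e-10)

  # Independent normal-equations oracle.
  dat <- fit$data
  expect_equal(setNames(am$mean, am$pop_id), oracle_ls_means(dat),
    tolerance = 1e-8)

  # emmeans cross-check on the same linear model.
  emm <- emmeans::emmeans(stats::lm(value ~ pop_id + block, data = dat), "pop_id")
  emm_df <- as.data.frame(emm)
  expect_equal(am$mean, emm_df$emmean[match(am$pop_id, emm_df$pop_id)],
    tolerance = 1e-8)
})

test_that("model 2 mean squares and components behave as constructed", {
  # No-interaction data: sigma_ge2 estimates near zero.
  fq <- fx_freqs(n = 100)
  sim <- simulate_phenotypes(fq, n_qtl = 20, h2_pop = 0.7, gxe_share = 0, seed = 3)
  fit <- fit_model2(sim$records, "trait_1")
  expect_lt(fit$sigma_ge2, 0.05 * (fit$sigma_g2 + fit$sigma_e2))

  # J < 2 is unsupported.
  one_env <- sim$records[sim$records$env == "env_1", ]
  expect_error(fit_model2(one_env, "trait_1"), class = "poolgp_unsupported_design")

  # Permuting environment labels leaves the mean squares unchanged.
  rec <- sim$records
  rec_p <- dplyr::mutate(rec, env = c(env_1 = "env_2", env_2 = "env_3", env_3 = "env_1")[env])
  expect_equal(fit_model2(rec_p, "trait_1")$anova_table$`Mean Sq`,
    fit$anova_table$`Mean Sq`, tolerance = 1e-10)
})

test_that("variance components are recovered from simulated balanced trials", {
  # Direct simulation at known components: sigma_g2 = 2, sigma_e2 = 1, R = 3.
  est1 <- t(vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 200
    g <- rnorm(n, sd = sqrt(2))
    rec <- balanced_records(n, 1, 3, function(gi, e, b) g[gi] + 0.5 * b + rnorm(1))
    fit <- fit_model1(rec, "t", "e1")
    c(fit$sigma_g2, fit$sigma_e2)
  }, numeric(2)))
  expect_lt(abs(mean(est1[, 1]) - 2), 0.4)
  expect_lt(abs(mean(est1[, 2]) - 1), 0.2)

  # Model 2: sigma_g2 = 1, sigma_ge2 = 0.5, sigma_e2 = 1, J = 3, R = 3.
  est2 <- t(vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 200
    g <- rnorm(n)
    ge <- matrix(rnorm(n * 3, sd = sqrt(0.5)), n, 3)
    rec <- balanced_records(n, 3, 3, function(gi, e, b) {
      g[gi] + 2 * e + ge[gi, e] + 0.3 * b + rnorm(1)
    })
    fit <- fit_model2(rec, "t")
    c(fit$sigma_g2, fit$sigma_ge2, fit$sigma_e2)
  }, numeric(3)))
  expect_lt(abs(mean(est2[, 1]) - 1), 0.3)
  expect_lt(abs(mean(est2[, 2]) - 0.5), 0.15)
  expect_lt(abs(mean(est2[, 3]) - 1), 0.3)
})

test_that("expected-mean-squares components agree with a REML oracle on balance", {
  set.seed(77)
  n <- 30
  g <- rnorm(n, sd = 1.3)
  rec <- balanced_records(n, 1, 3, function(gi, e, b) 5 + g[gi] + 0.4 * b + rnorm(1))
  fit <- fit_model1(rec, "t", "e1")
  lf <- lme4::lmer(value ~ block + (1 | pop_id), data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma_g2, vc$vcov[vc$grp == "pop_id"], tolerance = 1e-3)
  expect_equal(fit$sigma_e2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("heritability formula evaluates exactly and stays in [0, 1]", {
  mk_fit <- function(model_id, sg, sge, se, R, J) {
    structure(list(model_id = model_id, sigma_g2 = sg, sigma_ge2 = sge,
      sigma_e2 = se, R = R, J = J), class = "anova_fit")
  }
  expect_equal(heritability(mk_fit(1L, 1, 0, 1, 3, 1)), 0.75)
  expect_equal(heritability(mk_fit(2L, 1, 1, 1, 3, 2)), 0.6)
  expect_equal(heritability(mk_fit(1L, 0, 0, 1, 3, 1)), 0)

  # Monotone increasing in sigma_g2, bounded by [0, 1].
  h <- vapply(seq(0, 5, by = 0.5), function(sg) {
    heritability(mk_fit(2L, sg, 0.7, 1.2, 3, 3))
  }, numeric(1))
  expect_true(all(diff(h) > 0 | (h[-1] == 0 & h[-length(h)] == 0)))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("population F-test p-values are uniform under the null", {
  fq <- fx_freqs(n = 60, seed = 71)
  pvals <- vapply(1:150, function(s) {
    sim <- simulate_phenotypes(fq, n_qtl = 0, h2_pop = 0.5, n_envs = 1,
      seed = 700 + s)
    fit_model1(sim$records, "trait_1", "env_1")$p_value
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("trait correlations handle identity, negation and shared QTL", {
  fq <- fx_freqs(n = 50, seed = 81)
  sim <- simulate_phenotypes(fq, n_qtl = 8, h2_pop = 0.9, seed = 81)
  m <- adjusted_means(fit_model2(sim$records, "trait_1"))
  means <- dplyr::bind_rows(
    tibble::tibble(pop_id = m$pop_id, trait = "a", mean = m$mean),
    tibble::tibble(pop_id = m$pop_id, trait = "neg", mean = -m$mean),
    tibble::tibble(pop_id = m$pop_id, trait = "b",
      mean = m$mean + rnorm(nrow(m), sd = 0.2 * sd(m$mean)))
  )
  ct <- trait_correlations(means)
  get <- function(a, b) ct$r[ct$trait_1 == a & ct$trait_2 == b]
  expect_equal(get("a", "a"), 1)
  expect_equal(get("a", "neg"), -1)
  expect_gt(get("a", "b"), 0.8) # same underlying genetic values
  expect_equal(get("a", "b"), get("b", "a"))

  # Undefined below 3 shared populations.
  sparse <- dplyr::bind_rows(
    tibble::tibble(pop_id = c("x", "y"), trait = "u", mean = c(1, 2)),
    tibble::tibble(pop_id = c("x", "y", "z"), trait = "v", mean = c(2, 1, 5))
  )
  cs <- trait_correlations(sparse)
  expect_true(is.na(cs$r[cs$trait_1 == "u" & cs$trait_2 == "v"]))
})
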
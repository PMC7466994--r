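#' Balanced complete-block ANOVA within one environment
#'
#' Fits the single-environment fixed-effect model
#' `Y_ij = mu + g_i + b_j + E_ij` (population and block effects) by OLS,
#' reports the F test of the population effect, and estimates variance
#' components of the random-population version by expected mean squares:
#' `sigma_g^2 = max(0, (MS_g - MS_e) / R)` with `R` blocks. Only balanced
#' complete-block data are accepted — every population observed once in
#' every block — where the expected-mean-squares estimators are exact.
#'
#' @param records Phenotype records: tibble with `pop_id`, `env`, `block`,
#'   `trait`, `value`.
#' @param trait Trait label to fit.
#' @param env Environment label to fit.
#' @return An `anova_fit` object (see [tidy.anova_fit()] / [glance.anova_fit()]).
#' @export
fit_model1 <- function(records, trait, env) {
  dat <- records[records$trait == trait & records$env == env, , drop = FALSE]
  check_balanced(dat, within_env = TRUE)
  dat$pop_id <- factor(dat$pop_id)
  dat$block <- factor(dat$block)
  fit <- aov(value ~ pop_id + block, data = dat)
  tab <- anova(fit)
  R <- nlevels(dat$block)
  ms_g <- tab["pop_id", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  structure(list(
    model_id = 1L,
    trait = trait,
    envs = env,
    R = R,
    J = 1L,
    anova_table = tab,
    sigma_g2 = max(0, (ms_g - ms_e) / R),
    sigma_ge2 = 0,
    sigma_e2 = ms_e,
    f_statistic = tab["pop_id", "F value"],
    p_value = tab["pop_id", "Pr(>F)"],
    fit = fit,
    data = dat
  ), class = "anova_fit")
}

#' Balanced multi-environment ANOVA with G x E
#'
#' Fits `Y_ijr = mu + g_i + env_j + (g x env)_ij + b/env_jr + E_ijr` on a
#' balanced complete-block design across `J >= 2` environments with `R`
#' blocks nested in each. Mean squares come from the fixed-effect fit; the
#' population F statistic uses the interaction mean square as denominator
#' (environment and interaction treated as random), and variance components
#' follow the expected mean squares:
#' `sigma_g^2 = max(0, (MS_g - MS_gxe) / (J R))`,
#' `sigma_ge^2 = max(0, (MS_gxe - MS_e) / R)`.
#'
#' @inheritParams fit_model1
#' @return An `anova_fit` object with `model_id = 2`.
#' @export
fit_model2 <- function(records, trait) {
  dat <- records[records$trait == trait, , drop = FALSE]
  if (length(unique(dat$env)) < 2L) {
    stop_poolgp("Model 2 needs at least 2 environments.", "poolgp_unsupported_design")
  }
  check_balanced(dat, within_env = FALSE)
  dat$pop_id <- factor(dat$pop_id)
  dat$env <- factor(dat$env)
  dat$block <- factor(dat$block)
  fit <- aov(value ~ pop_id + env + pop_id:env + env:block, data = dat)
  tab <- anova(fit)
  J <- nlevels(dat$env)
  R <- nlevels(dat$block)
  ms_g <- tab["pop_id", "Mean Sq"]
  ms_ge <- tab["pop_id:env", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  f_g <- ms_g / ms_ge
  df_g <- tab["pop_id", "Df"]
  df_ge <- tab["pop_id:env", "Df"]
  structure(list(
    model_id = 2L,
    trait = trait,
    envs = levels(dat$env),
    R = R,
    J = J,
    anova_table = tab,
    sigma_g2 = max(0, (ms_g - ms_ge) / (J * R)),
    sigma_ge2 = max(0, (ms_ge - ms_e) / R),
    sigma_e2 = ms_e,
    f_statistic = f_g,
    p_value = pf(f_g, df_g, df_ge, lower.tail = FALSE),
    fit = fit,
    data = dat
  ), class = "anova_fit")
}

check_balanced <- function(dat, within_env) {
  if (nrow(dat) == 0L) {
    stop_poolgp("No records for this trait/environment.", "poolgp_invalid_argument")
  }
  if (anyNA(dat$value) || !all(is.finite(dat$value))) {
    stop_poolgp("Phenotype values must be finite.", "poolgp_format_error")
  }
  if (length(unique(dat$pop_id)) < 2L) {
    stop_poolgp("Population effect is not estimable from a single population.",
      "poolgp_invalid_argument")
  }
  key <- if (within_env) {
    paste(dat$pop_id, dat$block)
  } else {
    paste(dat$pop_id, dat$env, dat$block)
  }
  counts <- table(key)
  expected <- length(unique(dat$pop_id)) *
    (if (within_env) 1L else length(unique(dat$env))) *
    length(unique(dat$block))
  if (any(counts != 1L) || length(counts) != expected) {
    stop_poolgp("Design is not a balanced complete block; this fit supports balanced data only.",
      "poolgp_unsupported_design")
  }
  if (length(unique(dat$block)) < 2L) {
    stop_poolgp("Need at least 2 blocks.", "poolgp_unsupported_design")
  }
  invisible(dat)
}

#' Least-squares adjusted means per population
#'
#' LS-means from the fixed-effect fit: the model prediction for each
#' population averaged over all block (and, for the multi-environment model,
#' environment) levels. On balanced data this equals the raw population
#' mean. Multi-environment means carry the conventional `_avg` suffix on the
#' trait label.
#'
#' @param fit An `anova_fit` from [fit_model1()] or [fit_model2()].
#' @return Tibble: `pop_id`, `trait`, `env` (`NA` for across-environment
#'   means), `mean`.
#' @export
adjusted_means <- function(fit) {
  stopifnot(inherits(fit, "anova_fit"))
  dat <- fit$data
  pops <- levels(dat$pop_id)
  if (fit$model_id == 1L) {
    grid <- expand.grid(pop_id = pops, block = levels(dat$block),
      KEEP.OUT.ATTRS = FALSE)
    pred <- predict(fit$fit, newdata = grid)
    tibble(
      pop_id = pops,
      trait = fit$trait,
      env = fit$envs,
      mean = as.numeric(tapply(pred, grid$pop_id, mean))
    )
  } else {
    grid <- expand.grid(pop_id = pops, env = levels(dat$env),
      block = levels(dat$block), KEEP.OUT.ATTRS = FALSE)
    pred <- predict(fit$fit, newdata = grid)
    tibble(
      pop_id = pops,
      trait = paste0(fit$trait, "_avg"),
      env = NA_character_,
      mean = as.numeric(tapply(pred, grid$pop_id, mean))
    )
  }
}

#' Broad-sense heritability indicator
#'
#' Evaluates the heritability indicator of population means from the ANOVA
#' variance components: `H2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / R)` for a
#' single environment, and
#' `H2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2 / J + sigma_e^2 / (J R))`
#' across `J` environments with `R` blocks each. Returns 0 when the genetic
#' component is 0.
#'
#' @param fit An `anova_fit`.
#' @return A number in `[0, 1]`.
#' @examples
#' # sigma_g2 = 1, sigma_e2 = 1, R = 3 -> 0.75 by the single-env formula
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "anova_fit"))
  if (fit$sigma_g2 <= 0) {
    return(0)
  }
  denom <- if (fit$model_id == 1L) {
    fit$sigma_g2 + fit$sigma_e2 / fit$R
  } else {
    fit$sigma_g2 + fit$sigma_ge2 / fit$J + fit$sigma_e2 / (fit$J * fit$R)
  }
  fit$sigma_g2 / denom
}

#' Pairwise Pearson correlations between trait means
#'
#' @param means Tibble of adjusted means: `pop_id`, `trait`, `mean`; traits
#'   are correlated on the populations they share. Pairs with fewer than 3
#'   common populations are flagged undefined (`NA`).
#' @return Long symmetric tibble: `trait_1`, `trait_2`, `r`, `n_common`;
#'   includes the unit diagonal.
#' @export
trait_correlations <- function(means) {
  stopifnot(all(c("pop_id", "trait", "mean") %in% names(means)))
  traits <- unique(means$trait)
  if (length(traits) < 2L) {
    stop_poolgp("Need at least 2 traits.", "poolgp_invalid_argument")
  }
  wide <- tidyr::pivot_wider(means[, c("pop_id", "trait", "mean")],
    names_from = "trait", values_from = "mean")
  tidyr::expand_grid(trait_1 = traits, trait_2 = traits) |>
    dplyr::mutate(purrr::map2_dfr(.data$trait_1, .data$trait_2, function(a, b) {
      x <- wide[[a]]
      y <- wide[[b]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L) {
        tibble(r = NA_real_, n_common = sum(ok))
      } else {
        tibble(r = cor(x[ok], y[ok]), n_common = sum(ok))
      }
    }))
}

#' @describeIn fit_model1 One row per ANOVA term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p_value`.
#' @param x,object An `anova_fit`.
#' @param ... Ignored.
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) {
  tab <- x$anova_table
  tibble(
    term = rownames(tab),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
}

#' @describeIn fit_model1 One-row summary: model id, trait, variance
#'   components, population F statistic and p-value, and the heritability
#'   indicator.
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  tibble(
    model_id = x$model_id,
    trait = x$trait,
    n_envs = x$J,
    n_blocks = x$R,
    sigma_g2 = x$sigma_g2,
    sigma_ge2 = x$sigma_ge2,
    sigma_e2 = x$sigma_e2,
    f_statistic = x$f_statistic,
    p_value = x$p_value,
    h2 = heritability(x)
  )
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf(
    "<anova_fit> model %d, trait '%s', %d env(s) x %d blocks; F_g = %.3f (p = %.3g), H2 = %.3f\n",
    x$model_id, x$trait, x$J, x$R, x$f_statistic, x$p_value, heritability(x)
  ))
  invisible(x)
}
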
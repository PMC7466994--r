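#' Read an allele-frequency matrix from TSV
#'
#' Canonical format: a header row of marker ids, a first column `pop_id`,
#' frequencies in `[0, 1]`, and `NA` or empty cells for missing calls. A
#' marker map TSV (`marker_id`, `scaffold`, `pos_bp`) can accompany the
#' matrix; without one, markers are placed on a single synthetic scaffold.
#' Malformed input (values outside `[0, 1]`, duplicate ids) is rejected with
#' the offending row and column named, never silently coerced.
#'
#' @param path Frequencies TSV.
#' @param map_path Optional marker-map TSV.
#' @return A [freq_matrix].
#' @export
read_frequencies <- function(path, map_path = NULL) {
  if (!file.exists(path)) {
    stop_poolgp(paste0("File not found: ", path), "poolgp_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    pop_id = readr::col_character(),
    .default = readr::col_character()
  ), na = character(), comment = "#", progress = FALSE)
  if (!"pop_id" %in% names(df)) {
    stop_poolgp("Frequencies TSV must have a `pop_id` first column.",
      "poolgp_format_error")
  }
  pops <- df$pop_id
  if (anyDuplicated(pops)) {
    stop_poolgp(sprintf("Duplicate population id '%s'.", pops[duplicated(pops)][1]),
      "poolgp_format_error")
  }
  markers <- setdiff(names(df), "pop_id")
  if (anyDuplicated(markers)) {
    stop_poolgp("Duplicate marker columns in frequencies TSV.", "poolgp_format_error")
  }
  values <- matrix(NA_real_, length(pops), length(markers),
    dimnames = list(pops, markers))
  for (j in seq_along(markers)) {
    raw <- df[[markers[j]]]
    missing_tok <- is.na(raw) | raw %in% c("", "NA")
    num <- suppressWarnings(as.numeric(raw))
    bad <- !missing_tok & (is.na(num) | num < 0 | num > 1)
    if (any(bad)) {
      i <- which(bad)[1]
      stop_poolgp(
        sprintf("Invalid frequency '%s' at population '%s', marker '%s'.",
          raw[i], pops[i], markers[j]),
        "poolgp_format_error"
      )
    }
    num[missing_tok] <- NA_real_
    values[, j] <- num
  }
  map <- if (!is.null(map_path)) read_marker_map(map_path) else NULL
  freq_matrix(values, map)
}

read_marker_map <- function(path) {
  if (!file.exists(path)) {
    stop_poolgp(paste0("File not found: ", path), "poolgp_io_error")
  }
  map <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    scaffold = readr::col_character(),
    pos_bp = readr::col_integer()
  ), comment = "#", progress = FALSE)
  if (anyDuplicated(map$marker_id)) {
    stop_poolgp("Duplicate marker_id in marker map.", "poolgp_format_error")
  }
  map
}

#' Write an allele-frequency matrix (and its map) to TSV
#'
#' @param freqs A [freq_matrix].
#' @param path Output TSV for the matrix.
#' @param map_path Optional output TSV for the marker map.
#' @param comment_lines Optional character vector written as leading
#'   `#`-comment lines (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freqs, path, map_path = NULL, comment_lines = NULL) {
  stopifnot(inherits(freqs, "freq_matrix"))
  df <- as_tibble(freqs$values, rownames = "pop_id")
  write_tsv_commented(df, path, comment_lines)
  if (!is.null(map_path)) {
    write_tsv_commented(freqs$map, map_path, comment_lines)
  }
  invisible(path)
}

write_tsv_commented <- function(df, path, comment_lines = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment_lines)) {
    writeLines(paste0("# ", comment_lines), con)
  }
  readr::write_tsv(df, con, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read plot-level phenotype records from TSV
#'
#' Long format with columns `pop_id`, `env`, `block`, `trait`, `value`; the
#' key `(pop_id, env, block, trait)` must be unique and values finite.
#'
#' @param path Phenotypes TSV.
#' @return A tibble of records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    stop_poolgp(paste0("File not found: ", path), "poolgp_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    pop_id = readr::col_character(),
    env = readr::col_character(),
    block = readr::col_character(),
    trait = readr::col_character(),
    value = readr::col_double()
  ), comment = "#", progress = FALSE)
  needed <- c("pop_id", "env", "block", "trait", "value")
  if (!all(needed %in% names(df))) {
    stop_poolgp("Phenotypes TSV must have columns pop_id, env, block, trait, value.",
      "poolgp_format_error")
  }
  key <- paste(df$pop_id, df$env, df$block, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop_poolgp(
      sprintf("Duplicate record for (%s, %s, %s, %s).",
        d$pop_id, d$env, d$block, d$trait),
      "poolgp_format_error"
    )
  }
  if (anyNA(df$value) || !all(is.finite(df$value))) {
    stop_poolgp("Phenotype values must be finite.", "poolgp_format_error")
  }
  df[, needed]
}

#' Write phenotype records to TSV
#' @param records Phenotype records tibble.
#' @param path Output TSV.
#' @param comment_lines Optional leading comment lines.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path, comment_lines = NULL) {
  write_tsv_commented(records, path, comment_lines)
}

#' Read / write a population panel (pop_id, lon, lat) TSV
#' @param path Panel TSV.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_poolgp(paste0("File not found: ", path), "poolgp_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    pop_id = readr::col_character(),
    lon = readr::col_double(),
    lat = readr::col_double(),
    .default = readr::col_guess()
  ), comment = "#", progress = FALSE)
  if (!"is_cultivar" %in% names(df)) df$is_cultivar <- FALSE
  check_panel(df)
  df
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @param comment_lines Optional leading comment lines.
#' @export
write_panel <- function(panel, path, comment_lines = NULL) {
  write_tsv_commented(panel, path, comment_lines)
}

#' Pipeline configuration with the analysis defaults
#'
#' Builds (or reads from YAML) the configuration driving [run_pipeline()].
#' Defaults mirror the analysis settings this package implements:
#' q-value threshold 0.10, 100 CV repeats with 50 held-out populations,
#' 500 Mantel permutations, 1000 CDmean exchange iterations, mixing
#' parameter 0.5, MAF > 0.05 in at least 10 populations. Unknown keys are
#' rejected; invalid values fail here, before any stage runs.
#'
#' @param ... Named overrides of defaults, or `yaml = path` to read a YAML
#'   file of overrides.
#' @param yaml Optional path to a YAML file of overrides.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  defaults <- list(
    frequencies = NULL,
    marker_map = NULL,
    panel = NULL,
    phenotypes = NULL,
    out_dir = NULL,
    seed = 1L,
    maf_min = 0.05,
    maf_min_pops = 10L,
    q_threshold = 0.10,
    cv_repeats = 100L,
    holdout = 50L,
    mantel_permutations = 500L,
    cdmean_iterations = 1000L,
    cdmean_lambda = 1,
    clustgeo_alpha = 0.5,
    calib_k = 30L,
    calib_n_random = 100L,
    gwas_model = "kinship",
    run_spatial = TRUE,
    run_gwas = TRUE,
    run_gp = TRUE,
    run_calibration = TRUE
  )
  overrides <- list(...)
  if (!is.null(yaml)) {
    overrides <- modifyList(yaml::read_yaml(yaml), overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_poolgp(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
      "poolgp_config_error")
  }
  cfg <- modifyList(defaults, overrides)
  assert_fraction(cfg$q_threshold, "q_threshold", lo_open = TRUE)
  assert_fraction(cfg$maf_min, "maf_min", hi = 0.5)
  assert_fraction(cfg$clustgeo_alpha, "clustgeo_alpha")
  assert_count(cfg$cv_repeats, "cv_repeats", 1L)
  assert_count(cfg$holdout, "holdout", 1L)
  assert_count(cfg$mantel_permutations, "mantel_permutations", 1L)
  assert_count(cfg$cdmean_iterations, "cdmean_iterations", 1L)
  assert_count(cfg$seed, "seed", 0L)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains the package stages in order — read, MAF filter, mean imputation,
#' kinship, adjusted means and heritabilities, spatial statistics, GWAS with
#' stepwise multi-marker models, genomic-prediction cross-validation, and
#' calibration-set optimization — writing each result as TSV into
#' `config$out_dir` plus a JSON run manifest. Every output file carries the
#' configuration hash as a leading comment line, and the manifest records
#' the resolved configuration and seed, so a re-run with the same
#' configuration is byte-identical. Any stage failure aborts with an error
#' naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("frequencies", "panel", "phenotypes", "out_dir")) {
    if (is.null(config[[key]])) {
      stop_poolgp(paste0("Config must set `", key, "`."), "poolgp_config_error")
    }
  }
  hash <- config_hash(config)
  note <- paste0("config_hash: ", hash)
  out <- function(name) file.path(config$out_dir, name)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_poolgp(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        "poolgp_stage_error")
    })
  }

  freqs <- stage("read", {
    read_frequencies(config$frequencies, config$marker_map)
  })
  panel <- stage("read", read_panel(config$panel))
  records <- stage("read", read_phenotypes(config$phenotypes))

  freqs <- stage("filter", filter_markers(freqs, config$maf_min, config$maf_min_pops))
  freqs <- stage("impute", impute_missing(freqs))
  stage("filter", {
    write_frequencies(freqs, out("filtered_frequencies.tsv"),
      out("filtered_marker_map.tsv"), note)
    written <- c(written, out("filtered_frequencies.tsv"), out("filtered_marker_map.tsv"))
  })

  G <- stage("kinship", kinship(freqs))
  stage("kinship", {
    write_tsv_commented(as_tibble(G$G, rownames = "pop_id"), out("kinship.tsv"), note)
    written <- c(written, out("kinship.tsv"))
  })

  means_h2 <- stage("means", pipeline_means(records))
  stage("means", {
    write_tsv_commented(means_h2$means, out("adjusted_means.tsv"), note)
    write_tsv_commented(means_h2$h2, out("heritability.tsv"), note)
    written <- c(written, out("adjusted_means.tsv"), out("heritability.tsv"))
  })
  traits_for_gp <- unique(means_h2$primary$trait)

  if (isTRUE(config$run_spatial)) {
    stage("spatial", {
      sp <- spatial_summary(means_h2$primary, panel[panel$pop_id %in% pop_ids(freqs), ],
        freqs, config$mantel_permutations, config$seed)
      write_tsv_commented(sp$moran, out("moran.tsv"), note)
      write_tsv_commented(sp$mantel, out("mantel.tsv"), note)
      written <- c(written, out("moran.tsv"), out("mantel.tsv"))
    })
  }

  if (isTRUE(config$run_gwas)) {
    stage("gwas", {
      for (tr in traits_for_gp) {
        m <- means_h2$primary[means_h2$primary$trait == tr, ]
        yv <- setNames(m$mean, m$pop_id)[pop_ids(freqs)]
        scan <- run_gwas(yv, freqs, model = config$gwas_model, G = G)
        write_tsv_commented(as_tibble(scan), out(paste0("gwas_", tr, ".tsv")), note)
        written <- c(written, out(paste0("gwas_", tr, ".tsv")))
        hits <- significant(scan, config$q_threshold)
        if (length(hits)) {
          sw <- stepwise_model(yv, hits, freqs)
          write_tsv_commented(tidy(sw), out(paste0("stepwise_", tr, ".tsv")), note)
          written <- c(written, out(paste0("stepwise_", tr, ".tsv")))
        }
      }
    })
  }

  if (isTRUE(config$run_gp)) {
    stage("gp-cv", {
      cv_tab <- purrr::map_dfr(traits_for_gp, function(tr) {
        m <- means_h2$primary[means_h2$primary$trait == tr, ]
        yv <- setNames(m$mean, m$pop_id)[pop_ids(freqs)]
        cv <- cross_validate(freqs, yv, config$cv_repeats, config$holdout, config$seed)
        dplyr::mutate(glance(cv), trait = tr, .before = 1)
      })
      write_tsv_commented(cv_tab, out("gp_cv.tsv"), note)
      written <- c(written, out("gp_cv.tsv"))
    })
  }

  if (isTRUE(config$run_calibration)) {
    stage("calib", {
      D_gen <- euclidean_distances(freqs)
      calib_tab <- purrr::map_dfr(traits_for_gp, function(tr) {
        m <- means_h2$primary[means_h2$primary$trait == tr, ]
        yv <- setNames(m$mean, m$pop_id)[pop_ids(freqs)]
        set <- select_by_clustering(D_gen, config$calib_k)
        dplyr::mutate(
          as_tibble(evaluate_calibration(freqs, yv, set,
            config$calib_n_random, config$seed)),
          trait = tr, .before = 1)
      })
      write_tsv_commented(calib_tab, out("calibration.tsv"), note)
      written <- c(written, out("calibration.tsv"))
    })
  }

  manifest <- list(
    config_hash = hash,
    config = unclass(config),
    seed = config$seed,
    n_populations = nrow(freqs$values),
    n_markers = ncol(freqs$values),
    traits = traits_for_gp,
    files = basename(unique(written))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, out("manifest.json"))
  invisible(unique(written))
}

# Adjusted means and heritabilities for every trait: model 1 per
# environment, model 2 across environments when a trait has >= 2.
# `primary` holds the per-trait means used downstream (the _avg means when
# available, otherwise the single environment's).
pipeline_means <- function(records) {
  combos <- unique(records[, c("trait", "env")])
  means <- list()
  h2 <- list()
  primary <- list()
  for (tr in unique(records$trait)) {
    envs <- combos$env[combos$trait == tr]
    for (ev in envs) {
      fit <- fit_model1(records, tr, ev)
      means[[paste(tr, ev)]] <- adjusted_means(fit)
      h2[[paste(tr, ev)]] <- glance(fit)
    }
    if (length(envs) >= 2L) {
      fit2 <- fit_model2(records, tr)
      am <- adjusted_means(fit2)
      means[[paste0(tr, "_avg")]] <- am
      h2[[paste0(tr, "_avg")]] <- glance(fit2)
      primary[[tr]] <- dplyr::transmute(am, .data$pop_id, trait = tr, mean = .data$mean)
    } else {
      am <- means[[paste(tr, envs[1])]]
      primary[[tr]] <- dplyr::transmute(am, .data$pop_id, trait = tr, mean = .data$mean)
    }
  }
  list(
    means = dplyr::bind_rows(means),
    h2 = dplyr::bind_rows(h2),
    primary = dplyr::bind_rows(primary)
  )
}

#' Write simulation truth to JSON
#' @param truth A `sim_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}
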
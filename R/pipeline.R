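#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of a full scaling
#' analysis: input paths or in-memory objects, analysis switches, MCMC
#' settings, peak-detection mode and seed. May also be loaded from a YAML
#' file with [read_pipeline_config()].
#'
#' @param dataset path to the long-format dataset CSV, or a list of
#'   [intake_pattern] objects.
#' @param tree path to a Newick file, or an `ape::phylo`.
#' @param out_dir output directory, or `NULL` for no files.
#' @param characteristics which raw characteristics to regress.
#' @param run_raw,run_model_derived analysis switches: regressions on raw
#'   measurements and on Von Bertalanffy model estimates.
#' @param run_species_average one-point-per-species variant.
#' @param run_onset_mass mass-at-lactation-onset variant.
#' @param run_shape_covariate shape-as-covariate variant (see
#'   [shape_covariate_run()]).
#' @param run_ratio peak/initial ratio analysis.
#' @param apply_exclusions drop non-converged and abnormal fits from the
#'   model-derived regressions (logged).
#' @param robust_peak robust peak detection ([peak_rate_and_time()]).
#' @param n_iter,burn_in,thin MCMC settings (see [fit_phylo_mcmc()]).
#' @param seed integer seed; makes the whole run reproducible.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset, tree, out_dir = NULL,
                            characteristics = c("average_rate",
                                                "initial_rate", "peak_rate",
                                                "amplitude", "time_to_peak",
                                                "cumulative_elevation_to_peak"),
                            run_raw = TRUE, run_model_derived = TRUE,
                            run_species_average = FALSE,
                            run_onset_mass = FALSE,
                            run_shape_covariate = FALSE,
                            run_ratio = FALSE,
                            apply_exclusions = TRUE,
                            robust_peak = FALSE,
                            n_iter = 60000, burn_in = 10000, thin = 25,
                            seed = 1) {
  cfg <- as.list(environment())
  if (is.character(cfg$dataset) && !file.exists(cfg$dataset)) {
    stop("dataset file not found: ", cfg$dataset, call. = FALSE)
  }
  if (is.character(cfg$tree) && !file.exists(cfg$tree)) {
    stop("tree file not found: ", cfg$tree, call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configs", call. = FALSE)
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

summarize_fit_row <- function(fit, characteristic, phylo) {
  co <- fit$coefficients
  ci <- fit$interval_95
  p <- fit$p_values
  stars <- vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
  data.frame(
    characteristic = characteristic,
    phylogeny = if (phylo) "yes" else "no",
    intercept = co[["intercept"]],
    intercept_lo = ci["intercept", 1], intercept_hi = ci["intercept", 2],
    intercept_sig = stars[["intercept"]],
    b1 = co[["b1"]], b1_lo = ci["b1", 1], b1_hi = ci["b1", 2],
    b1_sig = stars[["b1"]],
    b2 = co[["b2"]], b2_lo = ci["b2", 1], b2_hi = ci["b2", 2],
    b2_sig = stars[["b2"]],
    diet_coef = co[["diet_coef"]],
    diet_lo = ci["diet_coef", 1], diet_hi = ci["diet_coef", 2],
    diet_sig = stars[["diet_coef"]],
    r2 = fit$marginal_r2,
    lambda = fit$lambda,
    stringsAsFactors = FALSE)
}

run_scaling_pair <- function(tab, characteristic, tree, cfg, mass_column) {
  data <- build_design(tab, characteristic, mass_column = mass_column)
  phylo_fit <- fit_phylo_mcmc(data, tree, n_iter = cfg$n_iter,
                              burn_in = cfg$burn_in, thin = cfg$thin)
  reml_fit <- fit_lmm(data)
  list(phylo = phylo_fit, reml = reml_fit,
       table = rbind(summarize_fit_row(phylo_fit, characteristic, TRUE),
                     summarize_fit_row(reml_fit, characteristic, FALSE)))
}

#' Run the full scaling analysis
#'
#' End-to-end pipeline: (1) extract the raw characteristics of every
#' pattern; (2) fit the generalized Von Bertalanffy model per pattern,
#' derive model-based characteristics and apply convergence and
#' abnormal-fit exclusions (logged by pattern id); (3) fit the scaling
#' regressions — phylogenetic MCMC and non-phylogenetic REML side by side
#' — for the raw characteristics and the model-derived ones; (4) optional
#' variants: species-averaged, onset-mass, shape covariate, peak/initial
#' ratio; (5) write a summary table (TSV), per-pattern fits (TSV), an
#' exclusion log and a machine-readable JSON of all estimates when
#' `out_dir` is set.
#'
#' The run is a deterministic function of (config, seed): identical
#' configurations give byte-identical JSON reports.
#'
#' @param config a [pipeline_config()].
#' @return list with `characteristics`, `vb_fits`, `excluded`,
#'   `scaling` (named list of `scaling_fit` pairs), `variants`,
#'   `summary_table`, and `files` (paths written, if any).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  patterns <- if (is.character(cfg$dataset)) read_dataset(cfg$dataset) else
    cfg$dataset
  tree <- if (is.character(cfg$tree)) read_newick(cfg$tree) else cfg$tree
  if (length(patterns) == 0) stop("pipeline: empty dataset", call. = FALSE)

  ## stage 1: raw characteristics
  tab <- tryCatch(characteristics_table(patterns, robust_peak = cfg$robust_peak),
                  error = function(e) stop("pipeline[features]: ",
                                           conditionMessage(e), call. = FALSE))

  ## stage 2: Von Bertalanffy fits + screening
  fits <- tryCatch(vb_fit_table(patterns),
                   error = function(e) stop("pipeline[vb_growth]: ",
                                            conditionMessage(e), call. = FALSE))
  excluded <- fits[!fits$converged | fits$abnormal,
                   c("pattern_id", "converged", "abnormal", "abnormal_reason")]
  excluded$reason <- ifelse(!excluded$converged, "fit did not converge",
                            excluded$abnormal_reason)
  if (nrow(excluded)) {
    message("excluding ", nrow(excluded), " pattern(s): ",
            paste(excluded$pattern_id, collapse = ", "))
  }

  # model-derived characteristics table (same covariates, VB estimates)
  keep <- if (cfg$apply_exclusions) fits$converged & !fits$abnormal else
    fits$converged
  m <- match(fits$pattern_id, tab$pattern_id)
  derived_tab <- data.frame(
    pattern_id = fits$pattern_id,
    species = tab$species[m], breed = tab$breed[m],
    diet_me_density = tab$diet_me_density[m],
    mass_peak_kg = tab$mass_peak_kg[m],
    mass_onset_kg = tab$mass_onset_kg[m],
    time_to_peak = fits$time_to_peak,
    amplitude = fits$amplitude,
    cumulative_elevation_to_peak = fits$cumulative_to_peak,
    shape = fits$shape,
    stringsAsFactors = FALSE)[keep, ]

  ## stage 3: scaling regressions
  scaling <- list()
  summary_rows <- list()
  if (cfg$run_raw) {
    for (ch in cfg$characteristics) {
      res <- tryCatch(run_scaling_pair(tab, ch, tree, cfg, "peak"),
                      error = function(e) stop("pipeline[allometry:raw:", ch,
                                               "]: ", conditionMessage(e),
                                               call. = FALSE))
      scaling[[paste0("raw_", ch)]] <- res[c("phylo", "reml")]
      summary_rows[[paste0("raw_", ch)]] <- res$table
    }
  }
  if (cfg$run_model_derived) {
    for (ch in intersect(c("time_to_peak", "amplitude",
                           "cumulative_elevation_to_peak"),
                         names(derived_tab))) {
      res <- tryCatch(run_scaling_pair(derived_tab, ch, tree, cfg, "peak"),
                      error = function(e) stop("pipeline[allometry:derived:",
                                               ch, "]: ", conditionMessage(e),
                                               call. = FALSE))
      scaling[[paste0("derived_", ch)]] <- res[c("phylo", "reml")]
      row <- res$table
      row$characteristic <- paste0("model-derived ", row$characteristic)
      summary_rows[[paste0("derived_", ch)]] <- row
    }
  }

  ## stage 4: variants
  variants <- list()
  if (cfg$run_species_average) {
    data <- build_design(tab, "peak_rate")
    variants$species_average <-
      species_average_analysis(data, tree, n_iter = cfg$n_iter,
                               burn_in = cfg$burn_in, thin = cfg$thin)
  }
  if (cfg$run_onset_mass) {
    data <- build_design(tab, "peak_rate", mass_column = "onset")
    variants$onset_mass <- fit_phylo_mcmc(data, tree, n_iter = cfg$n_iter,
                                          burn_in = cfg$burn_in,
                                          thin = cfg$thin)
  }
  if (cfg$run_shape_covariate) {
    variants$shape_covariate <- shape_covariate_fit(derived_tab, tree, cfg)
  }
  if (cfg$run_ratio) {
    variants$ratio_peak_initial <-
      ratio_scaling(tab, "peak_rate", "initial_rate", tree = tree,
                    n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                    thin = cfg$thin)
  }

  summary_table <- if (length(summary_rows)) {
    do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  } else NULL

  ## stage 5: outputs
  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    f_sum <- file.path(cfg$out_dir, "scaling_summary.tsv")
    f_fit <- file.path(cfg$out_dir, "vb_fits.tsv")
    f_chr <- file.path(cfg$out_dir, "characteristics.tsv")
    f_exc <- file.path(cfg$out_dir, "excluded_patterns.tsv")
    f_json <- file.path(cfg$out_dir, "estimates.json")
    write.table(summary_table, f_sum, sep = "\t", row.names = FALSE,
                quote = FALSE)
    write.table(fits, f_fit, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(tab, f_chr, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(excluded, f_exc, sep = "\t", row.names = FALSE, quote = FALSE)
    est <- lapply(scaling, function(pair) {
      lapply(pair, function(f) {
        list(coefficients = as.list(f$coefficients),
             interval_95 = apply(f$interval_95, 1, as.list),
             p_values = as.list(f$p_values),
             variance_components = as.list(f$variance_components),
             lambda = f$lambda, marginal_r2 = f$marginal_r2)
      })
    })
    jsonlite::write_json(est, f_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(summary = f_sum, vb_fits = f_fit, characteristics = f_chr,
               excluded = f_exc, json = f_json)
  }

  list(characteristics = tab, vb_fits = fits, excluded = excluded,
       derived_characteristics = derived_tab,
       scaling = scaling, variants = variants,
       summary_table = summary_table, files = files)
}

shape_covariate_fit <- function(derived_tab, tree, cfg) {
  data <- build_design(derived_tab, "cumulative_elevation_to_peak")
  m <- match(data$pattern_id, derived_tab$pattern_id)
  data$shape <- derived_tab$shape[m]
  if (sd(data$shape) < 1e-12) {
    message("shape is constant across patterns; covariate dropped")
    return(fit_phylo_mcmc(data, tree, n_iter = cfg$n_iter,
                          burn_in = cfg$burn_in, thin = cfg$thin))
  }
  fit_phylo_mcmc_shape(data, tree, cfg)
}

# cumulative-to-peak regression augmented with the shape statistic
fit_phylo_mcmc_shape <- function(data, tree, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1)
  pm <- prune_and_match(tree, data$species)
  data <- data[data$species %in% pm$matched, , drop = FALSE]
  V <- vcv_matrix(pm$tree)
  sp <- colnames(V)
  X <- cbind(1, data$x, data$x2, data$d, data$shape)
  colnames(X) <- c("intercept", "b1", "b2", "diet_coef", "shape_coef")
  Za <- outer(data$species, sp, "==") * 1
  breeds <- unique(data$breed[nzchar(data$breed) & data$breed != "none"])
  Zb <- if (length(breeds) > 1) outer(data$breed, breeds, "==") * 1 else
    matrix(0, nrow(data), 0)
  run_gibbs_lmm(data$y, X, Za, Zb, V, cfg$n_iter, cfg$burn_in, cfg$thin,
                species = sp,
                method = "phylogenetic animal model + shape covariate")
}

#' Shape-covariate scaling run
#'
#' Regression of the model-derived cumulative elevation to peak augmented
#' with the Von Bertalanffy shape statistic as a fixed covariate: a
#' positive coefficient means that, at a given mass and diet, mothers
#' that decelerate their intake later (larger shape) accumulate more
#' energy to the peak.
#'
#' @param config a [pipeline_config()] (model-derived analysis must be
#'   runnable).
#' @return `scaling_fit` with the extra `shape_coef` coefficient.
#' @export
shape_covariate_run <- function(config) {
  config$run_raw <- FALSE
  config$run_model_derived <- FALSE
  config$run_shape_covariate <- TRUE
  config$run_species_average <- FALSE
  config$run_onset_mass <- FALSE
  config$run_ratio <- FALSE
  res <- run_pipeline(config)
  res$variants$shape_covariate
}
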
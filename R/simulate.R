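#' Configuration for the synthetic lactation-intake generator
#'
#' Defaults emulate the statistical structure of a compiled comparative
#' dataset of mammalian lactation intake patterns: 24 species spanning
#' 0.01-600 kg with heterogeneous replication (a few heavily studied
#' species contribute most patterns), daily sampling in small species and
#' weekly sampling in large ones, curvilinear log-log scaling of the rate
#' characteristics with a diet energy-density effect, phylogenetically
#' structured species effects, breed-within-species effects and sigmoid
#' intake-elevation trajectories.
#'
#' The primary scaling law generates the log10 peak rate:
#' `log10(peak) = intercept + diet_coef*d + (b1 + b2*log10 M)*log10 M`
#' plus species, breed and residual effects. The initial rate follows the
#' same law shifted down by `log10(ratio_peak_initial)` (mothers increase
#' intake ~1.9-fold to the peak, independent of mass) with its own
#' residual; the amplitude is their difference. The time to peak has its
#' own law (`ttp_*`). Default coefficients are phylogeny-controlled
#' estimates typical of such data: peak rate (-0.233, 0.667, 0.050,
#' 0.024) and time to peak (1.266, 0.078, 0.036, -0.001).
#'
#' @param n_species number of species (>= 2).
#' @param n_patterns total number of patterns across species.
#' @param n_heavy_species number of species that absorb all replication
#'   beyond one pattern each (heavy-tailed design).
#' @param mass_range_kg (min, max) species body mass, kg; sampled
#'   log-uniformly.
#' @param true_intercept,true_b1,true_b2,true_diet_coef coefficients of
#'   the peak-rate scaling law (log10 MJ/day scale; diet effect per
#'   MJ/kg DM).
#' @param ratio_peak_initial mass-independent peak/initial fold change.
#' @param ttp_intercept,ttp_b1,ttp_b2,ttp_diet_coef coefficients of the
#'   time-to-peak law (log10 days scale).
#' @param diet_density_range (min, max) diet ME density, MJ/kg DM.
#' @param sigma_phylo,sigma_breed,sigma_resid SDs of the phylogenetic
#'   species effect, breed-within-species effect and pattern residual, all
#'   on the log10 scale.
#' @param lambda_true Pagel lambda of the species-effect covariance,
#'   in \[0, 1\].
#' @param c_meanlog,c_sdlog lognormal parameters of `c - 1`, so the drawn
#'   Von Bertalanffy exponent always exceeds 1 (defaults give median
#'   c = 2.5, i.e. a mean shape statistic near 0.66).
#' @param obs_noise_cv coefficient of variation of the multiplicative
#'   lognormal observation noise on daily intake.
#' @param weekly_mass_threshold_kg species at or above this mass are
#'   sampled weekly (weekly mean rate tagged at the interval midpoint);
#'   lighter species daily.
#' @param followup_factor length of the emitted series as a multiple of
#'   the generating time to peak (must exceed 1 so the peak is observable).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 24,
                       n_patterns = 52,
                       n_heavy_species = 5,
                       mass_range_kg = c(0.01, 600),
                       true_intercept = -0.233,
                       true_b1 = 0.667,
                       true_b2 = 0.050,
                       true_diet_coef = 0.024,
                       ratio_peak_initial = 1.9,
                       ttp_intercept = 1.266,
                       ttp_b1 = 0.078,
                       ttp_b2 = 0.036,
                       ttp_diet_coef = -0.001,
                       diet_density_range = c(8, 14),
                       sigma_phylo = 0.08,
                       sigma_breed = 0.035,
                       sigma_resid = 0.045,
                       lambda_true = 0.65,
                       c_meanlog = log(1.5),
                       c_sdlog = 0.45,
                       obs_noise_cv = 0.05,
                       weekly_mass_threshold_kg = 10,
                       followup_factor = 1.6) {
  cfg <- as.list(environment())
  if (cfg$n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (cfg$n_patterns < cfg$n_species) {
    stop("n_patterns must be >= n_species (each species contributes >= 1)",
         call. = FALSE)
  }
  if (any(cfg$mass_range_kg <= 0) || diff(cfg$mass_range_kg) < 0) {
    stop("mass_range_kg must be positive and increasing", call. = FALSE)
  }
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1) {
    stop("lambda_true must be in [0, 1]", call. = FALSE)
  }
  if (cfg$sigma_phylo < 0 || cfg$sigma_breed < 0 || cfg$sigma_resid < 0) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (cfg$ratio_peak_initial <= 1) {
    stop("ratio_peak_initial must exceed 1", call. = FALSE)
  }
  if (cfg$obs_noise_cv < 0) stop("obs_noise_cv must be >= 0", call. = FALSE)
  if (cfg$followup_factor <= 1) {
    stop("followup_factor must exceed 1 so the peak is observable",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric pure-birth species tree
#'
#' Tree from a pure-birth (Yule) process, rescaled to unit root-to-tip
#' height, with tip labels `sp_001`, `sp_002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param seed optional integer seed.
#' @return an `ape::phylo`.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp_%03d", seq_len(n_species))
  tr
}

#' Simulate phylogenetically structured species effects
#'
#' One draw from a zero-mean multivariate normal with covariance
#' `sigma_phylo^2 * V_lambda`, where `V_lambda` is the tree covariance
#' with off-diagonals multiplied by `lambda_true` (see
#' [lambda_transform()]). The marginal variance of every species effect is
#' `sigma_phylo^2` regardless of `lambda_true`.
#'
#' @param tree an `ape::phylo`.
#' @param sigma_phylo SD of the species effect (log10 scale); >= 0.
#' @param lambda_true in \[0, 1\].
#' @param seed optional integer seed.
#' @return named numeric vector, one effect per tip.
#' @export
simulate_species_effects <- function(tree, sigma_phylo, lambda_true = 1,
                                     seed = NULL) {
  if (sigma_phylo < 0) stop("sigma_phylo must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  if (sigma_phylo == 0) {
    return(setNames(rep(0, n), tree$tip.label))
  }
  V <- lambda_transform(vcv_matrix(tree), lambda_true)
  L <- t(chol(V + diag(1e-10, n)))
  eff <- sigma_phylo * as.vector(L %*% rnorm(n))
  setNames(eff, colnames(V))
}

# evaluate a log10-scale scaling law at log10-mass x and diet density d
scaling_law <- function(intercept, b1, b2, diet_coef, x, d) {
  intercept + diet_coef * d + (b1 + b2 * x) * x
}

#' Simulate one lactation intake pattern
#'
#' Draws the target characteristics (peak rate, initial rate, time to
#' peak) from the configured scaling laws with the supplied species/breed
#' effects and per-characteristic residual noise, then builds a
#' generalized Von Bertalanffy trajectory that reproduces those targets
#' exactly before observation noise: `c` from the configured lognormal,
#' `k = log(c) / time_to_peak`, `A = amplitude / (k * (1-1/c)^(c-1))`.
#' The emitted MEI series is `initial_rate + vb_rate(...)` on a daily or
#' weekly grid (weekly series carry the interval mean rate tagged at the
#' interval midpoint), multiplied by lognormal observation noise, and
#' extends `followup_factor` times past the peak.
#'
#' @param species_ctx list with `species`, `breed`, `mass_kg`,
#'   `diet_me_density`, `species_effect`, `breed_effect` (log10 scale).
#' @param config a [sim_config()].
#' @param pattern_id identifier for the emitted pattern.
#' @param max_retries resampling attempts when a drawn characteristic is
#'   non-positive or the initial rate exceeds the peak.
#' @return an [intake_pattern] with attribute `truth`: the generating
#'   characteristics and Von Bertalanffy parameters.
#' @export
simulate_pattern <- function(species_ctx, config, pattern_id = "p1",
                             max_retries = 50) {
  cfg <- config
  x <- log10(species_ctx$mass_kg)
  d <- species_ctx$diet_me_density
  re <- species_ctx$species_effect + species_ctx$breed_effect

  for (try in seq_len(max_retries)) {
    log_peak <- scaling_law(cfg$true_intercept, cfg$true_b1, cfg$true_b2,
                            cfg$true_diet_coef, x, d) +
      re + rnorm(1, 0, cfg$sigma_resid)
    log_init <- scaling_law(cfg$true_intercept, cfg$true_b1, cfg$true_b2,
                            cfg$true_diet_coef, x, d) -
      log10(cfg$ratio_peak_initial) + re + rnorm(1, 0, cfg$sigma_resid)
    log_ttp <- scaling_law(cfg$ttp_intercept, cfg$ttp_b1, cfg$ttp_b2,
                           cfg$ttp_diet_coef, x, d) +
      re + rnorm(1, 0, cfg$sigma_resid)
    peak <- 10^log_peak
    init <- 10^log_init
    ttp <- 10^log_ttp
    if (is.finite(peak) && is.finite(init) && is.finite(ttp) &&
        peak > init && ttp > 2) break
    if (try == max_retries) {
      stop("failed to draw positive characteristics after ", max_retries,
           " attempts", call. = FALSE)
    }
  }
  amplitude <- peak - init
  cc <- 1 + rlnorm(1, cfg$c_meanlog, cfg$c_sdlog)
  k <- log(cc) / ttp
  A <- amplitude / (k * (1 - 1 / cc)^(cc - 1))

  weekly <- species_ctx$mass_kg >= cfg$weekly_mass_threshold_kg
  horizon <- cfg$followup_factor * ttp
  if (weekly) {
    n_int <- max(3, ceiling(horizon / 7))
    bounds <- 7 * (0:n_int)
    # weekly mean extra rate = increment of the cumulative curve / 7
    extra <- diff(vb_cumulative(A, k, cc, bounds)) / 7
    times <- bounds[-1] - 3.5
  } else {
    times <- seq(1, max(3, ceiling(horizon)))
    extra <- vb_rate(A, k, cc, times)
  }
  mei <- init + extra
  if (cfg$obs_noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$obs_noise_cv^2))
    mei <- mei * rlnorm(length(mei), -sdlog^2 / 2, sdlog)
  }

  pat <- intake_pattern(
    pattern_id = pattern_id,
    species = species_ctx$species,
    breed = species_ctx$breed,
    times = times, mei = mei,
    diet_me_density = d,
    mass_peak_kg = species_ctx$mass_kg,
    mass_onset_kg = species_ctx$mass_onset_kg %||% species_ctx$mass_kg)
  attr(pat, "truth") <- list(initial_rate = init, peak_rate = peak,
                             amplitude = amplitude, time_to_peak = ttp,
                             A = A, k = k, c = cc,
                             shape = (1 - 1 / cc) / log(cc),
                             cumulative_to_peak = A * (1 - 1 / cc)^cc,
                             weekly = weekly)
  pat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generating ("true") characteristics of simulated patterns
#'
#' Returns the characteristics each simulated pattern was built to have
#' (before sampling-grid discretization and observation noise), together
#' with its covariates — the exact data-generating values behind the
#' scaling laws, for parameter-recovery studies.
#'
#' @param patterns list of patterns from [simulate_dataset()] or
#'   [simulate_pattern()].
#' @return data frame with pattern_id, species, breed, covariates and
#'   the generating initial/peak rate, amplitude, time to peak, shape and
#'   cumulative elevation to peak.
#' @export
true_characteristics_table <- function(patterns) {
  rows <- lapply(patterns, function(p) {
    tr <- attr(p, "truth")
    if (is.null(tr)) stop("pattern `", p$pattern_id,
                          "` carries no generating truth", call. = FALSE)
    data.frame(pattern_id = p$pattern_id, species = p$species,
               breed = p$breed, diet_me_density = p$diet_me_density,
               mass_peak_kg = p$mass_peak_kg,
               mass_onset_kg = p$mass_onset_kg,
               initial_rate = tr$initial_rate, peak_rate = tr$peak_rate,
               amplitude = tr$amplitude, time_to_peak = tr$time_to_peak,
               shape = tr$shape,
               cumulative_elevation_to_peak = tr$cumulative_to_peak,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full comparative dataset
#'
#' Builds a pure-birth tree, draws species masses log-uniformly over the
#' configured range and diet densities uniformly, assigns replication with
#' a heavy tail (every species contributes one pattern; the surplus is
#' split among `n_heavy_species` randomly chosen species, which also get
#' breed labels), draws phylogenetic species effects and breed effects,
#' and emits one [intake_pattern] per pattern.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of (config, seed).
#' @return list with `patterns` (list of [intake_pattern]), `tree`
#'   (`ape::phylo`), `species` (data frame of species-level truths) and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  cfg <- config
  set.seed(seed)
  tree <- simulate_tree(cfg$n_species)
  sp <- tree$tip.label
  mass <- 10^runif(cfg$n_species, log10(cfg$mass_range_kg[1]),
                   log10(cfg$mass_range_kg[2]))
  sp_eff <- simulate_species_effects(tree, cfg$sigma_phylo, cfg$lambda_true)

  n_rep <- rep(1L, cfg$n_species)
  extra <- cfg$n_patterns - cfg$n_species
  heavy <- sample(cfg$n_species, min(cfg$n_heavy_species, cfg$n_species))
  if (extra > 0) {
    add <- tabulate(sample(heavy, extra, replace = TRUE), nbins = cfg$n_species)
    n_rep <- n_rep + add
  }

  patterns <- list()
  pid <- 0
  for (i in seq_len(cfg$n_species)) {
    n_breeds <- if (n_rep[i] > 1) min(n_rep[i], sample(2:3, 1)) else 1
    breed_labels <- if (n_breeds > 1) {
      paste0(sp[i], "_br", seq_len(n_breeds))
    } else ""
    breed_eff <- rnorm(n_breeds, 0, cfg$sigma_breed)
    for (j in seq_len(n_rep[i])) {
      pid <- pid + 1
      b <- ((j - 1) %% n_breeds) + 1
      mass_j <- mass[i] * 10^rnorm(1, 0, 0.02)
      ctx <- list(species = sp[i],
                  breed = breed_labels[b],
                  mass_kg = mass_j,
                  mass_onset_kg = mass_j * 10^rnorm(1, 0.02, 0.015),
                  diet_me_density = runif(1, cfg$diet_density_range[1],
                                          cfg$diet_density_range[2]),
                  species_effect = sp_eff[[sp[i]]],
                  breed_effect = breed_eff[b])
      patterns[[pid]] <- simulate_pattern(ctx, cfg,
                                          pattern_id = sprintf("pat_%03d", pid))
    }
  }
  species_df <- data.frame(species = sp, mass_kg = mass,
                           species_effect = unname(sp_eff),
                           n_patterns = n_rep, stringsAsFactors = FALSE)
  list(patterns = patterns, tree = tree, species = species_df, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Long-format CSV (one row per measurement: pattern_id, species, breed,
#' day, mei_mj_per_day, diet_me_mj_per_kg_dm, mass_peak_kg, mass_onset_kg)
#' plus a Newick tree whose tip labels match the `species` column.
#'
#' @param patterns list of [intake_pattern] objects (non-empty).
#' @param tree an `ape::phylo`.
#' @param out_dir directory (created if needed).
#' @return named character vector of the written file paths.
#' @export
write_dataset <- function(patterns, tree, out_dir) {
  if (length(patterns) == 0) stop("no patterns to write", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(patterns, function(p) {
    data.frame(pattern_id = p$pattern_id, species = p$species,
               breed = p$breed, day = p$times, mei_mj_per_day = p$mei,
               diet_me_mj_per_kg_dm = p$diet_me_density,
               mass_peak_kg = p$mass_peak_kg,
               mass_onset_kg = p$mass_onset_kg,
               stringsAsFactors = FALSE)
  })
  csv <- file.path(out_dir, "patterns.csv")
  nwk <- file.path(out_dir, "tree.nwk")
  write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  write_newick(tree, nwk)
  c(csv = csv, newick = nwk)
}

#' Read a long-format intake dataset
#'
#' Inverse of [write_dataset()]. If a tree is supplied (path or `phylo`),
#' species absent from it are reported in the `unmatched_species`
#' attribute with a warning, so callers can exclude them from
#' phylogenetic analyses.
#'
#' @param csv_path path to the long-format CSV.
#' @param tree optional Newick path or `ape::phylo` for name checking.
#' @return list of [intake_pattern] objects, attribute
#'   `unmatched_species`.
#' @export
read_dataset <- function(csv_path, tree = NULL) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("pattern_id", "species", "breed", "day", "mei_mj_per_day",
            "diet_me_mj_per_kg_dm", "mass_peak_kg", "mass_onset_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dataset CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$breed[is.na(df$breed)] <- ""
  patterns <- lapply(split(df, df$pattern_id), function(g) {
    g <- g[order(g$day), ]
    intake_pattern(g$pattern_id[1], g$species[1], g$breed[1],
                   g$day, g$mei_mj_per_day, g$diet_me_mj_per_kg_dm[1],
                   g$mass_peak_kg[1], g$mass_onset_kg[1])
  })
  # preserve input order of first appearance
  patterns <- patterns[unique(df$pattern_id)]
  unmatched <- character(0)
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- read_newick(tree)
    key <- normalize_species(tree$tip.label)
    sp <- unique(df$species)
    unmatched <- sp[!(normalize_species(sp) %in% key)]
    if (length(unmatched)) {
      warning("species in dataset but not on tree: ",
              paste(unmatched, collapse = ", "))
    }
  }
  attr(patterns, "unmatched_species") <- unmatched
  patterns
}
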
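test_that("the design table logs masses in kg and drops non-positive rows", {
  tab <- data.frame(pattern_id = c("a", "b", "c"),
                    species = "sp", breed = "",
                    peak_rate = c(10, 0, 2),
                    diet_me_density = 11,
                    mass_peak_kg = c(1, 2, 0.05),
                    mass_onset_kg = c(1.2, 2.2, 0.06))
  expect_message(d <- build_design(tab, "peak_rate"), "dropped")
  expect_equal(nrow(d), 2)
  expect_equal(d$x[1], 0)   # 1 kg -> log10 mass 0
  expect_equal(d$x2[1], 0)
  expect_equal(d$y[2], log10(2))

  d2 <- suppressMessages(build_design(tab, "peak_rate", mass_column = "onset"))
  expect_equal(d2$x[1], log10(1.2))
  expect_error(build_design(tab, "nope"), "no column")
})

test_that("local exponents follow b1 + b2*log10(mass)", {
  expect_equal(round(local_exponent(0.67, 0.050, 0.05), 2), 0.60)
  expect_equal(round(local_exponent(0.73, 0.092, 500), 2), 0.98)
  expect_equal(local_exponent(0.75, 0, c(0.01, 1, 1000)), rep(0.75, 3))
  expect_error(local_exponent(0.7, 0.05, -1), "> 0")
})

test_that("REML recovers exact coefficients on noiseless data and ignores row order", {
  cfg <- sim_config(obs_noise_cv = 0, sigma_phylo = 0, sigma_breed = 0,
                    sigma_resid = 0)
  sim <- simulate_dataset(cfg, seed = 6)
  d <- truth_design(sim)
  f <- suppressWarnings(fit_lmm(d))
  expect_equal(unname(f$coefficients),
               c(-0.233, 0.667, 0.050, 0.024), tolerance = 1e-6)
  expect_lt(f$variance_components[["resid"]], 1e-10)
  expect_equal(f$marginal_r2, 1, tolerance = 1e-6)

  sim2 <- simulate_dataset(sim_config(), seed = 16)
  d2 <- truth_design(sim2)
  f2 <- suppressWarnings(fit_lmm(d2))
  perm <- d2[sample(nrow(d2)), ]
  f3 <- suppressWarnings(fit_lmm(perm))
  expect_equal(f2$coefficients, f3$coefficients, tolerance = 1e-8)
  expect_equal(f2$variance_components, f3$variance_components,
               tolerance = 1e-6)
})

test_that("REML fixed effects equal the GLS solution at the estimated variances", {
  sim <- simulate_dataset(sim_config(), seed = 23)
  d <- truth_design(sim)
  f <- fit_lmm(d)
  vc <- f$variance_components
  sp <- unique(d$species)
  Za <- outer(d$species, sp, "==") * 1
  sb <- unique(paste(d$species, d$breed))
  Zb <- outer(paste(d$species, d$breed), sb, "==") * 1
  S <- vc[["resid"]] * diag(nrow(d)) + vc[["species"]] * tcrossprod(Za) +
    vc[["breed"]] * tcrossprod(Zb)
  X <- cbind(1, d$x, d$x2, d$d)
  bg <- solve(t(X) %*% solve(S, X), t(X) %*% solve(S, d$y))
  expect_equal(unname(f$coefficients), as.vector(bg), tolerance = 1e-4)
})

test_that("with pinned variances the posterior mean matches the GLS closed form", {
  sim <- simulate_dataset(sim_config(), seed = 5)
  d <- truth_design(sim)
  pr <- list(fixed_variances = c(0.006, 0.001, 0.003))
  f <- fit_phylo_mcmc(d, sim$tree, n_iter = 30000, burn_in = 5000, thin = 10,
                      priors = pr, lambda = 1, seed = 11)
  V <- vcv_matrix(sim$tree)[unique(d$species), unique(d$species)]
  Za <- outer(d$species, colnames(V), "==") * 1
  breeds <- unique(d$breed[d$breed != "none"])
  Zb <- outer(d$breed, breeds, "==") * 1
  S <- 0.003 * diag(nrow(d)) + 0.006 * Za %*% V %*% t(Za) +
    0.001 * tcrossprod(Zb)
  X <- cbind(1, d$x, d$x2, d$d)
  bg <- as.vector(solve(t(X) %*% solve(S, X), t(X) %*% solve(S, d$y)))
  expect_equal(unname(f$coefficients), bg, tolerance = 0.02)
  # pinned variances are echoed back exactly
  expect_equal(unname(f$variance_components), c(0.006, 0.001, 0.003))
})

test_that("MCMC and REML agree on data without phylogenetic signal", {
  cfg <- sim_config(lambda_true = 0)
  sim <- simulate_dataset(cfg, seed = 31)
  d <- truth_design(sim)
  fm <- suppressWarnings(fit_phylo_mcmc(d, sim$tree, seed = 7))
  fr <- suppressWarnings(fit_lmm(d))
  # slopes agree tightly; the intercept trades off against the variance
  # components, so it gets a wider band
  expect_lt(abs(fm$coefficients[["intercept"]] -
                  fr$coefficients[["intercept"]]), 0.06)
  for (nm in c("b1", "b2", "diet_coef")) {
    expect_lt(abs(fm$coefficients[[nm]] - fr$coefficients[[nm]]), 0.02)
  }
})

test_that("a prior-only run reproduces the prior moments of the variances", {
  sim <- simulate_dataset(sim_config(n_species = 6, n_patterns = 10), seed = 3)
  d <- truth_design(sim)
  pr <- list(shape = rep(3, 3), scale = rep(2, 3))
  f <- fit_phylo_mcmc(d, sim$tree, n_iter = 60000, burn_in = 5000, thin = 10,
                      priors = pr, seed = 13, prior_only = TRUE)
  draws <- f$posterior_draws$variances
  # inverse-gamma(3, 2): mean 1, sd 1
  for (cmp in c("phylo", "breed", "resid")) {
    expect_equal(mean(draws[, cmp]), 1, tolerance = 0.08)
    expect_equal(sd(draws[, cmp]), 1, tolerance = 0.25)
  }
  # lambda prior is uniform on [0, 1]
  expect_equal(mean(f$posterior_draws$lambda), 0.5, tolerance = 0.05)
})

test_that("marginal r2 is bounded and degenerate cases behave", {
  expect_equal(lactscale:::compute_marginal_r2(rep(2, 10), c(1, 1)), 0)
  expect_equal(lactscale:::compute_marginal_r2(rnorm(10), c(0, 0)), 1)
  sim <- simulate_dataset(sim_config(), seed = 41)
  f <- fit_lmm(truth_design(sim))
  expect_gte(marginal_r2(f), 0)
  expect_lte(marginal_r2(f), 1)
})

test_that("rate characteristics carry more mass signal than time to peak", {
  sim <- simulate_dataset(sim_config(), seed = 19)
  tt <- true_characteristics_table(sim$patterns)
  r2_rate <- fit_lmm(build_design(tt, "peak_rate"))$marginal_r2
  r2_ttp <- fit_lmm(build_design(tt, "time_to_peak"))$marginal_r2
  expect_gt(r2_rate, 0.95)
  expect_gt(r2_rate, r2_ttp)
})

test_that("species averaging is idempotent for one-point-per-species data", {
  cfg <- sim_config(n_species = 10, n_patterns = 10)
  sim <- simulate_dataset(cfg, seed = 9)
  d <- truth_design(sim)
  d <- d[order(d$species), ]
  d$breed <- "none"
  direct <- fit_phylo_mcmc(d, sim$tree, n_iter = 10000, burn_in = 2000,
                           thin = 10, seed = 21)
  avg <- species_average_analysis(d, sim$tree, n_iter = 10000,
                                  burn_in = 2000, thin = 10, seed = 21)
  expect_equal(avg$coefficients, direct$coefficients, tolerance = 1e-8)
  expect_equal(nrow(avg$interval_95), 4)
})

test_that("species averaging attenuates a within-species diet effect", {
  # the diet signal lives within one heavily replicated species; between
  # species the diet carries no signal, so one-point-per-species
  # averaging must lose the effect
  set.seed(77)
  tr <- simulate_tree(8)
  sp <- tr$tip.label
  rows <- list()
  for (i in seq_along(sp)) {
    n <- if (i == 1) 30 else 1
    mass <- 10^runif(1, -1, 2)
    diet <- runif(n, 8, 14)
    y <- 0.7 * log10(mass) + (if (i == 1) 0.05 * diet else 0.05 * 11) +
      rnorm(n, 0, 0.01)
    rows[[i]] <- data.frame(pattern_id = paste0(sp[i], "_", seq_len(n)),
                            y = y, x = log10(mass), x2 = log10(mass)^2,
                            d = diet, species = sp[i], breed = "none")
  }
  d <- do.call(rbind, rows)
  class(d) <- c("scaling_data", "data.frame")
  full <- fit_phylo_mcmc(d, tr, n_iter = 10000, burn_in = 2000, thin = 10,
                         seed = 2)
  avg <- species_average_analysis(d, tr, n_iter = 10000, burn_in = 2000,
                                  thin = 10, seed = 2)
  expect_gt(full$coefficients[["diet_coef"]], 0.04)
  expect_lt(abs(avg$coefficients[["diet_coef"]]),
            abs(full$coefficients[["diet_coef"]]))
})

test_that("ratio scaling reports the fold change with flat mass effects", {
  sim <- simulate_dataset(sim_config(n_species = 8, n_patterns = 16,
                                     obs_noise_cv = 0, sigma_phylo = 0,
                                     sigma_breed = 0, sigma_resid = 0),
                          seed = 12)
  tt <- true_characteristics_table(sim$patterns)
  # constructed: peak exactly twice the initial rate everywhere
  tt$peak_rate <- 2 * tt$initial_rate
  f <- suppressWarnings(ratio_scaling(tt, "peak_rate", "initial_rate"))
  expect_equal(f$fold_change, 2, tolerance = 1e-6)
  expect_equal(f$coefficients[["b1"]], 0, tolerance = 1e-6)
  expect_equal(f$coefficients[["b2"]], 0, tolerance = 1e-6)

  # log10 ratio of identical series is exactly zero
  tt$peak_rate <- tt$initial_rate
  f0 <- suppressWarnings(ratio_scaling(tt, "peak_rate", "initial_rate"))
  expect_equal(f0$fold_change, 1, tolerance = 1e-8)

  # generator truths: parallel laws give a mass-free fold change near 1.9
  sim2 <- simulate_dataset(sim_config(), seed = 13)
  tt2 <- true_characteristics_table(sim2$patterns)
  f2 <- ratio_scaling(tt2, "peak_rate", "initial_rate", tree = sim2$tree,
                      n_iter = 20000, burn_in = 4000, thin = 10, seed = 3)
  expect_equal(f2$fold_change, 1.9, tolerance = 0.1)
  expect_lt(abs(f2$coefficients[["b1"]]), 0.1)
  expect_lt(abs(f2$coefficients[["b2"]]), 0.05)
})

test_that("MCMC estimates are invariant to row permutation up to Monte-Carlo error", {
  sim <- simulate_dataset(sim_config(n_species = 8, n_patterns = 14), seed = 25)
  d <- truth_design(sim)
  f1 <- fit_phylo_mcmc(d, sim$tree, n_iter = 20000, burn_in = 4000,
                       thin = 10, seed = 5)
  set.seed(99)
  f2 <- fit_phylo_mcmc(d[sample(nrow(d)), ], sim$tree, n_iter = 20000,
                       burn_in = 4000, thin = 10, seed = 5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 0.05)
})
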
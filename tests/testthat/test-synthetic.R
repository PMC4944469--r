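test_that("pure-birth trees are ultrametric, unit height and fully labelled", {
  t2 <- simulate_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(depths[1], depths[2])

  t24 <- simulate_tree(24, seed = 1)
  expect_equal(ape::Ntip(t24), 24)
  expect_equal(t24$Nnode, 23) # bifurcating
  expect_true(ape::is.ultrametric(t24, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t24)), 1)
  expect_equal(sort(t24$tip.label), sprintf("sp_%03d", 1:24))

  t8 <- simulate_tree(8, seed = 5)
  expect_equal(unname(diag(vcv_matrix(t8))), rep(1, 8))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("species effects have the requested covariance structure", {
  tr <- simulate_tree(6, seed = 9)
  expect_equal(unname(simulate_species_effects(tr, 0, 0.5, seed = 1)),
               rep(0, 6))
  expect_error(simulate_species_effects(tr, -1, 0.5), ">= 0")

  # star tree: independent draws whatever lambda
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  set.seed(33)
  draws <- t(replicate(4000, simulate_species_effects(star, 1, 0.9)))
  cors <- cor(draws)[upper.tri(diag(4))]
  expect_lt(max(abs(cors)), 0.06)

  # marginal variance is invariant to lambda (only covariance changes)
  set.seed(44)
  v0 <- apply(t(replicate(4000, simulate_species_effects(tr, 0.5, 0))), 2, var)
  v1 <- apply(t(replicate(4000, simulate_species_effects(tr, 0.5, 1))), 2, var)
  expect_equal(unname(v0), rep(0.25, 6), tolerance = 0.1)
  expect_equal(unname(v1), rep(0.25, 6), tolerance = 0.1)

  # lambda = 0: empirical cross-species correlation near zero
  set.seed(55)
  d0 <- t(replicate(4000, simulate_species_effects(tr, 1, 0)))
  expect_lt(max(abs(cor(d0)[upper.tri(diag(6))])), 0.06)
})

test_that("noiseless patterns reproduce their generating characteristics", {
  cfg <- sim_config(obs_noise_cv = 0, sigma_phylo = 0, sigma_breed = 0,
                    sigma_resid = 0)
  ctx <- list(species = "sp_001", breed = "", mass_kg = 0.5,
              diet_me_density = 11, species_effect = 0, breed_effect = 0)
  set.seed(10)
  p <- simulate_pattern(ctx, cfg)
  tr <- attr(p, "truth")
  chr <- pattern_characteristics(p)
  # daily sampling: raw time to peak within one sampling interval
  expect_lt(abs(chr$time_to_peak - tr$time_to_peak), 1 + 1e-9)
  # the daily grid maximum sits slightly below the continuous-time peak
  expect_lte(chr$amplitude, tr$amplitude + 1e-9)
  expect_equal(chr$amplitude, tr$amplitude, tolerance = 0.1)
  expect_equal(chr$initial_rate, p$mei[1])

  # weekly species: peak recovered within one 7-day interval
  ctxw <- modifyList(ctx, list(mass_kg = 300))
  set.seed(11)
  w <- simulate_pattern(ctxw, cfg)
  trw <- attr(w, "truth")
  expect_true(trw$weekly)
  expect_equal(median(diff(w$times)), 7)
  expect_lt(abs(pattern_characteristics(w)$time_to_peak - trw$time_to_peak),
            7 + 1e-9)
})

test_that("large c gives an accelerating (concave-up) early trajectory", {
  cfg <- sim_config(obs_noise_cv = 0, sigma_phylo = 0, sigma_breed = 0,
                    sigma_resid = 0, c_meanlog = log(19), c_sdlog = 1e-6)
  ctx <- list(species = "sp_001", breed = "", mass_kg = 0.5,
              diet_me_density = 11, species_effect = 0, breed_effect = 0)
  set.seed(12)
  p <- simulate_pattern(ctx, cfg)
  expect_gt(attr(p, "truth")$c, 15)
  early <- head(p$mei, 4)
  expect_true(all(diff(diff(early)) > 0)) # second finite difference positive
})

test_that("generated cumulative elevation is non-decreasing before noise", {
  cfg <- sim_config(obs_noise_cv = 0)
  sim <- simulate_dataset(cfg, seed = 14)
  for (p in sim$patterns[1:10]) {
    expect_true(all(diff(cumulative_series(p)$cumulative) >= -1e-9),
                info = p$pattern_id)
  }
})

test_that("noiseless zero-random-effect data recover the scaling law exactly by OLS", {
  cfg <- sim_config(obs_noise_cv = 0, sigma_phylo = 0, sigma_breed = 0,
                    sigma_resid = 0)
  sim <- simulate_dataset(cfg, seed = 2)
  tt <- true_characteristics_table(sim$patterns)
  co <- coef(lm(log10(peak_rate) ~ log10(mass_peak_kg) +
                  I(log10(mass_peak_kg)^2) + diet_me_density, data = tt))
  expect_equal(unname(co), c(-0.233, 0.667, 0.050, 0.024), tolerance = 1e-7)
})

test_that("replication is heavy-tailed across species", {
  sim <- simulate_dataset(sim_config(), seed = 8)
  expect_length(sim$patterns, 52)
  expect_equal(nrow(sim$species), 24)
  reps <- sim$species$n_patterns
  expect_equal(sum(reps), 52)
  # a handful of species carry all the replication
  expect_lte(sum(reps > 1), 5)
  expect_gte(sum(sort(reps, decreasing = TRUE)[1:5]), 52 - 24 + 5)
})

test_that("datasets round-trip through CSV + Newick", {
  sim <- simulate_dataset(sim_config(n_species = 5, n_patterns = 8), seed = 4)
  out <- withr::local_tempdir()
  paths <- write_dataset(sim$patterns, sim$tree, out)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(paths[["csv"]], tree = paths[["newick"]])
  expect_length(back, length(sim$patterns))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$mei, sim$patterns[[i]]$mei, tolerance = 1e-10)
    expect_equal(back[[i]]$times, sim$patterns[[i]]$times)
    expect_equal(back[[i]]$species, sim$patterns[[i]]$species)
  }
  expect_length(attr(back, "unmatched_species"), 0)

  expect_error(write_dataset(list(), sim$tree, out), "no patterns")

  # constructed name mismatch is reported
  mangled <- sim$patterns
  mangled[[1]]$species <- "not_a_species"
  paths2 <- write_dataset(mangled, sim$tree, withr::local_tempdir())
  expect_warning(b2 <- read_dataset(paths2[["csv"]], tree = paths2[["newick"]]),
                 "not_a_species")
  expect_equal(attr(b2, "unmatched_species"), "not_a_species")
})
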
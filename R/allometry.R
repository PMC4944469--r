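#' Build the design table for a scaling regression
#'
#' One row per pattern: `y = log10(characteristic)`, `x = log10(mass, kg)`,
#' `x2 = x^2`, `d` = diet ME density (MJ/kg DM, untransformed), species
#' and breed. Rows with non-positive characteristic values are dropped
#' with a message. Body mass at the time of peak intake is the default;
#' mass at lactation onset is available as a variant.
#'
#' @param characteristics data frame with columns `species`, `breed`,
#'   `diet_me_density`, `mass_peak_kg`, `mass_onset_kg` and the requested
#'   characteristic column (e.g. from [characteristics_table()]).
#' @param characteristic name of the column to model.
#' @param mass_column `"peak"` or `"onset"`.
#' @return data frame of class `scaling_data` with columns `pattern_id`,
#'   `y`, `x`, `x2`, `d`, `species`, `breed`.
#' @export
build_design <- function(characteristics, characteristic,
                         mass_column = c("peak", "onset")) {
  mass_column <- match.arg(mass_column)
  mcol <- if (mass_column == "peak") "mass_peak_kg" else "mass_onset_kg"
  if (!characteristic %in% names(characteristics)) {
    stop("no column `", characteristic, "` in the characteristics table",
         call. = FALSE)
  }
  val <- characteristics[[characteristic]]
  keep <- is.finite(val) & val > 0
  if (!any(keep)) stop("no positive values of `", characteristic, "`",
                       call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with non-positive or missing `",
            characteristic, "` dropped")
  }
  cc <- characteristics[keep, ]
  x <- log10(cc[[mcol]])
  out <- data.frame(pattern_id = cc$pattern_id,
                    y = log10(cc[[characteristic]]),
                    x = x, x2 = x^2, d = cc$diet_me_density,
                    species = cc$species,
                    breed = ifelse(nzchar(cc$breed), cc$breed, "none"),
                    stringsAsFactors = FALSE)
  class(out) <- c("scaling_data", "data.frame")
  attr(out, "characteristic") <- characteristic
  out
}

#' Local scaling exponent of a curvilinear allometry
#'
#' Under `y = a * M^(b1 + b2*log10 M)` the exponent at mass `M` (kg) is
#' `b1 + b2 * log10(M)`.
#'
#' @param b1 linear coefficient of log10 body mass.
#' @param b2 quadratic coefficient.
#' @param mass_kg body mass, kg; > 0 (vectorized).
#' @return dimensionless exponent(s).
#' @export
#' @examples
#' local_exponent(0.67, 0.050, 0.05) # exponent for a 50-g mother
local_exponent <- function(b1, b2, mass_kg) {
  if (any(mass_kg <= 0)) stop("mass must be > 0", call. = FALSE)
  b1 + b2 * log10(mass_kg)
}

#' Marginal r-squared of a scaling fit
#'
#' Variance explained by the fixed effects:
#' `var(X beta) / (var(X beta) + sum(variance components) + resid var)`
#' (the Nakagawa-Schielzeth marginal r2).
#'
#' @param fit a `scaling_fit`.
#' @return fraction in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  fit$marginal_r2
}

compute_marginal_r2 <- function(Xbeta, var_components) {
  vf <- var(Xbeta) * (length(Xbeta) - 1) / length(Xbeta)
  tot <- vf + sum(var_components)
  if (tot <= 0) return(0)
  vf / tot
}

fixed_formula_terms <- c("(Intercept)" = "intercept", "x" = "b1",
                         "x2" = "b2", "d" = "diet_coef")

new_scaling_fit <- function(method, coefs, ci, p, varcomp, lambda,
                            marg_r2, draws = NULL, rhat = NULL, extra = list()) {
  structure(c(list(method = method, coefficients = coefs, interval_95 = ci,
                   p_values = p, variance_components = varcomp,
                   lambda = lambda, marginal_r2 = marg_r2,
                   posterior_draws = draws, rhat = rhat), extra),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit>", x$method, "\n")
  tab <- data.frame(estimate = x$coefficients,
                    lo95 = x$interval_95[, 1], hi95 = x$interval_95[, 2],
                    p = x$p_values)
  print(round(tab, 4))
  cat("variance components:",
      paste(names(x$variance_components),
            signif(x$variance_components, 3), sep = "=", collapse = ", "), "\n")
  if (!is.na(x$lambda)) cat("lambda =", round(x$lambda, 3), "\n")
  cat("marginal r2 =", round(x$marginal_r2, 3), "\n")
  invisible(x)
}

#' REML scaling fit with species and breed random effects
#'
#' Non-phylogenetic route: `y ~ x + x2 + d + (1|species) +
#' (1|species:breed)` fitted by REML in lme4. Wald 95% intervals and
#' p-values. Singular fits are reported with the component at zero and a
#' warning, not as failures. The breed term is dropped when every pattern
#' has a distinct or a single breed level (it would be confounded).
#'
#' @param data a `scaling_data` from [build_design()].
#' @return object of class `scaling_fit` with coefficients `intercept`,
#'   `b1`, `b2`, `diet_coef`; variance components `species`, `breed`,
#'   `resid`; `lambda = NA` (not defined without a phylogeny).
#' @export
fit_lmm <- function(data) {
  if (length(unique(data$species)) < 2) {
    stop("need >= 2 species", call. = FALSE)
  }
  if (sd(data$y) < 1e-12) {
    # constant response: closed form, all slopes and variances zero
    b <- c(intercept = data$y[[1]], b1 = 0, b2 = 0, diet_coef = 0)
    ci <- cbind(lo = b, hi = b)
    varcomp <- c(species = 0, breed = 0, resid = 0)
    return(new_scaling_fit("REML (lme4), no phylogeny", b, ci,
                           setNames(c(0, 1, 1, 1), names(b)), varcomp,
                           NA_real_, 0))
  }
  data$sb <- interaction(data$species, data$breed, drop = TRUE)
  use_breed <- length(unique(data$breed)) > 1 &&
    nlevels(data$sb) > length(unique(data$species)) &&
    nlevels(data$sb) < nrow(data)
  form <- if (use_breed) {
    y ~ x + x2 + d + (1 | species) + (1 | sb)
  } else {
    y ~ x + x2 + d + (1 | species)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular REML fit: one or more variance components estimated at zero")
  }
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  names(b) <- fixed_formula_terms[names(b)]
  ci <- cbind(b - 1.96 * se, b + 1.96 * se)
  dimnames(ci) <- list(names(b), c("lo", "hi"))
  p <- 2 * pnorm(-abs(b / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  varcomp <- c(species = getv("species"), breed = getv("sb"),
               resid = getv("Residual"))
  X <- cbind(1, data$x, data$x2, data$d)
  r2 <- compute_marginal_r2(as.vector(X %*% b), varcomp)
  new_scaling_fit("REML (lme4), no phylogeny", b, ci, p, varcomp,
                  NA_real_, r2)
}

# split-half Rhat for a single chain (per column of draws)
split_rhat <- function(draws) {
  apply(draws, 2, function(v) {
    n <- length(v) %/% 2
    if (n < 4) return(NA_real_)
    halves <- list(v[1:n], v[(n + 1):(2 * n)])
    m <- vapply(halves, mean, numeric(1))
    s2 <- vapply(halves, var, numeric(1))
    W <- mean(s2)
    B <- n * var(m)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Phylogenetic animal-model scaling fit by MCMC
#'
#' Gibbs sampler over `y = X beta + Z_a u_a + Z_b u_b + e`, where `u_a` is
#' a species-level effect with covariance `sigma2_phylo * V_lambda`
#' (`V` the unit-height tree covariance, `V_lambda = lambda*V +
#' (1-lambda)*I`; repeated measures are mapped through an incidence
#' matrix so multiple patterns per species enter without weighting),
#' `u_b` a breed-within-species effect and `e` the residual. Flat priors
#' on fixed effects; weakly informative inverse-gamma(0.001, 0.001)
#' priors on each variance by default; uniform(0, 1) prior on the
#' phylogenetic signal `lambda`, updated by a reflected random-walk
#' Metropolis step within the Gibbs scan (`V_lambda` shares the
#' eigenvectors of `V`, so each update only reshifts eigenvalues).
#' The reported `lambda` is the posterior mean of the sampled parameter;
#' the phylogenetic-heritability ratio `sigma2_phylo / (sigma2_phylo +
#' sigma2_breed + sigma2_resid)` is also returned.
#'
#' @param data a `scaling_data` from [build_design()].
#' @param tree `ape::phylo` covering the species (extra tips pruned;
#'   unmatched species dropped with a warning).
#' @param n_iter,burn_in,thin chain settings. Desk-scale defaults
#'   (60000/10000/25) keep a fit under a few seconds; production-scale
#'   chains (1e6/15000/100) are available by argument.
#' @param priors list with elements `shape` and `scale` (length-3, order
#'   phylo/breed/resid) and optionally `fixed_variances` (length-3; `NA`
#'   entries are estimated, numeric entries pinned — pinning all three
#'   turns the sampler into a GLS draw).
#' @param lambda `"sample"` (default) or a fixed numeric value in
#'   \[0, 1\] (1 = plain Brownian animal model).
#' @param mh_sd proposal SD of the lambda Metropolis step.
#' @param seed integer seed for the chain (set before sampling).
#' @param prior_only sample variances and lambda from their priors,
#'   ignoring the data (sampler validation).
#' @return `scaling_fit` with posterior means, 95% equal-tailed credible
#'   intervals, pMCMC (`2*min(Pr(>0), Pr(<0))`, floored at 2/n_kept),
#'   variance components (posterior means), `lambda`,
#'   `phylo_heritability`, marginal r2, retained draws and split-Rhat per
#'   coefficient (warning above 1.1).
#' @export
fit_phylo_mcmc <- function(data, tree, n_iter = 60000, burn_in = 10000,
                           thin = 25, priors = NULL, lambda = "sample",
                           mh_sd = 0.12, seed = NULL, prior_only = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pm <- prune_and_match(tree, data$species)
  data <- data[data$species %in% pm$matched, , drop = FALSE]
  if (length(unique(data$species)) < 2) {
    stop("need >= 2 species on the tree", call. = FALSE)
  }
  V <- vcv_matrix(pm$tree)
  sp <- colnames(V)

  X <- cbind(1, data$x, data$x2, data$d)
  colnames(X) <- c("intercept", "b1", "b2", "diet_coef")
  Za <- outer(data$species, sp, "==") * 1
  breeds <- unique(data$breed[nzchar(data$breed) & data$breed != "none"])
  Zb <- if (length(breeds) > 1) outer(data$breed, breeds, "==") * 1 else
    matrix(0, nrow(data), 0)

  run_gibbs_lmm(data$y, X, Za, Zb, V, n_iter, burn_in, thin, priors,
                lambda, mh_sd, prior_only, species = sp)
}

# shared driver behind the MCMC fits (with or without extra covariates)
run_gibbs_lmm <- function(y, X, Za, Zb, V, n_iter, burn_in, thin,
                          priors = NULL, lambda = "sample", mh_sd = 0.12,
                          prior_only = FALSE, species = colnames(V),
                          method = "phylogenetic animal model (Gibbs MCMC)") {
  eg <- eigen(V, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    stop("tree covariance is not positive semidefinite", call. = FALSE)
  }
  d_eig <- pmax(eg$values, 1e-12)

  if (is.null(priors)) priors <- list()
  shape <- priors$shape %||% rep(0.001, 3)
  scale <- priors$scale %||% rep(0.001, 3)
  fixedv <- priors$fixed_variances %||% rep(NA_real_, 3)
  fixedv[is.na(fixedv)] <- -1

  sample_lambda <- identical(lambda, "sample")
  lambda_init <- if (sample_lambda) 0.5 else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda
  }

  res <- gibbs_lmm_cpp(y, X, Za, Zb, eg$vectors, d_eig,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin),
                       shape, scale, fixedv,
                       sample_lambda, lambda_init, mh_sd, prior_only)
  beta <- res$beta
  colnames(beta) <- colnames(X)
  vars <- res$variances
  colnames(vars) <- c("phylo", "breed", "resid")

  b <- colMeans(beta)
  ci <- t(apply(beta, 2, quantile, c(0.025, 0.975), names = FALSE))
  dimnames(ci) <- list(names(b), c("lo", "hi"))
  nk <- nrow(beta)
  p <- apply(beta, 2, function(v) {
    max(2 * min(mean(v > 0), mean(v < 0)), 2 / nk)
  })
  herit <- vars[, "phylo"] /
    pmax(vars[, "phylo"] + vars[, "breed"] + vars[, "resid"], 1e-300)
  lam_mean <- if (sample_lambda) mean(res$lambda) else lambda_init
  varcomp <- colMeans(vars)
  r2 <- compute_marginal_r2(as.vector(X %*% b), varcomp)
  rhat <- split_rhat(beta)
  if (!prior_only && any(is.finite(rhat) & rhat > 1.1)) {
    warning("split-Rhat > 1.1 for: ",
            paste(names(b)[is.finite(rhat) & rhat > 1.1], collapse = ", "),
            " - consider longer chains")
  }
  new_scaling_fit(method, b, ci, p, varcomp, lam_mean, r2,
                  draws = list(beta = beta, variances = vars,
                               lambda = res$lambda, heritability = herit),
                  rhat = rhat,
                  extra = list(species = species, n_kept = nk,
                               phylo_heritability = mean(herit),
                               lambda_accept = res$accept_rate))
}

#' Species-averaged scaling analysis
#'
#' Collapses the design to one point per species (means of `y`, `x`, `d`;
#' `x2` recomputed from the mean `x`), drops the breed effect, and fits
#' the phylogenetic model with an identity species incidence — the
#' one-point-per-species analysis commonly practiced in comparative work.
#'
#' @param data a `scaling_data`.
#' @param tree `ape::phylo`.
#' @param ... passed to [fit_phylo_mcmc()].
#' @return `scaling_fit`.
#' @export
species_average_analysis <- function(data, tree, ...) {
  if (length(unique(data$species)) < 3) {
    stop("need >= 3 species", call. = FALSE)
  }
  agg <- aggregate(cbind(y, x, d) ~ species, data = data, FUN = mean)
  agg$x2 <- agg$x^2
  agg$breed <- "none"
  agg$pattern_id <- agg$species
  class(agg) <- c("scaling_data", "data.frame")
  fit_phylo_mcmc(agg, tree, ...)
}

#' Scaling of the ratio of two characteristics
#'
#' Fits the standard model to `y = log10(numerator/denominator)` of
#' paired per-pattern characteristics. The back-transformed intercept at
#' the mean diet density, `10^(intercept + diet_coef * mean(d))`, is
#' reported as the fold change.
#'
#' @param characteristics characteristics table (see [build_design()]).
#' @param numerator,denominator column names (e.g. `"peak_rate"`,
#'   `"initial_rate"`).
#' @param tree optional `ape::phylo`; with a tree the phylogenetic model
#'   is used, otherwise REML.
#' @param mass_column `"peak"` or `"onset"`.
#' @param ... passed to [fit_phylo_mcmc()].
#' @return `scaling_fit` with an extra `fold_change` element.
#' @export
ratio_scaling <- function(characteristics, numerator, denominator,
                          tree = NULL, mass_column = "peak", ...) {
  cc <- characteristics
  den <- cc[[denominator]]
  keep <- is.finite(den) & den > 0 & is.finite(cc[[numerator]]) &
    cc[[numerator]] > 0
  cc <- cc[keep, ]
  cc$.ratio <- cc[[numerator]] / cc[[denominator]]
  data <- build_design(cc, ".ratio", mass_column = mass_column)
  fit <- if (is.null(tree)) fit_lmm(data) else fit_phylo_mcmc(data, tree, ...)
  fit$fold_change <-
    10^(fit$coefficients[["intercept"]] +
          fit$coefficients[["diet_coef"]] * mean(data$d))
  fit
}
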
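# small deterministic fixtures used across test files

# daily pattern with the given MEI values on days 1..n
make_pattern <- function(mei, times = seq_along(mei), id = "p1",
                         species = "Mus musculus", breed = "",
                         diet = 11, mass = 0.03) {
  intake_pattern(id, species, breed, times, mei, diet, mass)
}

# noiseless Von Bertalanffy pattern: MEI = init + vb_rate on days 1..T
make_vb_pattern <- function(A = 10, k = 0.2, c = 3, init = 5, Tend = 40,
                            id = "vb1", species = "sp_a", mass = 1,
                            diet = 11) {
  t <- seq(1, Tend)
  intake_pattern(id, species, "", t, init + vb_rate(A, k, c, t), diet, mass)
}

# triangular extra-intake pattern: rate rises linearly to a peak at day
# t_peak then declines symmetrically to zero (observed over the full
# course, so the cumulative curve saturates)
make_triangle_series <- function(t_peak = 20) {
  s <- 0:(2 * t_peak)
  rate <- ifelse(s <= t_peak, s, pmax(2 * t_peak - s, 0))
  cum <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2))
  data.frame(s = s, cumulative = cum, extra_rate = rate)
}

# design-level scaling data built directly from generating truths
truth_design <- function(sim, characteristic = "peak_rate") {
  build_design(true_characteristics_table(sim$patterns), characteristic)
}
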
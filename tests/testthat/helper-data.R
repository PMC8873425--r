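# Shared fixtures, built in code.

# corrected-series tibble with a given hierarchy shape and arbitrary values
series_shape <- function(k, genos_per_pop, M, n, seed = 1) {
  set.seed(seed)
  L <- sum(genos_per_pop)
  gp <- rep(seq_len(k), genos_per_pop)
  base <- sort(rep(seq_len(L), length.out = M))
  tibble::tibble(
    population = rep(sprintf("P%d", gp[base]), each = n),
    genotype = rep(sprintf("g%03d", base), each = n),
    plant = rep(sprintf("pl%04d", seq_len(M)), each = n),
    time = rep(seq(0, 1, length.out = n), M),
    corrected = stats::rnorm(M * n),
    weight = 1
  )
}

# tiny valid phenotype table (2 populations, 2 genotypes each, 2 plants each)
toy_table <- function(n_times = 3) {
  tt <- seq_len(n_times)
  grid <- expand.grid(g = 1:4, i = 1:2)
  tab <- purrr::pmap_dfr(grid, function(g, i) {
    p <- ifelse(g <= 2, 1, 2)
    tibble::tibble(
      population = sprintf("P%d", p), genotype = sprintf("g%d", g),
      plant = sprintf("g%d_pl%d", g, i),
      row = g, col = i, time = tt, value = g + 0.1 * tt
    )
  })
  tab
}

# simulation matched to the hierarchical model (no surface/factors, constant
# noise) for stage-2 recovery checks
model_matched_sim <- function(seed, b = 9, ...) {
  simulate_experiment(sim_config(
    seed = seed, b_gen = b, b_plant = b,
    surface_amplitude = 0, factor_effect = 0,
    sigma_drift = 0, missingness = 0, ...))
}

as_corrected <- function(sim) {
  dplyr::mutate(sim$table, corrected = .data$value, weight = 1)
}
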
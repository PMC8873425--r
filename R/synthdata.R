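#' Configuration for a synthetic HTP experiment
#'
#' Defines the data-generating process used throughout the package's
#' simulation studies: logistic population growth curves; genotype- and
#' plant-level deviations drawn as random intercept + random slope + smooth
#' B-spline coefficient draws (the same generative form the hierarchical
#' growth model assumes); a smooth bivariate spatial nuisance surface over the
#' row-by-column grid whose amplitude and phase drift over time; optional
#' categorical design-factor effects; heteroscedastic Gaussian noise; and
#' missing records at a fixed rate.
#'
#' Defaults describe a compact greenhouse-style experiment: two populations of
#' 10 genotypes with 4 plants each (M = 80) on a 10 x 8 grid, measured at
#' n = 15 common times over DOY 100-135, logistic population curves with
#' plateaus near 100 and 140 units, and a spatial surface of about a tenth of
#' the signal range.
#'
#' @param k number of populations.
#' @param genos_per_pop genotypes per population (scalar or length-k).
#' @param plants_per_geno plants per genotype (scalar or length-L).
#' @param grid integer c(rows, cols); must hold all plants.
#' @param times measurement time grid.
#' @param logistic data frame (or NULL) with columns `K`, `rate`, `t0` and
#'   optionally `base` (baseline size), one row per population; defaults
#'   stagger K between 100 and 140 above a baseline of 20.
#' @param var_gen named numeric: `int`, `slope`, `smooth` genotype-deviation
#'   variances (intercept/slope on the unit-scaled time).
#' @param var_plant same for plant deviations.
#' @param b_gen,b_plant basis dimensions for the smooth deviation draws.
#' @param surface_amplitude peak height of the spatial nuisance surface
#'   (0 disables it).
#' @param factor_effect effect size of a two-level design factor assigned by
#'   grid half (0 disables the factor).
#' @param sigma residual standard deviation at the first time.
#' @param sigma_drift relative linear increase of the residual sd over the
#'   time range (heteroscedastic noise; 0 = homoscedastic).
#' @param missingness probability that a (plant, time) record is unobserved.
#' @param seed integer seed; all draws are derived from it deterministically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(k = 2, genos_per_pop = 10, plants_per_geno = 4,
                       grid = c(10, 8),
                       times = seq(100, 135, length.out = 15),
                       logistic = NULL,
                       var_gen = c(int = 16, slope = 25, smooth = 4),
                       var_plant = c(int = 4, slope = 4, smooth = 1),
                       b_gen = 7, b_plant = 7,
                       surface_amplitude = 8,
                       factor_effect = 3,
                       sigma = 2, sigma_drift = 0.3,
                       missingness = 0.05, seed = 1L) {
  if (length(genos_per_pop) == 1) genos_per_pop <- rep(genos_per_pop, k)
  stopifnot(length(genos_per_pop) == k)
  L <- sum(genos_per_pop)
  if (length(plants_per_geno) == 1) plants_per_geno <- rep(plants_per_geno, L)
  stopifnot(length(plants_per_geno) == L)
  M <- sum(plants_per_geno)
  if (M > prod(grid)) stop("grid too small for ", M, " plants")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  if (any(c(var_gen, var_plant) < 0)) stop("variances must be >= 0")
  if (is.null(logistic)) {
    logistic <- data.frame(
      K = seq(100, 140, length.out = max(k, 2))[seq_len(k)],
      rate = rep(0.25, k),
      t0 = rep(mean(range(times)), k),
      base = 20 # plants start at a positive size
    )
  }
  if (is.null(logistic$base)) logistic$base <- 0
  stopifnot(nrow(logistic) == k)
  structure(list(
    k = k, genos_per_pop = genos_per_pop, plants_per_geno = plants_per_geno,
    L = L, M = M, grid = grid, times = times, logistic = logistic,
    var_gen = var_gen, var_plant = var_plant, b_gen = b_gen,
    b_plant = b_plant, surface_amplitude = surface_amplitude,
    factor_effect = factor_effect, sigma = sigma, sigma_drift = sigma_drift,
    missingness = missingness, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic sub-seed per generator component
.sub_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2147483629L

.draw_deviations <- function(n_units, mm, v, seed) {
  set.seed(seed)
  nr <- mm$n_random
  list(
    int = stats::rnorm(n_units, 0, sqrt(v[["int"]])),
    slope = stats::rnorm(n_units, 0, sqrt(v[["slope"]])),
    smooth = matrix(stats::rnorm(n_units * nr, 0, sqrt(v[["smooth"]])),
                    n_units, nr)
  )
}

.eval_deviation <- function(dev, j, mm, times) {
  X <- mm_design_fixed(mm, times)
  Z <- mm_design_random(mm, times)
  as.numeric(X %*% c(dev$int[j], dev$slope[j]) + Z %*% dev$smooth[j, ])
}

#' Simulate a synthetic HTP experiment with known truth
#'
#' @param config a [sim_config()].
#' @return list with `table` (a validated [validate_pheno()] tibble, with a
#'   `batch` design-factor column when `factor_effect != 0`) and `truth`, a
#'   list recording every generated component (population curves, deviation
#'   draws and their bases, the spatial surface per time, factor effects,
#'   noise sd per time).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tr <- range(cf$times)
  ts01 <- function(t) (t - tr[1]) / (tr[2] - tr[1])

  pops <- sprintf("P%02d", seq_len(cf$k))
  geno_pop <- rep(seq_len(cf$k), cf$genos_per_pop)
  genos <- sprintf("%s_g%03d", pops[geno_pop], sequence(cf$genos_per_pop))
  plant_geno <- rep(seq_len(cf$L), cf$plants_per_geno)
  plants <- sprintf("%s_pl%02d", genos[plant_geno], sequence(cf$plants_per_geno))

  # plant positions: random permutation of grid cells
  set.seed(.sub_seed(cf$seed, 1L))
  cells <- sample.int(prod(cf$grid), cf$M)
  rows <- ((cells - 1L) %% cf$grid[1]) + 1L
  cols <- ((cells - 1L) %/% cf$grid[1]) + 1L

  mm_gen <- mm_transform(basis_spec(tr, cf$b_gen))
  mm_plant <- mm_transform(basis_spec(tr, cf$b_plant))
  dev_gen <- .draw_deviations(cf$L, mm_gen, cf$var_gen, .sub_seed(cf$seed, 2L))
  dev_plant <- .draw_deviations(cf$M, mm_plant, cf$var_plant,
                                .sub_seed(cf$seed, 3L))

  n <- length(cf$times)
  # spatial nuisance: low-frequency product surface with drifting phase/amplitude
  set.seed(.sub_seed(cf$seed, 4L))
  phase_u <- stats::runif(1, 0, 2 * pi); phase_v <- stats::runif(1, 0, 2 * pi)
  surface <- function(u, v, j) {
    # additive low-frequency row/column gradients (the dominant part of
    # greenhouse/field trends) plus a weaker smooth interaction, with
    # amplitude and phase drifting over time
    amp <- cf$surface_amplitude * (0.6 + 0.4 * ts01(cf$times[j]))
    su <- sin(2 * pi * u / cf$grid[1] + phase_u + 0.2 * j)
    sv <- cos(2 * pi * v / cf$grid[2] + phase_v - 0.15 * j)
    amp * (0.45 * su + 0.35 * sv + 0.2 * su * sv)
  }

  batch <- if (cf$factor_effect != 0) {
    ifelse(cols <= cf$grid[2] / 2, "B1", "B2")
  } else NULL
  batch_eff <- c(B1 = 0, B2 = cf$factor_effect)

  pop_curve <- function(p, t) {
    with(cf$logistic[p, ], base + K / (1 + exp(-rate * (t - t0))))
  }

  sd_t <- cf$sigma * (1 + cf$sigma_drift * ts01(cf$times))

  set.seed(.sub_seed(cf$seed, 5L))
  recs <- vector("list", cf$M)
  for (i in seq_len(cf$M)) {
    g <- plant_geno[i]; p <- geno_pop[g]
    mu <- pop_curve(p, cf$times) +
      .eval_deviation(dev_gen, g, mm_gen, cf$times) +
      .eval_deviation(dev_plant, i, mm_plant, cf$times)
    sp <- vapply(seq_len(n), function(j) surface(rows[i], cols[i], j),
                 numeric(1))
    fe <- if (!is.null(batch)) batch_eff[[batch[i]]] else 0
    y <- mu + sp + fe + stats::rnorm(n, 0, sd_t)
    recs[[i]] <- tibble::tibble(
      population = pops[p], genotype = genos[g], plant = plants[i],
      row = rows[i], col = cols[i], time = cf$times, value = y
    )
  }
  tab <- dplyr::bind_rows(recs)
  if (!is.null(batch)) tab$batch <- rep(batch, each = n)
  if (cf$missingness > 0) {
    set.seed(.sub_seed(cf$seed, 6L))
    drop <- stats::runif(nrow(tab)) < cf$missingness
    tab <- tab[!drop, , drop = FALSE]
  }
  factors <- if (!is.null(batch)) c(batch = "average") else NULL
  tab <- validate_pheno(tab, factors = factors)

  truth <- list(
    config = cf, populations = pops, genotypes = genos, plants = plants,
    geno_pop = geno_pop, plant_geno = plant_geno,
    rows = rows, cols = cols,
    mm_gen = mm_gen, mm_plant = mm_plant,
    dev_gen = dev_gen, dev_plant = dev_plant,
    pop_curve = pop_curve, surface = surface,
    batch = batch, batch_eff = batch_eff, sd_t = sd_t
  )
  list(table = tab, truth = truth)
}

#' Evaluate a true component curve from a simulation
#'
#' @param truth the `truth` element of [simulate_experiment()].
#' @param level `"population"`, `"genotype"` or `"plant"`.
#' @param unit unit id (as in the generated table).
#' @param grid evaluation times.
#' @param type `"curve"` (the level's full curve, population + nested
#'   deviations) or `"deviation"` (the level's own deviation only).
#' @return numeric vector of true values on `grid`.
#' @export
truth_curves <- function(truth, level, unit, grid, type = "curve") {
  level <- match.arg(level, c("population", "genotype", "plant"))
  type <- match.arg(type, c("curve", "deviation"))
  if (level == "population") {
    p <- match(unit, truth$populations)
    if (is.na(p)) stop("unknown population: ", unit)
    return(truth$pop_curve(p, grid))
  }
  if (level == "genotype") {
    g <- match(unit, truth$genotypes)
    if (is.na(g)) stop("unknown genotype: ", unit)
    dev <- .eval_deviation(truth$dev_gen, g, truth$mm_gen, grid)
    if (type == "deviation") return(dev)
    return(truth$pop_curve(truth$geno_pop[g], grid) + dev)
  }
  i <- match(unit, truth$plants)
  if (is.na(i)) stop("unknown plant: ", unit)
  dev <- .eval_deviation(truth$dev_plant, i, truth$mm_plant, grid)
  if (type == "deviation") return(dev)
  g <- truth$plant_geno[i]
  truth$pop_curve(truth$geno_pop[g], grid) +
    .eval_deviation(truth$dev_gen, g, truth$mm_gen, grid) + dev
}
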
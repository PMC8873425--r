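# reconstruct the estimated spatial nuisance (polynomial surface part +
# smooth blocks + row/col effects) for a single-time fit
est_spatial <- function(sfit) {
  fit <- sfit$fit
  blocks <- build_spatial_blocks(sfit$spec, sfit$obs$row, sfit$obs$col)
  # fixed polynomial columns are the last three of the fixed part
  p <- fit$p
  out <- as.numeric(fit$spec$X[, (p - 2):p, drop = FALSE] %*%
                      fit$beta[(p - 2):p])
  for (lab in c("spat_u", "spat_v", "spat_u_lin_v", "spat_lin_u_v", "spat_uv")) {
    out <- out + as.numeric(blocks$random[[lab]] %*% fit$u[[lab]])
  }
  rowlv <- sort(unique(as.character(sfit$obs$row)))
  collv <- sort(unique(as.character(sfit$obs$col)))
  out + fit$u$row_effect[match(as.character(sfit$obs$row), rowlv)] +
    fit$u$col_effect[match(as.character(sfit$obs$col), collv)]
}

test_that("PS-ANOVA blocks have the documented dimensions", {
  spec <- spatial_spec(20, 12, b_row = 10, b_col = 8, nested = TRUE)
  coords <- expand.grid(row = 1:20, col = 1:12)
  bl <- build_spatial_blocks(spec, coords$row, coords$col)
  expect_equal(colnames(bl$fixed), c("us", "vs", ""))
  expect_equal(ncol(bl$random$spat_u), 10L - 2L)
  expect_equal(ncol(bl$random$spat_v), 8L - 2L)
  expect_equal(ncol(bl$random$spat_u_lin_v), 10L - 2L)
  expect_equal(ncol(bl$random$spat_lin_u_v), 8L - 2L)
  # nested halving: ceil(10/2) = 5 and ceil(8/2) = 4 marginal dimensions
  expect_equal(ncol(bl$random$spat_uv), (5L - 2L) * (4L - 2L))
  expect_error(build_spatial_blocks(spec, 21, 5), "grid")
})

test_that("the PhenoArch-sized surface specification builds", {
  spec <- spatial_spec(60, 28, b_row = 60, b_col = 28, nested = TRUE)
  coords <- expand.grid(row = 1:60, col = 1:28)
  bl <- build_spatial_blocks(spec, coords$row, coords$col)
  expect_equal(ncol(bl$random$spat_u), 58L)
  expect_equal(ncol(bl$random$spat_v), 26L)
  expect_equal(ncol(bl$random$spat_uv), (30L - 2L) * (14L - 2L))
})

test_that("per-population genetic variances appear as separate components", {
  sim <- simulate_experiment(sim_config(seed = 21, genos_per_pop = 6,
                                        plants_per_geno = 3, grid = c(6, 6),
                                        times = c(0, 1, 2), missingness = 0))
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = d$factors)
  sfit <- quiet_fit(fit_timepoint(slots[slots$time == 0, ], spec))
  expect_setequal(grep("^geno_", sfit$fit$groups, value = TRUE),
                  c("geno_P01", "geno_P02"))
  # genotype BLUPs are centred (approximately) within population
  for (g in c("geno_P01", "geno_P02")) {
    expect_lt(abs(mean(sfit$fit$u[[g]])), 0.35 * stats::sd(sfit$fit$u[[g]]))
  }
})

test_that("the correction identity and missingness bookkeeping hold", {
  sim <- simulate_experiment(sim_config(seed = 22, genos_per_pop = 5,
                                        plants_per_geno = 3, grid = c(6, 5),
                                        times = seq(0, 6, length.out = 6),
                                        missingness = 0.1))
  cs <- quiet_fit(run_stage1(sim$table))
  d <- pheno_dims(sim$table)
  expect_equal(nrow(cs), d$n_slots)
  obs <- cs[!cs$missing, ]
  # corrected = prediction + residual, exactly
  expect_lt(max(abs(obs$corrected - obs$prediction - obs$residual)), 1e-10)
  expect_true(all(obs$weight > 0 & is.finite(obs$weight)))
  # missing raw slots stay missing in the corrected series
  expect_true(all(is.na(cs$corrected[cs$missing])))
  # no RNG in stage 1: a second run is identical
  cs2 <- quiet_fit(run_stage1(sim$table))
  expect_identical(cs$corrected, cs2$corrected)
  expect_identical(cs$weight, cs2$weight)
})

test_that("weights match a dense-inverse oracle and equalise when exchangeable", {
  sim <- simulate_experiment(sim_config(seed = 23, genos_per_pop = 4,
                                        plants_per_geno = 3, grid = c(6, 4),
                                        times = c(0, 1), missingness = 0))
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = d$factors)
  sfit <- quiet_fit(fit_timepoint(slots[slots$time == 0, ], spec))
  w <- stage1_weights(sfit)
  # dense oracle: explicit inverse of the full MME matrix
  A <- phenospline:::.phat_map(sfit)
  Ci <- solve(as.matrix(sfit$fit$C))
  Vp <- A %*% Ci %*% t(A) + diag(sfit$fit$variances$sigma2, nrow(A))
  expect_lt(max(abs(w - diag(solve(Vp)))), 1e-9)

  # single genotype, no nuisance: all plants exchangeable -> equal weights
  tab <- tibble::tibble(
    population = "P1", genotype = "g1",
    plant = sprintf("pl%d", 1:9),
    row = rep(1:3, 3), col = rep(1:3, each = 3),
    time = 0, value = stats::rnorm(9, 10))
  tab <- validate_pheno(tab)
  sp1 <- spatial_spec(3, 3)
  sf1 <- quiet_fit(fit_timepoint(complete_slots(tab), sp1))
  w1 <- stage1_weights(sf1)
  expect_lt(diff(range(w1)) / mean(w1), 1e-6)
})

test_that("spatial trends are removed and the surface is recovered", {
  # strong surface: corrected values should be less variable within genotype
  # no design factor here: a factor allocated by grid half would absorb part
  # of the column gradient and is not part of the surface being recovered
  sim <- simulate_experiment(sim_config(seed = 24, genos_per_pop = 15,
                                        plants_per_geno = 4, grid = c(12, 10),
                                        times = seq(0, 4, length.out = 4),
                                        surface_amplitude = 10,
                                        factor_effect = 0,
                                        missingness = 0))
  cs <- quiet_fit(run_stage1(sim$table))
  obs <- cs[!cs$missing, ]
  wv <- obs |>
    dplyr::group_by(.data$genotype, .data$time) |>
    dplyr::summarise(raw = stats::var(value), cor = stats::var(corrected),
                     .groups = "drop")
  expect_lt(mean(wv$cor), mean(wv$raw))

  # surface recovery at one time: correlation with the truth
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = d$factors)
  sfit <- quiet_fit(fit_timepoint(slots[slots$time == d$times[2], ], spec))
  fhat <- est_spatial(sfit)
  tru <- vapply(seq_len(nrow(sfit$obs)), function(i)
    sim$truth$surface(sfit$obs$row[i], sfit$obs$col[i], 2), numeric(1))
  expect_gt(stats::cor(fhat, tru), 0.8)
})

test_that("a null surface is estimated as (nearly) zero", {
  sim <- simulate_experiment(sim_config(seed = 25, genos_per_pop = 8,
                                        plants_per_geno = 4, grid = c(8, 8),
                                        times = c(0, 1), missingness = 0,
                                        surface_amplitude = 0, sigma = 2))
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = d$factors)
  sfit <- quiet_fit(fit_timepoint(slots[slots$time == 0, ], spec))
  fhat <- est_spatial(sfit)
  expect_lt(max(abs(fhat)), 3 * 2) # well below 3 noise sd
})

test_that("nothing is corrected when there is nothing to correct", {
  sim <- simulate_experiment(sim_config(seed = 26, genos_per_pop = 4,
                                        plants_per_geno = 3, grid = c(6, 4),
                                        times = c(0, 1, 2),
                                        surface_amplitude = 0,
                                        factor_effect = 0, sigma = 0,
                                        missingness = 0))
  cs <- quiet_fit(run_stage1(sim$table))
  obs <- cs[!cs$missing, ]
  # the fixed polynomial trend always enters the correction, so the identity
  # is approximate: tiny relative to the genetic signal
  expect_gt(stats::cor(obs$corrected, obs$value), 0.98)
  expect_lt(mean(abs(obs$corrected - obs$value)), 0.15 * stats::sd(obs$value))
})

test_that("genotype BLUPs track the simulated genetic effects", {
  # 2 populations x 25 genotypes x 4 replicates, known genotype deviations
  sim <- simulate_experiment(sim_config(seed = 27, genos_per_pop = 25,
                                        plants_per_geno = 4, grid = c(16, 13),
                                        times = c(0, 1),
                                        var_gen = c(int = 25, slope = 0, smooth = 0),
                                        var_plant = c(int = 1, slope = 0, smooth = 0),
                                        missingness = 0))
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = d$factors)
  sfit <- quiet_fit(fit_timepoint(slots[slots$time == 0, ], spec))
  blup <- c(sfit$fit$u$geno_P01, sfit$fit$u$geno_P02)
  gl <- c(sfit$geno_info$geno_P01, sfit$geno_info$geno_P02)
  tru <- vapply(gl, function(g)
    truth_curves(sim$truth, "genotype", g, 0, type = "deviation"), numeric(1))
  expect_gt(stats::cor(blup, tru), 0.9)
})

test_that("fixed- and random-genotype corrections essentially agree", {
  sim <- simulate_experiment(sim_config(seed = 28, genos_per_pop = 6,
                                        plants_per_geno = 4, grid = c(8, 6),
                                        times = seq(0, 3, length.out = 4),
                                        missingness = 0))
  d <- pheno_dims(sim$table)
  cs_r <- quiet_fit(run_stage1(sim$table,
                               spatial_spec(d$r, d$c, factors = d$factors)))
  cs_f <- quiet_fit(run_stage1(sim$table,
                               spatial_spec(d$r, d$c, factors = d$factors,
                                            genotype_as = "fixed")))
  ok <- !cs_r$missing
  expect_gt(stats::cor(cs_r$corrected[ok], cs_f$corrected[ok]), 0.99)
})

test_that("the correction is invariant to relabelling averaged factor levels", {
  sim <- simulate_experiment(sim_config(seed = 29, genos_per_pop = 4,
                                        plants_per_geno = 3, grid = c(6, 4),
                                        times = c(0, 1), missingness = 0))
  slots <- complete_slots(sim$table)
  d <- pheno_dims(sim$table)
  spec <- spatial_spec(d$r, d$c, factors = c(batch = "average"))
  tab0 <- slots[slots$time == 0, ]
  c1 <- correct_timepoint(quiet_fit(fit_timepoint(tab0, spec)))
  # swap level labels so the reference level changes
  tab2 <- tab0
  tab2$batch <- ifelse(tab0$batch == "B1", "Z9", "A0")
  c2 <- correct_timepoint(quiet_fit(fit_timepoint(tab2, spec)))
  expect_equal(c1$corrected, c2$corrected, tolerance = 1e-6)
})
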
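test_that("design bookkeeping matches the coefficient-count formula", {
  # PhenoArch shape: k = 4, L = 180, M = 1656, b = 13 everywhere
  d1 <- build_hier_design(series_shape(4, c(60, 60, 30, 30), 1656, 4),
                          hier_config(b_pop = 13))
  expect_equal(d1$n_coef, 23920L)
  expect_equal(d1$n_vc, 11L)
  # FIP shape: k = 7, L = 334, M = 720, b = 20, per-region genetic variances
  d2 <- build_hier_design(
    series_shape(7, c(17, 39, 114, 11, 90, 38, 25), 720, 4),
    hier_config(b_pop = 20, per_population_genetic = TRUE))
  expect_equal(d2$n_coef, 21220L)
  expect_equal(d2$n_vc, 32L)
  # smallest possible hierarchy
  d3 <- build_hier_design(series_shape(1, 1, 1, 5), hier_config(b_pop = 5))
  expect_equal(d3$n_coef, 15L)
  expect_equal(d3$n_vc, 8L)
  # property: k * b + L * b + M * b over random configurations
  set.seed(31)
  for (rep in 1:3) {
    k <- sample(1:3, 1)
    gpp <- sample(1:4, k, replace = TRUE)
    M <- sum(gpp) * sample(1:3, 1)
    b <- sample(4:8, 1)
    dd <- build_hier_design(series_shape(k, gpp, M, 4, seed = rep),
                            hier_config(b_pop = b))
    expect_equal(dd$n_coef, (k + sum(gpp) + M) * b)
  }
  expect_error(hier_config(b_pop = 3), ">= 4")
  expect_warning(hier_config(b_pop = 6, b_gen = 5), "same dimension")
})

test_that("the REML fit matches a dense brute-force oracle on a tiny instance", {
  sim <- model_matched_sim(32, b = 4, k = 2, genos_per_pop = 2,
                           plants_per_geno = 2, grid = c(3, 3),
                           times = seq(100, 135, length.out = 6))
  s <- as_corrected(sim)
  des <- build_hier_design(s, hier_config(b_pop = 4))
  fit <- quiet_fit(fit_growth(des))
  # dense oracle: explicit V, numeric REML optimisation over all variances
  X <- as.matrix(des$spec$X)
  Zs <- lapply(des$spec$random, as.matrix)
  v_hat <- c(vapply(fit$groups, function(g) fit$variances[[g]], numeric(1)),
             fit$variances$sigma2)
  dev_hat <- dense_reml_deviance(des$spec$y, X, Zs, v_hat[-length(v_hat)],
                                 v_hat[length(v_hat)])
  expect_equal(fit$deviance, dev_hat, tolerance = 1e-6)
  opt <- dense_reml_optim(des$spec$y, X, Zs, init = log(pmax(v_hat, 1e-4)))
  expect_lt(fit$deviance, opt$deviance + 1e-5)
  g <- dense_gls(des$spec$y, X, Zs, v_hat[-length(v_hat)], v_hat[length(v_hat)])
  fitted_dense <- as.numeric(X %*% g$beta) +
    Reduce(`+`, lapply(seq_along(Zs), function(i) as.numeric(Zs[[i]] %*% g$u[[i]])))
  expect_lt(max(abs(fit$fitted - fitted_dense)), 1e-5)
})

test_that("curves are additive across the hierarchy and match fitted values", {
  sim <- model_matched_sim(33, b = 6, genos_per_pop = 5, plants_per_geno = 3,
                           grid = c(6, 5))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 6)))
  grid <- seq(100, 135, length.out = 41)
  pc <- evaluate_curves(fit, "population", grid = grid, se = FALSE)
  gns <- fit$design$gtab$genotype[c(1, 7)]
  for (g in gns) {
    gc <- evaluate_curves(fit, "genotype", units = g, grid = grid, se = FALSE)
    gd <- evaluate_curves(fit, "genotype", units = g, grid = grid,
                          type = "deviation", se = FALSE)
    pop <- pc[pc$unit == gc$population[1], ]
    expect_equal(gc$estimate, pop$estimate + gd$estimate, tolerance = 1e-10)
  }
  # plant curves evaluated at observed times reproduce the fitted values
  obs <- fit$design$obs
  pl <- obs$plant[1]
  sel <- obs$plant == pl
  pcv <- evaluate_curves(fit, "plant", units = pl, grid = obs$time[sel],
                         se = FALSE)
  expect_lt(max(abs(pcv$estimate - fit$fitted[sel])), 1e-9)
  expect_error(evaluate_curves(fit, "genotype", units = "nope"), "unknown")
  expect_error(evaluate_curves(fit, "genotype", grid = c(90, 110)),
               "within the observed time range")
})

test_that("derivatives are linear in the hierarchy and match finite differences", {
  sim <- model_matched_sim(34, b = 6, genos_per_pop = 4, plants_per_geno = 2,
                           grid = c(4, 4))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 6)))
  grid <- seq(101, 134, length.out = 31)
  g <- fit$design$gtab$genotype[2]
  dg <- evaluate_derivatives(fit, "genotype", units = g, grid = grid, se = FALSE)
  dp <- evaluate_derivatives(fit, "population", units = dg$population[1],
                             grid = grid, se = FALSE)
  dd <- evaluate_derivatives(fit, "genotype", units = g, grid = grid,
                             type = "deviation", se = FALSE)
  expect_equal(dg$estimate, dp$estimate + dd$estimate, tolerance = 1e-10)
  h <- 1e-4
  up <- evaluate_curves(fit, "genotype", units = g, grid = grid + h, se = FALSE)
  dn <- evaluate_curves(fit, "genotype", units = g, grid = grid - h, se = FALSE)
  fd <- (up$estimate - dn$estimate) / (2 * h)
  expect_lt(max(abs(dg$estimate - fd)) / max(abs(fd)), 1e-6)
})

test_that("MAPE is zero for a perfect fit and scale invariant", {
  sim <- model_matched_sim(35, b = 5, genos_per_pop = 3, plants_per_geno = 2,
                           grid = c(4, 3), times = seq(100, 135, length.out = 8))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 5)))
  m1 <- mape(fit)
  expect_gt(m1, 0)
  perfect <- fit
  perfect$fitted <- perfect$spec$y
  expect_equal(mape(perfect), 0)
  scaled <- fit
  scaled$spec$y <- 10 * scaled$spec$y
  scaled$fitted <- 10 * scaled$fitted
  expect_equal(mape(scaled), m1, tolerance = 1e-12)
})

test_that("with a single curve the model collapses to one penalised P-spline", {
  set.seed(36)
  n <- 20
  tt <- seq(0, 10, length.out = n)
  y <- 5 + 2 * sin(tt / 2) + stats::rnorm(n, 0, 0.3)
  s <- tibble::tibble(population = "P1", genotype = "g1", plant = "pl1",
                      time = tt, corrected = y, weight = 1)
  fit <- quiet_fit(fit_growth(s, hier_config(b_pop = 6)))
  v <- fit$variances
  sp <- basis_spec(range(tt), 6)
  B <- bspline_basis(sp, tt)
  D <- difference_matrix(6, 2)
  lam <- v$sigma2 / (v$pop_smooth_P1 + v$gen_smooth + v$plant_smooth)
  cfit <- B %*% solve(crossprod(B) + lam * crossprod(D), crossprod(B, y))
  expect_lt(max(abs(fit$fitted - as.numeric(cfit))), 1e-6)
})

test_that("the model-implied covariance follows the hierarchy", {
  sim <- model_matched_sim(37, b = 5, genos_per_pop = 3, plants_per_geno = 2,
                           grid = c(4, 3), times = seq(100, 135, length.out = 8))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 5)))
  pt <- fit$design$ptab
  tt <- c(105, 120, 130)
  # across populations: exactly zero
  a <- pt$plant[pt$pop_i == 1][1]
  b <- pt$plant[pt$pop_i == 2][1]
  expect_equal(model_covariance(fit, a, b, tt), matrix(0, 3, 3))
  # same plant variance dominates same-genotype cross-plant covariance
  sib <- pt$plant[pt$gen_i == pt$gen_i[1]][2]
  Vaa <- model_covariance(fit, a, a, tt)
  Vab <- model_covariance(fit, a, sib, tt)
  expect_true(all(diag(Vaa) >= diag(Vab) - 1e-10))
  # same population, different genotype: only the population smooth term
  other <- pt$plant[pt$pop_i == 1 & pt$gen_i != pt$gen_i[1]][1]
  Zp <- as.matrix(phenospline:::mm_design_random(fit$design$mm_pop, tt))
  expect_equal(model_covariance(fit, a, other, tt),
               fit$variances$pop_smooth_P01 * tcrossprod(Zp),
               tolerance = 1e-10)
})

test_that("the covariance formula matches simulated curve draws", {
  # simulate plant pairs directly from the fitted variance components and
  # compare the empirical covariance with the closed form
  sim <- model_matched_sim(38, b = 5, genos_per_pop = 3, plants_per_geno = 2,
                           grid = c(4, 3), times = seq(100, 135, length.out = 8))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 5)))
  d <- fit$design
  v <- fit$variances
  tt <- c(110, 125)
  Xg <- as.matrix(phenospline:::mm_design_fixed(d$mm_gen, tt))
  Zp <- as.matrix(phenospline:::mm_design_random(d$mm_pop, tt))
  Zg <- as.matrix(phenospline:::mm_design_random(d$mm_gen, tt))
  Zl <- as.matrix(phenospline:::mm_design_random(d$mm_plant, tt))
  nb <- ncol(Zp)
  set.seed(39)
  nrep <- 2000
  y1 <- matrix(0, nrep, 2); y2 <- matrix(0, nrep, 2)
  for (r in seq_len(nrep)) {
    upop <- stats::rnorm(nb, 0, sqrt(v$pop_smooth_P01))
    bg <- c(stats::rnorm(1, 0, sqrt(v$gen_int)), stats::rnorm(1, 0, sqrt(v$gen_slope)))
    ug <- stats::rnorm(ncol(Zg), 0, sqrt(v$gen_smooth))
    shared <- Zp %*% upop + Xg %*% bg + Zg %*% ug
    own <- function() {
      bp <- c(stats::rnorm(1, 0, sqrt(v$plant_int)), stats::rnorm(1, 0, sqrt(v$plant_slope)))
      Xg %*% bp + Zl %*% stats::rnorm(ncol(Zl), 0, sqrt(v$plant_smooth)) +
        stats::rnorm(2, 0, sqrt(v$sigma2))
    }
    y1[r, ] <- shared + own(); y2[r, ] <- shared + own()
  }
  emp <- stats::cov(y1, y2)
  # two plants of the same genotype: shared terms only
  pt <- fit$design$ptab
  a <- pt$plant[1]; sib <- pt$plant[pt$gen_i == pt$gen_i[1]][2]
  Vab <- model_covariance(fit, a, sib, tt)
  # elementwise Monte-Carlo standard errors of the cross products
  for (i in 1:2) for (j in 1:2) {
    mc_se <- stats::sd(y1[, i] * y2[, j]) / sqrt(nrep)
    expect_lt(abs(emp[i, j] - Vab[i, j]), 3 * mc_se)
  }
})

test_that("deleting 20% of the observations barely moves genotype curves", {
  sim <- model_matched_sim(40, b = 6, genos_per_pop = 5, plants_per_geno = 4,
                           grid = c(8, 5))
  s <- as_corrected(sim)
  fit_full <- quiet_fit(fit_growth(s, hier_config(b_pop = 6)))
  set.seed(41)
  s20 <- s[stats::runif(nrow(s)) > 0.2, ]
  fit_20 <- quiet_fit(fit_growth(s20, hier_config(b_pop = 6)))
  grid <- seq(101, 134, length.out = 21)
  c_full <- evaluate_curves(fit_full, "genotype", grid = grid)
  c_20 <- evaluate_curves(fit_20, "genotype", grid = grid, se = FALSE)
  halfwidth <- 1.96 * c_full$se
  frac <- mean(abs(c_full$estimate - c_20$estimate) < halfwidth)
  expect_gt(frac, 0.9)
})

test_that("both readings of the stage-1 weights are available", {
  sim <- model_matched_sim(42, b = 5, genos_per_pop = 3, plants_per_geno = 2,
                           grid = c(4, 3), times = seq(100, 135, length.out = 8))
  s <- as_corrected(sim)
  s$weight <- stats::runif(nrow(s), 0.5, 2)
  f1 <- quiet_fit(fit_growth(s, hier_config(b_pop = 5)))
  f2 <- quiet_fit(fit_growth(s, hier_config(b_pop = 5, weight_mode = "variance")))
  expect_false(isTRUE(all.equal(f1$fitted, f2$fitted)))
  expect_equal(f1$spec$weights, s$weight[!is.na(s$corrected)])
  expect_equal(f2$spec$weights, 1 / s$weight[!is.na(s$corrected)])
})

test_that("tidy and glance report the fit structure", {
  sim <- model_matched_sim(43, b = 5, genos_per_pop = 3, plants_per_geno = 2,
                           grid = c(4, 3), times = seq(100, 135, length.out = 8))
  fit <- quiet_fit(fit_growth(as_corrected(sim), hier_config(b_pop = 5)))
  td <- tidy(fit)
  expect_equal(nrow(td), fit$design$n_vc)
  expect_true(all(td$variance > 0))
  gl <- glance(fit)
  expect_equal(gl$n_coefficients, fit$design$n_coef)
  expect_equal(gl$k, 2)
})
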
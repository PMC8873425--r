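#' Configuration of the hierarchical growth model
#'
#' @param b_pop basis dimension for the population curves (cubic B-splines,
#'   second-order difference penalty).
#' @param b_gen,b_plant basis dimensions for the genotype and plant deviation
#'   curves. The same dimension at all three levels is recommended and is the
#'   default; overriding it triggers a warning.
#' @param per_population_genetic separate genotype-level intercept/slope/
#'   smooth variances per population.
#' @param per_genotype_plant separate plant-level variances per genotype
#'   (needs many plants per genotype; default off).
#' @param weight_mode how stage-1 weights enter the residual covariance:
#'   `"precision"` (default) treats them as inverse variances,
#'   residual covariance `sigma^2 * diag(1/w)`; `"variance"` is the literal
#'   reading `sigma^2 * diag(w)`.
#' @param reml_tol,max_iter,variance_floor REML controls (see [reml_fit()]).
#' @param grid_n default evaluation grid resolution.
#' @export
hier_config <- function(b_pop = 13, b_gen = NULL, b_plant = NULL,
                        per_population_genetic = FALSE,
                        per_genotype_plant = FALSE,
                        weight_mode = c("precision", "variance"),
                        reml_tol = 1e-8, max_iter = 200L,
                        variance_floor = NULL, grid_n = 401L) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(b_gen)) b_gen <- b_pop
  if (is.null(b_plant)) b_plant <- b_pop
  if (b_gen != b_pop || b_plant != b_pop) {
    warning("using different basis dimensions across hierarchy levels; ",
            "the same dimension at all levels is recommended")
  }
  if (min(b_pop, b_gen, b_plant) < 4) stop("basis dimensions must be >= 4")
  structure(list(b_pop = as.integer(b_pop), b_gen = as.integer(b_gen),
                 b_plant = as.integer(b_plant),
                 per_population_genetic = per_population_genetic,
                 per_genotype_plant = per_genotype_plant,
                 weight_mode = weight_mode, reml_tol = reml_tol,
                 max_iter = as.integer(max_iter),
                 variance_floor = variance_floor,
                 grid_n = as.integer(grid_n)),
            class = "hier_config")
}

#' Build the three-level hierarchical growth design
#'
#' Assembles the Kronecker-structured sparse design of the nested growth
#' model: a fixed population intercept/slope block, random population smooth
#' blocks (one variance per population), random genotype intercept, slope and
#' smooth blocks (variances shared or per population), and random plant
#' intercept, slope and smooth blocks. Missing observations are dropped from
#' the rows; every unit keeps its coefficients. The total coefficient count is
#' `k * b_pop + L * b_gen + M * b_plant`.
#'
#' @param series a `corrected_series` from [run_stage1()], or any data frame
#'   with columns population, genotype, plant, time, corrected (and
#'   optionally weight; missing rows may be flagged by `missing` or carry
#'   `NA` corrected values).
#' @param config a [hier_config()].
#' @return an object of class `hier_design`.
#' @export
build_hier_design <- function(series, config = hier_config()) {
  stopifnot(inherits(config, "hier_config"))
  df <- tibble::as_tibble(series)
  if (!"corrected" %in% names(df)) stop("series must have a 'corrected' column")
  if (!"weight" %in% names(df)) df$weight <- 1
  obs <- df[!is.na(df$corrected), , drop = FALSE]
  obs$weight[is.na(obs$weight)] <- 1
  # order by population, genotype, plant, time
  obs <- dplyr::arrange(obs, .data$population, .data$genotype, .data$plant,
                        .data$time)
  pops <- unique(obs$population)
  gtab <- dplyr::distinct(obs, .data$population, .data$genotype)
  ptab <- dplyr::distinct(obs, .data$population, .data$genotype, .data$plant)
  k <- length(pops); L <- nrow(gtab); M <- nrow(ptab)
  obs$pop_i <- match(obs$population, pops)
  obs$gen_i <- match(obs$genotype, gtab$genotype)
  obs$plant_i <- match(obs$plant, ptab$plant)
  gtab$pop_i <- match(gtab$population, pops)
  ptab$gen_i <- match(ptab$genotype, gtab$genotype)
  ptab$pop_i <- match(ptab$population, pops)

  times <- sort(unique(obs$time))
  tr <- range(times)
  if (tr[1] == tr[2]) stop("need at least two distinct times")
  obs$time_i <- match(obs$time, times)
  N <- nrow(obs)

  mk <- function(b) mm_transform(basis_spec(tr, b))
  mm_pop <- mk(config$b_pop); mm_gen <- mk(config$b_gen)
  mm_plant <- mk(config$b_plant)
  Xt <- mm_design_fixed(mm_pop, times) # identical [1 | ts] for all levels
  Zpop <- mm_design_random(mm_pop, times)
  Zgen <- mm_design_random(mm_gen, times)
  Zplant <- mm_design_random(mm_plant, times)

  rows_of <- seq_len(N)
  ti <- obs$time_i
  # unit-indexed intercept/slope block: N x (2 * n_units), cols (2j-1, 2j)
  int_slope_block <- function(unit_i, n_units) {
    Matrix::sparseMatrix(
      i = c(rows_of, rows_of), j = c(2L * unit_i - 1L, 2L * unit_i),
      x = c(Xt[ti, 1], Xt[ti, 2]), dims = c(N, 2L * n_units))
  }
  # unit-indexed smooth block: N x (n_units * nb)
  smooth_block <- function(unit_i, n_units, Zl) {
    nb <- ncol(Zl)
    Matrix::sparseMatrix(
      i = rep(rows_of, nb),
      j = rep((unit_i - 1L) * nb, nb) + rep(seq_len(nb), each = N),
      x = as.numeric(Zl[ti, ]), dims = c(N, n_units * nb))
  }

  Xfix <- int_slope_block(obs$pop_i, k)

  random <- list(); labels <- character(0)
  col_groups <- list() # per-label global column ranges, filled after layout
  # population smooth: one block (and variance) per population
  nbp <- ncol(Zpop)
  Zps <- smooth_block(obs$pop_i, k, Zpop)
  for (p in seq_len(k)) {
    lab <- paste0("pop_smooth_", pops[p])
    random[[lab]] <- Zps[, (p - 1L) * nbp + seq_len(nbp), drop = FALSE]
  }
  # genotype intercept/slope/smooth (gtab row g is genotype index g)
  Zgi <- int_slope_block(obs$gen_i, L)
  Zgs <- smooth_block(obs$gen_i, L, Zgen)
  add_split <- function(random, base, Mint, unit_pop, per_group, stride,
                        groups_of_unit) {
    # split columns of Mint into variance groups; unit j owns columns
    # (j-1)*stride + 1..stride
    if (!per_group) {
      random[[base]] <- Mint
    } else {
      for (g in unique(groups_of_unit)) {
        units <- which(groups_of_unit == g)
        cols <- as.vector(outer(seq_len(stride), (units - 1L) * stride, `+`))
        random[[paste0(base, "_", g)]] <- Mint[, sort(cols), drop = FALSE]
      }
    }
    random
  }
  gen_groups <- gtab$population
  random <- add_split(random, "gen_int",
                      Zgi[, seq(1, 2 * L, by = 2), drop = FALSE],
                      NULL, config$per_population_genetic, 1L, gen_groups)
  random <- add_split(random, "gen_slope",
                      Zgi[, seq(2, 2 * L, by = 2), drop = FALSE],
                      NULL, config$per_population_genetic, 1L, gen_groups)
  random <- add_split(random, "gen_smooth", Zgs, NULL,
                      config$per_population_genetic, ncol(Zgen), gen_groups)
  plant_groups <- ptab$genotype
  Zpi <- int_slope_block(obs$plant_i, M)
  Zpsm <- smooth_block(obs$plant_i, M, Zplant)
  random <- add_split(random, "plant_int",
                      Zpi[, seq(1, 2 * M, by = 2), drop = FALSE],
                      NULL, config$per_genotype_plant, 1L, plant_groups)
  random <- add_split(random, "plant_slope",
                      Zpi[, seq(2, 2 * M, by = 2), drop = FALSE],
                      NULL, config$per_genotype_plant, 1L, plant_groups)
  random <- add_split(random, "plant_smooth", Zpsm, NULL,
                      config$per_genotype_plant, ncol(Zplant), plant_groups)

  w <- obs$weight
  lmm_w <- if (config$weight_mode == "precision") w else 1 / w
  spec <- lmm_spec(obs$corrected, Xfix, random = random, weights = lmm_w)

  # global column layout: fixed block first, then groups in insertion order
  offs <- ncol(Xfix)
  colmap <- list()
  for (lab in names(random)) {
    colmap[[lab]] <- offs + seq_len(ncol(random[[lab]]))
    offs <- offs + ncol(random[[lab]])
  }
  n_coef <- offs
  stopifnot(n_coef == k * config$b_pop + L * config$b_gen + M * config$b_plant)

  # per-unit coefficient lookup tables
  unit_cols <- .build_unit_cols(pops, gtab, ptab, colmap, config,
                                nbp, ncol(Zgen), ncol(Zplant))

  structure(list(
    spec = spec, config = config, obs = obs,
    pops = pops, gtab = gtab, ptab = ptab,
    k = k, L = L, M = M, times = times,
    mm_pop = mm_pop, mm_gen = mm_gen, mm_plant = mm_plant,
    colmap = colmap, unit_cols = unit_cols,
    n_coef = n_coef,
    n_vc = length(random) + 1L
  ), class = "hier_design")
}

# coefficient positions for every unit at each level
.build_unit_cols <- function(pops, gtab, ptab, colmap, config,
                             nbp, nbg, nbl) {
  k <- length(pops); L <- nrow(gtab); M <- nrow(ptab)
  pop_fixed <- lapply(seq_len(k), function(p) c(2L * p - 1L, 2L * p))
  pop_smooth <- lapply(seq_len(k), function(p)
    colmap[[paste0("pop_smooth_", pops[p])]])
  within_group_pos <- function(groups) {
    pos <- integer(length(groups))
    for (g in unique(groups)) pos[groups == g] <- seq_len(sum(groups == g))
    pos
  }
  if (config$per_population_genetic) {
    gpos <- within_group_pos(gtab$population)
    gen_int <- mapply(function(g, pp) colmap[[paste0("gen_int_", pp)]][g],
                      gpos, gtab$population)
    gen_slope <- mapply(function(g, pp) colmap[[paste0("gen_slope_", pp)]][g],
                        gpos, gtab$population)
    gen_smooth <- mapply(function(g, pp)
      colmap[[paste0("gen_smooth_", pp)]][(g - 1L) * nbg + seq_len(nbg)],
      gpos, gtab$population, SIMPLIFY = FALSE)
  } else {
    gen_int <- colmap$gen_int
    gen_slope <- colmap$gen_slope
    gen_smooth <- lapply(seq_len(L), function(g)
      colmap$gen_smooth[(g - 1L) * nbg + seq_len(nbg)])
  }
  if (config$per_genotype_plant) {
    ppos <- within_group_pos(ptab$genotype)
    plant_int <- mapply(function(i, gg) colmap[[paste0("plant_int_", gg)]][i],
                        ppos, ptab$genotype)
    plant_slope <- mapply(function(i, gg) colmap[[paste0("plant_slope_", gg)]][i],
                          ppos, ptab$genotype)
    plant_smooth <- mapply(function(i, gg)
      colmap[[paste0("plant_smooth_", gg)]][(i - 1L) * nbl + seq_len(nbl)],
      ppos, ptab$genotype, SIMPLIFY = FALSE)
  } else {
    plant_int <- colmap$plant_int
    plant_slope <- colmap$plant_slope
    plant_smooth <- lapply(seq_len(M), function(i)
      colmap$plant_smooth[(i - 1L) * nbl + seq_len(nbl)])
  }
  list(pop_fixed = pop_fixed, pop_smooth = pop_smooth,
       gen_int = gen_int, gen_slope = gen_slope, gen_smooth = gen_smooth,
       plant_int = plant_int, plant_slope = plant_slope,
       plant_smooth = plant_smooth)
}

#' Fit the hierarchical growth model
#'
#' REML fit of the three-level P-spline growth model via the package's sparse
#' Henderson/Harville engine, with the stage-1 precision weights in the
#' residual covariance.
#'
#' @param design a [build_hier_design()] result (or a `corrected_series`,
#'   in which case the design is built with `config`).
#' @param config used when `design` is a series.
#' @param ... passed to [reml_fit()] (e.g. `init`).
#' @return an object of class `hier_fit` (also `lmm_fit`).
#' @export
fit_growth <- function(design, config = hier_config(), ...) {
  if (!inherits(design, "hier_design")) {
    design <- build_hier_design(design, config)
  }
  cfg <- design$config
  fit <- reml_fit(design$spec, tol = cfg$reml_tol, max_iter = cfg$max_iter, ...)
  fit$design <- design
  class(fit) <- c("hier_fit", class(fit))
  fit
}

#' @exportS3Method base::print
print.hier_fit <- function(x, ...) {
  d <- x$design
  cat("<hier_fit> three-level P-spline growth model\n")
  cat(sprintf("  %d populations, %d genotypes, %d plants; %d observations\n",
              d$k, d$L, d$M, d$spec$N))
  cat(sprintf("  %d coefficients, %d variance components; -2 REML loglik %.4f\n",
              d$n_coef, d$n_vc, x$deviance))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

# stacked coefficient solution in global column order
.hier_sol <- function(fit) c(fit$beta, unlist(fit$u, use.names = FALSE))

# sparse evaluation map for one unit at one level
.unit_map <- function(design, level, unit, grid, deriv = 0L,
                      type = c("curve", "deviation")) {
  type <- match.arg(type)
  uc <- design$unit_cols
  ng <- length(grid)
  Xg <- mm_design_fixed(design$mm_pop, grid, deriv = deriv)
  ii <- c(); jj <- c(); xx <- c()
  add <- function(cols, vals) {
    ii <<- c(ii, rep(seq_len(ng), length(cols)))
    jj <<- c(jj, rep(cols, each = ng))
    xx <<- c(xx, as.numeric(vals))
  }
  add_pop <- function(p) {
    add(uc$pop_fixed[[p]], Xg)
    add(uc$pop_smooth[[p]],
        mm_design_random(design$mm_pop, grid, deriv = deriv))
  }
  add_gen <- function(g) {
    add(c(uc$gen_int[g], uc$gen_slope[g]), Xg)
    add(uc$gen_smooth[[g]],
        mm_design_random(design$mm_gen, grid, deriv = deriv))
  }
  add_plant <- function(i) {
    add(c(uc$plant_int[i], uc$plant_slope[i]), Xg)
    add(uc$plant_smooth[[i]],
        mm_design_random(design$mm_plant, grid, deriv = deriv))
  }
  if (level == "population") {
    p <- match(unit, design$pops)
    if (is.na(p)) stop("unknown population: ", unit)
    add_pop(p) # population deviation == population curve
  } else if (level == "genotype") {
    g <- match(unit, design$gtab$genotype)
    if (is.na(g)) stop("unknown genotype: ", unit)
    if (type == "curve") add_pop(design$gtab$pop_i[g])
    add_gen(g)
  } else if (level == "plant") {
    i <- match(unit, design$ptab$plant)
    if (is.na(i)) stop("unknown plant: ", unit)
    if (type == "curve") {
      g <- design$ptab$gen_i[i]
      add_pop(design$ptab$pop_i[i])
      add_gen(g)
    }
    add_plant(i)
  } else stop("level must be population, genotype or plant")
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(ng, design$n_coef))
}

#' Evaluate estimated curves with pointwise confidence bands
#'
#' Returns the estimated curve of each requested unit on a time grid:
#' population curves f_p, genotype curves f_p + f_pg (or genotype deviations
#' f_pg), plant curves f_p + f_pg + f_pgi (or plant deviations). Pointwise
#' standard errors come from the prediction error variance of the
#' corresponding coefficient combination; 95% bands use estimate +/- 1.96 se.
#'
#' @param fit a [fit_growth()] result.
#' @param level `"population"`, `"genotype"` or `"plant"`.
#' @param units unit ids; default all units at the level.
#' @param grid evaluation times (within the observed range); default
#'   `config$grid_n` equally spaced points.
#' @param type `"curve"` or `"deviation"`.
#' @param se compute pointwise standard errors (skip for speed).
#' @param ci_mult multiplier for the confidence bands (1.96 = 95%).
#' @return a `curve_set` tibble: level, unit, population, time, estimate,
#'   se, lower, upper, kind.
#' @export
evaluate_curves <- function(fit, level = "genotype", units = NULL,
                            grid = NULL, type = c("curve", "deviation"),
                            se = TRUE, ci_mult = 1.96) {
  type <- match.arg(type)
  .eval_level(fit, level, units, grid, type, se, ci_mult, deriv = 0L)
}

#' First derivatives of estimated curves
#'
#' Same contract as [evaluate_curves()] but rows evaluate the first
#' derivative of the level's curve (or deviation), via the derivative of the
#' B-spline basis applied to the same coefficients.
#'
#' @inheritParams evaluate_curves
#' @export
evaluate_derivatives <- function(fit, level = "genotype", units = NULL,
                                 grid = NULL, type = c("curve", "deviation"),
                                 se = TRUE, ci_mult = 1.96) {
  type <- match.arg(type)
  .eval_level(fit, level, units, grid, type, se, ci_mult, deriv = 1L)
}

.eval_level <- function(fit, level, units, grid, type, se, ci_mult, deriv) {
  design <- fit$design
  if (is.null(grid)) {
    grid <- seq(design$times[1], design$times[length(design$times)],
                length.out = design$config$grid_n)
  }
  tr <- range(design$times)
  if (any(grid < tr[1] - 1e-9 | grid > tr[2] + 1e-9)) {
    stop("evaluation grid must lie within the observed time range")
  }
  if (is.null(units)) {
    units <- switch(level, population = design$pops,
                    genotype = design$gtab$genotype,
                    plant = design$ptab$plant,
                    stop("level must be population, genotype or plant"))
  }
  sol <- .hier_sol(fit)
  maps <- lapply(units, function(u)
    .unit_map(design, level, u, grid, deriv = deriv, type = type))
  Lmat <- do.call(rbind, maps)
  est <- as.numeric(Lmat %*% sol)
  sev <- if (se) sqrt(pmax(prediction_error_variance(fit, Lmat,
                                                     diag_only = TRUE), 0))
         else NA_real_
  popof <- switch(level,
    population = units,
    genotype = design$gtab$population[match(units, design$gtab$genotype)],
    plant = design$ptab$population[match(units, design$ptab$plant)])
  kind <- if (deriv == 0L) type else paste0(
    if (type == "curve") "" else "deviation_", "first_derivative")
  out <- tibble::tibble(
    level = level, unit = rep(units, each = length(grid)),
    population = rep(popof, each = length(grid)),
    time = rep(grid, length(units)),
    estimate = est, se = sev,
    lower = est - ci_mult * sev, upper = est + ci_mult * sev,
    kind = kind
  )
  class(out) <- unique(c("curve_set", class(out)))
  out
}

#' Mean absolute percentage error of the plant-curve fit
#'
#' MAPE (in percent) between the corrected observations and the fitted plant
#' curves at the observed times, over records with |y| above a relative
#' floor `eps = 1e-8 * max |y|`.
#'
#' @param fit a `hier_fit`.
#' @return percentage (scalar).
#' @export
mape <- function(fit) {
  y <- fit$spec$y
  eps <- 1e-8 * max(abs(y))
  keep <- abs(y) >= eps
  if (!any(keep)) stop("all corrected values are (numerically) zero")
  100 * mean(abs(y[keep] - fit$fitted[keep]) / abs(y[keep]))
}

#' Model-implied covariance between two plant curves
#'
#' Evaluates the hierarchy-induced covariance between the corrected series of
#' two plants at given times: zero across populations; the shared population
#' smooth term within a population; plus the genotype terms within a
#' genotype; plus the plant terms and the residual variance for the same
#' plant. Residual variance at a time uses that plant's stage-1 weight when
#' the time matches an observed record (weight 1 otherwise).
#'
#' @param fit a `hier_fit`.
#' @param plant_a,plant_b plant ids.
#' @param times evaluation times.
#' @return a `length(times) x length(times)` covariance matrix.
#' @export
model_covariance <- function(fit, plant_a, plant_b, times) {
  design <- fit$design
  ia <- match(plant_a, design$ptab$plant)
  ib <- match(plant_b, design$ptab$plant)
  if (is.na(ia) || is.na(ib)) stop("unknown plant id")
  pa <- design$ptab$pop_i[ia]; pb <- design$ptab$pop_i[ib]
  nt <- length(times)
  V <- matrix(0, nt, nt)
  if (pa != pb) return(V)
  vv <- fit$variances
  pop <- design$pops[pa]
  Zp <- as.matrix(mm_design_random(design$mm_pop, times))
  V <- V + vv[[paste0("pop_smooth_", pop)]] * tcrossprod(Zp)
  ga <- design$ptab$gen_i[ia]; gb <- design$ptab$gen_i[ib]
  if (ga != gb) return(V)
  geno <- design$gtab$genotype[ga]
  lab <- function(base, per, suffix) {
    if (per) paste0(base, "_", suffix) else base
  }
  per_g <- design$config$per_population_genetic
  Xg <- as.matrix(mm_design_fixed(design$mm_gen, times))
  Zg <- as.matrix(mm_design_random(design$mm_gen, times))
  Sg <- diag(c(vv[[lab("gen_int", per_g, pop)]],
               vv[[lab("gen_slope", per_g, pop)]]))
  V <- V + Xg %*% Sg %*% t(Xg) + vv[[lab("gen_smooth", per_g, pop)]] * tcrossprod(Zg)
  if (ia != ib) return(V)
  per_p <- design$config$per_genotype_plant
  Xl <- as.matrix(mm_design_fixed(design$mm_plant, times))
  Zl <- as.matrix(mm_design_random(design$mm_plant, times))
  Sl <- diag(c(vv[[lab("plant_int", per_p, geno)]],
               vv[[lab("plant_slope", per_p, geno)]]))
  V <- V + Xl %*% Sl %*% t(Xl) + vv[[lab("plant_smooth", per_p, geno)]] * tcrossprod(Zl)
  # residual: sigma^2 / w (precision mode) at matching observed times
  wob <- design$obs[design$obs$plant_i == ia, c("time", "weight")]
  wt <- rep(1, nt)
  mm <- match(round(times, 9), round(wob$time, 9))
  wt[!is.na(mm)] <- wob$weight[mm[!is.na(mm)]]
  rv <- if (design$config$weight_mode == "precision") vv$sigma2 / wt
        else vv$sigma2 * wt
  V + diag(rv, nt)
}

#' @rdname tidy.lmm_fit
#' @export
tidy.hier_fit <- function(x, ...) {
  out <- NextMethod()
  dplyr::rename(out, variance_component = "component")
}

#' @rdname tidy.lmm_fit
#' @export
glance.hier_fit <- function(x, ...) {
  g <- NextMethod()
  d <- x$design
  dplyr::mutate(g, k = d$k, L = d$L, M = d$M,
                n_coefficients = d$n_coef, mape = mape(x))
}
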
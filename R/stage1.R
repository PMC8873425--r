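#' Spatial model specification for the per-time correction
#'
#' Describes the per-time-point spatial mixed model: a PS-ANOVA tensor-product
#' P-spline surface over the (row, col) grid, random row and column effects,
#' genotype as random with (optionally) one genetic variance per population,
#' and role-tagged design factors. Factor roles: `"condition"` factors are
#' fixed effects retained in the corrected phenotype; `"average"` factors are
#' fixed effects averaged over their levels in the correction; `"random"`
#' factors are random nuisance effects ignored by the correction.
#'
#' @param rows,cols grid dimensions (r, c).
#' @param b_row,b_col marginal B-spline dimensions for the surface; default
#'   one basis function per row/column as in typical platform analyses,
#'   capped below by 4.
#' @param nested use nested (half-dimension) marginal bases for the
#'   smooth-by-smooth interaction block.
#' @param factors named character vector of design-factor roles (see above).
#' @param per_population_genetic one genetic variance per population.
#' @param genotype_as `"random"` (default) or `"fixed"`.
#' @param reml_control list passed to [reml_fit()] (`tol`, `max_iter`).
#' @export
spatial_spec <- function(rows, cols, b_row = NULL, b_col = NULL,
                         nested = TRUE, factors = NULL,
                         per_population_genetic = TRUE,
                         genotype_as = c("random", "fixed"),
                         reml_control = list()) {
  genotype_as <- match.arg(genotype_as)
  if (is.null(b_row)) b_row <- max(4L, min(rows, 60L))
  if (is.null(b_col)) b_col <- max(4L, min(cols, 60L))
  structure(list(rows = rows, cols = cols,
                 b_row = as.integer(b_row), b_col = as.integer(b_col),
                 nested = nested, factors = factors,
                 per_population_genetic = per_population_genetic,
                 genotype_as = genotype_as, reml_control = reml_control),
            class = "spatial_spec")
}

# orthogonalise Z against fixed polynomial part F and centre columns
.orth <- function(Z, Fmat) {
  Z <- as.matrix(Z)
  Z - Fmat %*% solve(crossprod(Fmat), crossprod(Fmat, Z))
}

#' Build the PS-ANOVA spatial design blocks
#'
#' Decomposes the bivariate surface f(u, v) into a fixed polynomial part
#' `{1, u, v, uv}` and five random smooth blocks — f(u), f(v), u * smooth(v),
#' smooth(u) * v and smooth(u) * smooth(v) — each carrying its own variance
#' parameter. Smooth blocks are column-centred and orthogonalised against the
#' polynomial part; the smooth-by-smooth block uses nested (half-dimension)
#' marginal bases when `spec$nested` is set.
#'
#' @param spec a [spatial_spec()].
#' @param u,v row and column coordinates (1-based, on the grid).
#' @return list with `fixed` (matrix, no intercept column: `u`, `v`, `uv`)
#'   and `random` (named list of blocks).
#' @export
build_spatial_blocks <- function(spec, u, v) {
  if (any(u < 1 | u > spec$rows | v < 1 | v > spec$cols)) {
    stop("coordinates outside the ", spec$rows, " x ", spec$cols, " grid")
  }
  us <- (u - 1) / max(spec$rows - 1, 1)
  vs <- (v - 1) / max(spec$cols - 1, 1)
  F <- cbind(1, us, vs, us * vs)

  mm_u <- mm_transform(basis_spec(c(1, spec$rows), spec$b_row))
  mm_v <- mm_transform(basis_spec(c(1, spec$cols), spec$b_col))
  Zu <- mm_design_random(mm_u, u)
  Zv <- mm_design_random(mm_v, v)
  half <- function(b) max(4L, as.integer(ceiling(b / 2)))
  if (spec$nested) {
    mm_un <- mm_transform(basis_spec(c(1, spec$rows), half(spec$b_row)))
    mm_vn <- mm_transform(basis_spec(c(1, spec$cols), half(spec$b_col)))
    Zun <- mm_design_random(mm_un, u)
    Zvn <- mm_design_random(mm_vn, v)
  } else {
    Zun <- Zu; Zvn <- Zv
  }
  # row-wise tensor (face-splitting) product for the smooth x smooth block
  rowkron <- function(A, B) {
    A[, rep(seq_len(ncol(A)), each = ncol(B)), drop = FALSE] *
      B[, rep(seq_len(ncol(B)), times = ncol(A)), drop = FALSE]
  }
  blocks <- list(
    spat_u = Zu,
    spat_v = Zv,
    spat_u_lin_v = Zu * vs,
    spat_lin_u_v = Zv * us,
    spat_uv = rowkron(Zun, Zvn)
  )
  blocks <- lapply(blocks, .orth, Fmat = F)
  # rescale each block to mean unit column norm: an equivalent
  # reparameterisation that keeps the variance parameters on comparable
  # scales and speeds up the REML fixed point
  blocks <- lapply(blocks, function(Z) {
    s <- sqrt(mean(colSums(Z^2)))
    if (s > 0) Z / s else Z
  })
  list(fixed = F[, -1, drop = FALSE], random = blocks)
}

#' Fit the spatial model at one measurement time
#'
#' Fits the per-time mixed model: intercept, population (and any condition
#' factors) and average-over factors as fixed effects; row, column, random
#' design factors, genotype (one variance per population when requested) and
#' the five PS-ANOVA surface blocks as random effects. Plants with missing
#' values at this time are excluded from the fit.
#'
#' @param table_t rows of a validated table at a single time.
#' @param spec a [spatial_spec()].
#' @return an object of class `stage1_fit`.
#' @export
fit_timepoint <- function(table_t, spec) {
  obs <- table_t[!is.na(table_t$value), , drop = FALSE]
  if (nrow(obs) == 0) {
    stop("all values missing at time ", unique(table_t$time)[1])
  }
  y <- obs$value
  Mt <- nrow(obs)
  pops <- sort(unique(obs$population))
  # fixed part: intercept + population (reference coding) + factor dummies
  X <- matrix(1, Mt, 1, dimnames = list(NULL, "(Intercept)"))
  pop_cols <- integer(0)
  if (length(pops) > 1) {
    Pd <- stats::model.matrix(~ factor(population, levels = pops),
                              data = obs)[, -1, drop = FALSE]
    pop_cols <- ncol(X) + seq_len(ncol(Pd))
    X <- cbind(X, Pd)
  }
  factors <- spec$factors
  avg_cols <- list(); cond_cols <- integer(0)
  rand_factors <- character(0)
  if (!is.null(factors)) {
    for (f in names(factors)) {
      lv <- sort(unique(as.character(obs[[f]])))
      role <- factors[[f]]
      if (role == "random") { rand_factors <- c(rand_factors, f); next }
      if (length(lv) < 2) next
      Fd <- stats::model.matrix(~ factor(obs[[f]], levels = lv))[, -1, drop = FALSE]
      cols <- ncol(X) + seq_len(ncol(Fd))
      X <- cbind(X, Fd)
      if (role == "average") avg_cols[[f]] <- list(cols = cols, c_r = length(lv))
      else cond_cols <- c(cond_cols, cols)
    }
  }

  random <- list()
  fac_sparse <- function(x) {
    lv <- sort(unique(x))
    Matrix::sparseMatrix(i = seq_along(x), j = match(x, lv),
                         x = 1, dims = c(length(x), length(lv)),
                         dimnames = list(NULL, lv))
  }
  random$row_effect <- fac_sparse(as.character(obs$row))
  random$col_effect <- fac_sparse(as.character(obs$col))
  for (f in rand_factors) random[[paste0("rf_", f)]] <- fac_sparse(as.character(obs[[f]]))

  # genotype blocks, one per population when per-population variances requested
  geno_info <- list()
  if (spec$genotype_as == "random") {
    if (spec$per_population_genetic) {
      for (p in pops) {
        sel <- obs$population == p
        gl <- sort(unique(obs$genotype[sel]))
        Zg <- Matrix::sparseMatrix(
          i = which(sel), j = match(obs$genotype[sel], gl), x = 1,
          dims = c(Mt, length(gl)), dimnames = list(NULL, gl))
        lab <- paste0("geno_", p)
        random[[lab]] <- Zg
        geno_info[[lab]] <- gl
      }
    } else {
      gl <- sort(unique(obs$genotype))
      random$geno <- fac_sparse(obs$genotype)
      geno_info$geno <- gl
    }
  } else {
    gl <- sort(unique(obs$genotype))
    # fixed genotype, centred coding within the table (sum contrasts)
    Gd <- stats::model.matrix(
      ~ factor(genotype, levels = gl), data = obs,
      contrasts.arg = list(`factor(genotype, levels = gl)` = "contr.sum")
    )[, -1, drop = FALSE]
    geno_fixed_cols <- ncol(X) + seq_len(ncol(Gd))
    X <- cbind(X, Gd)
    geno_info$fixed <- gl
  }

  sp_blocks <- build_spatial_blocks(spec, obs$row, obs$col)
  X <- cbind(X, sp_blocks$fixed)
  random <- c(random, sp_blocks$random)

  lmm <- lmm_spec(y, X, random = random)
  ctrl <- spec$reml_control
  fit <- reml_fit(lmm,
                  tol = ctrl$tol %||% 1e-8,
                  max_iter = ctrl$max_iter %||% 200L)

  structure(list(
    fit = fit, spec = spec, obs = obs, time = obs$time[1],
    pops = pops, pop_cols = pop_cols, avg_cols = avg_cols,
    cond_cols = cond_cols, geno_info = geno_info,
    geno_fixed_cols = if (spec$genotype_as == "fixed") geno_fixed_cols else NULL
  ), class = "stage1_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coefficient map of the prediction p-hat (the kept terms of the
# correction) for the observed
# plants: intercept + averaged design factors + population (+ condition
# factors) + genotype effects. Columns follow the fitted coefficient layout.
.phat_map <- function(sfit) {
  fit <- sfit$fit
  Mt <- nrow(sfit$obs)
  ntot <- fit$p + sum(unlist(fit$q_g))
  A <- matrix(0, Mt, ntot)
  # fixed columns survive rank-dropping; map through kept_fixed
  fcol <- function(orig) match(orig, fit$kept_fixed)
  A[, fcol(1)] <- 1
  for (f in names(sfit$avg_cols)) {
    ac <- sfit$avg_cols[[f]]
    kc <- fcol(ac$cols)
    A[, kc[!is.na(kc)]] <- 1 / ac$c_r
  }
  for (cset in list(sfit$pop_cols, sfit$cond_cols, sfit$geno_fixed_cols)) {
    if (length(cset)) {
      kc <- fcol(cset)
      ok <- !is.na(kc)
      A[, kc[ok]] <- as.matrix(fit$spec$X[, cset[ok], drop = FALSE])
    }
  }
  if (sfit$spec$genotype_as == "random") {
    for (lab in names(sfit$geno_info)) {
      gl <- sfit$geno_info[[lab]]
      idx <- fit$idx[[lab]]
      pos <- match(sfit$obs$genotype, gl)
      ok <- !is.na(pos)
      A[cbind(which(ok), idx[pos[ok]])] <- 1
    }
  }
  A
}

#' Phenotype correction at one time point
#'
#' The corrected phenotype keeps only the sources of variation of interest
#' plus the residual: intercept, the mean over levels of each averaged design
#' factor, population (and condition-factor) effects, genotype BLUPs, and the
#' per-plant residual. Spatial trends, row/column effects and random design
#' factors are omitted.
#'
#' @param sfit a `stage1_fit`.
#' @return tibble with one row per plant observed at this time: `prediction`
#'   (p-hat), `residual`, `corrected` (= prediction + residual).
#' @export
correct_timepoint <- function(sfit) {
  fit <- sfit$fit
  A <- .phat_map(sfit)
  sol <- c(fit$beta, unlist(fit$u, use.names = FALSE))
  phat <- as.numeric(A %*% sol)
  tibble::tibble(
    plant = sfit$obs$plant, time = sfit$obs$time,
    prediction = phat, residual = fit$residuals,
    corrected = phat + fit$residuals
  )
}

#' Stage-1 precision weights
#'
#' Implements w(t) = diag((vcov(p-hat) + sigma^2 I)^-1): the variance-
#' covariance of the predictions is obtained from the inverse Henderson
#' coefficient matrix (fixed-estimate variance and random-effect prediction
#' error variance jointly), the residual variance is added on the diagonal,
#' and the full matrix is inverted.
#'
#' @param sfit a `stage1_fit`.
#' @return numeric weight vector, one per plant observed at this time.
#' @export
stage1_weights <- function(sfit) {
  fit <- sfit$fit
  A <- .phat_map(sfit)
  Vp <- prediction_error_variance(fit, A)
  Vp <- Vp + diag(fit$variances$sigma2, nrow(Vp))
  w <- diag(solve(Vp))
  if (any(!is.finite(w) | w <= 0)) {
    stop("non-positive weights: prediction covariance not positive definite")
  }
  w
}

#' Run the full first stage
#'
#' Fits the spatial model separately at every measurement time, applies the
#' correction and computes precision weights. Missing (plant, time)
#' slots are preserved with a missing flag; times where the fit fails are
#' kept as missing and logged.
#'
#' @param table a validated [validate_pheno()] table (the `factors` roles
#'   recorded there are used unless `spec` overrides them).
#' @param spec a [spatial_spec()]; defaults to one inferred from the table's
#'   grid.
#' @return a `corrected_series` tibble with columns population, genotype,
#'   plant, row, col, time, value (raw), corrected, prediction, residual,
#'   weight, missing; attributes carry the per-time variance components and
#'   convergence log.
#' @export
run_stage1 <- function(table, spec = NULL) {
  d <- pheno_dims(table)
  if (is.null(spec)) {
    spec <- spatial_spec(d$r, d$c, factors = d$factors)
  }
  slots <- complete_slots(table)
  out <- slots
  out$corrected <- NA_real_; out$prediction <- NA_real_
  out$residual <- NA_real_; out$weight <- NA_real_

  vc_log <- list(); conv <- list()
  for (j in seq_along(d$times)) {
    t_j <- d$times[j]
    tab_t <- slots[slots$time == t_j, , drop = FALSE]
    res <- tryCatch({
      sfit <- fit_timepoint(tab_t, spec)
      corr <- correct_timepoint(sfit)
      corr$weight <- stage1_weights(sfit)
      list(corr = corr, fit = sfit$fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      conv[[j]] <- tibble::tibble(time = t_j, status = "failed",
                                  message = conditionMessage(res))
      next
    }
    conv[[j]] <- tibble::tibble(time = t_j,
                                status = if (res$fit$converged) "ok" else "not_converged",
                                message = "")
    vc_log[[j]] <- dplyr::mutate(tidy(res$fit), time = t_j, .before = 1)
    m <- match(paste(res$corr$plant, res$corr$time),
               paste(out$plant, out$time))
    out$corrected[m] <- res$corr$corrected
    out$prediction[m] <- res$corr$prediction
    out$residual[m] <- res$corr$residual
    out$weight[m] <- res$corr$weight
  }
  convlog <- dplyr::bind_rows(conv)
  if (all(convlog$status == "failed")) {
    stop("stage 1 failed at every time point; first error: ",
         convlog$message[1])
  }
  attr(out, "variance_components") <- dplyr::bind_rows(vc_log)
  attr(out, "convergence") <- convlog
  attr(out, "pheno_dims") <- d
  class(out) <- unique(c("corrected_series", class(out)))
  out
}
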
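# coerce any matrix-like input to sparse column format
.as_sparse <- function(A) {
  if (inherits(A, "CsparseMatrix")) return(A)
  if (inherits(A, "Matrix")) return(methods::as(A, "CsparseMatrix"))
  methods::as(Matrix::Matrix(as.matrix(A), sparse = TRUE), "CsparseMatrix")
}

#' Linear mixed-model specification
#'
#' A generic sparse variance-component mixed model
#' \deqn{y = X\beta + \sum_g Z_g u_g + \epsilon,\qquad
#'       u_g \sim N(0, \sigma_g^2 I),\ \epsilon \sim N(0, \sigma^2 W^{-1})}
#' where `W = diag(weights)` holds known precision weights. Random design
#' blocks carry a variance-group label; blocks sharing a label share one
#' variance parameter.
#'
#' @param y numeric response (length N).
#' @param X fixed-effect design (N x p), dense or sparse; must have at least
#'   one column.
#' @param random named list of random design blocks (each N x q_g, coercible
#'   to `dgCMatrix`). Names are the variance-group labels; duplicate names
#'   pool blocks into one variance parameter.
#' @param weights positive precision weights (default 1).
#' @return an object of class `lmm_spec`.
#' @export
lmm_spec <- function(y, X, random = list(), weights = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  X <- .as_sparse(X)
  if (ncol(X) < 1L) stop("at least one fixed-effect column is required")
  if (nrow(X) != N) stop("X must have length(y) rows")
  if (is.null(weights)) weights <- rep(1, N)
  if (length(weights) != N || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be strictly positive, finite and of length N")
  }
  if (length(random)) {
    if (is.null(names(random)) || any(!nzchar(names(random)))) {
      stop("random blocks must be named with variance-group labels")
    }
    random <- lapply(random, function(Z) {
      Z <- .as_sparse(Z)
      if (nrow(Z) != N) stop("all random blocks must have length(y) rows")
      Z
    })
  }
  structure(list(y = y, X = X, random = random, weights = weights, N = N),
            class = "lmm_spec")
}

# Drop dependent fixed-effect columns (rank deficiency), keeping leading ones.
.fix_rank <- function(X) {
  Xd <- as.matrix(X)
  qrX <- qr(Xd)
  r <- qrX$rank
  if (r < ncol(Xd)) {
    keep <- sort(qrX$pivot[seq_len(r)])
    warning("fixed-effect design is rank deficient; dropping column(s) ",
            paste(setdiff(seq_len(ncol(Xd)), keep), collapse = ", "))
    list(X = X[, keep, drop = FALSE], keep = keep, rank = r)
  } else {
    list(X = X, keep = seq_len(ncol(Xd)), rank = r)
  }
}

# Internal: assemble spec into combined blocks + group index bookkeeping.
.lmm_setup <- function(spec) {
  groups <- unique(names(spec$random))
  Zs <- lapply(groups, function(g) {
    blocks <- spec$random[names(spec$random) == g]
    do.call(cbind, blocks)
  })
  names(Zs) <- groups
  q_g <- vapply(Zs, ncol, integer(1))
  Z <- if (length(Zs)) do.call(cbind, Zs) else NULL
  p <- ncol(spec$X)
  # coefficient index ranges, fixed part first
  idx <- list()
  off <- p
  for (g in groups) {
    idx[[g]] <- off + seq_len(q_g[[g]])
    off <- off + q_g[[g]]
  }
  list(groups = groups, Zs = Zs, Z = Z, q_g = q_g, p = p, idx = idx)
}

#' Solve Henderson's mixed model equations
#'
#' Builds and solves the sparse system
#' \deqn{C\,[\beta; u] = [X^T R^{-1} y;\ Z^T R^{-1} y],\qquad
#'   C = [X^T R^{-1} X,\ X^T R^{-1} Z;\ Z^T R^{-1} X,\ Z^T R^{-1} Z + G^{-1}]}
#' with \eqn{R^{-1} = \mathrm{diag}(w)/\sigma^2}. In this scaling,
#' \eqn{C^{-1}} is directly the joint (co)variance of
#' \eqn{(\hat\beta - \beta,\ \hat u - u)} (prediction error variance).
#'
#' @param spec an [lmm_spec()].
#' @param variances named list/vector with one element per variance group plus
#'   `sigma2` for the residual variance. All must be > 0.
#' @return list with `beta` (BLUE), `u` (named list of BLUPs per group),
#'   `fitted`, `residuals`, `C` (the MME matrix), `chol` (its Cholesky
#'   factor), `solve_C(B)` for \eqn{C^{-1}B}, and bookkeeping (`idx`, `p`,
#'   `rank_X`, `kept_fixed`).
#' @export
henderson_solve <- function(spec, variances) {
  stopifnot(inherits(spec, "lmm_spec"))
  sigma2 <- variances[["sigma2"]]
  if (is.null(sigma2) || sigma2 <= 0) stop("variances must include sigma2 > 0")
  fr <- .fix_rank(spec$X)
  spec$X <- fr$X
  su <- .lmm_setup(spec)
  for (g in su$groups) {
    vg <- variances[[g]]
    if (is.null(vg) || vg <= 0) stop("missing or non-positive variance for group ", g)
  }
  w <- spec$weights / sigma2
  XZ <- if (is.null(su$Z)) spec$X else cbind(spec$X, su$Z)
  Cmat <- Matrix::crossprod(XZ * w, XZ)
  if (length(su$groups)) {
    ginv <- c(rep(0, su$p),
              unlist(lapply(su$groups, function(g)
                rep(1 / variances[[g]], su$q_g[[g]]))))
    Cmat <- Cmat + Matrix::Diagonal(x = ginv)
  }
  rhs <- Matrix::crossprod(XZ, w * spec$y)
  Cmat <- Matrix::forceSymmetric(Cmat)
  ch <- tryCatch(Matrix::Cholesky(Cmat, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("MME coefficient matrix is singular: ", conditionMessage(e)))
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  beta <- sol[seq_len(su$p)]
  u <- lapply(su$groups, function(g) sol[su$idx[[g]]])
  names(u) <- su$groups
  fitted <- as.numeric(XZ %*% sol)
  list(beta = beta, u = u, fitted = fitted,
       residuals = spec$y - fitted,
       C = Cmat, chol = ch,
       solve_C = function(B) Matrix::solve(ch, B, system = "A"),
       idx = su$idx, p = su$p, q_g = su$q_g, groups = su$groups,
       rank_X = fr$rank, kept_fixed = fr$keep)
}

#' REML estimation of variance components
#'
#' Maximises the restricted likelihood by the Harville fixed point (the SOP
#' algorithm for models linear in the variance parameters): each iteration
#' solves Henderson's equations at the current variances, computes each
#' group's effective dimension
#' \eqn{ED_g = q_g - \mathrm{tr}([C^{-1}]_{gg})/\sigma_g^2}
#' from the inverse MME matrix, and updates
#' \eqn{\sigma_g^2 \leftarrow u_g^T u_g / ED_g} and
#' \eqn{\sigma^2 \leftarrow \mathrm{wRSS} / (N - \mathrm{rank}(X) - \sum_g ED_g)}.
#'
#' Convergence requires both a relative change in the -2 REML log-likelihood
#' below `tol` and a maximum relative variance change below `vtol`.
#' Components that collapse are pinned at a small floor
#' (`1e-10 * var(y)`) and reported.
#'
#' @param spec an [lmm_spec()].
#' @param init optional named list of starting variances (including `sigma2`);
#'   defaults to `var(y) / (#groups + 1)` for every component.
#' @param tol,vtol convergence tolerances (see Details).
#' @param max_iter maximum number of fixed-point iterations.
#' @return an object of class `lmm_fit`: the final Henderson solution plus
#'   `variances`, `ed` (effective dimensions), `deviance` (-2 REML
#'   log-likelihood, without the additive constant), `iterations` (log
#'   tibble), `converged`, `pinned`.
#' @export
reml_fit <- function(spec, init = NULL, tol = 1e-8, vtol = 1e-6,
                     max_iter = 200L) {
  stopifnot(inherits(spec, "lmm_spec"))
  groups <- unique(names(spec$random))
  vy <- stats::var(spec$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  floor_v <- 1e-10 * vy
  v0 <- vy / (length(groups) + 1)
  variances <- c(stats::setNames(as.list(rep(v0, length(groups))), groups),
                 list(sigma2 = v0))
  if (!is.null(init)) for (nm in names(init)) variances[[nm]] <- init[[nm]]

  if (length(groups) == 0L) {
    # weighted least squares closed form
    hs <- henderson_solve(spec, list(sigma2 = 1))
    wrss <- sum(spec$weights * hs$residuals^2)
    sigma2 <- wrss / (spec$N - hs$rank_X)
    hs <- henderson_solve(spec, list(sigma2 = sigma2))
    dev <- .reml_deviance(spec, hs, list(sigma2 = sigma2), numeric(0))
    return(structure(
      c(hs, list(variances = list(sigma2 = sigma2),
                 ed = stats::setNames(numeric(0), character(0)),
                 deviance = dev, converged = TRUE, pinned = character(0),
                 iterations = tibble::tibble(iter = 1L, deviance = dev,
                                             sigma2 = sigma2),
                 spec = spec)),
      class = "lmm_fit"))
  }

  dev_prev <- Inf
  log <- vector("list", max_iter)
  converged <- FALSE
  ed <- NULL; hs <- NULL
  for (it in seq_len(max_iter)) {
    hs <- henderson_solve(spec, variances)
    # effective dimensions: ED_g = q_g - tr([C^-1]_gg) / sigma_g^2
    diagC <- .inv_diag(hs)
    ed <- vapply(groups, function(g)
      hs$q_g[[g]] - sum(diagC[hs$idx[[g]]]) / variances[[g]], numeric(1))
    names(ed) <- groups
    wrss <- sum(spec$weights * hs$residuals^2)
    new_var <- variances
    for (g in groups) {
      ssq <- sum(hs$u[[g]]^2)
      new_var[[g]] <- max(if (ed[[g]] > 1e-12) ssq / ed[[g]] else 0, floor_v)
    }
    denom <- spec$N - hs$rank_X - sum(ed)
    new_var$sigma2 <- max(wrss / max(denom, 1e-8), floor_v)
    dev <- .reml_deviance(spec, hs, variances, ed)
    log[[it]] <- tibble::tibble(iter = it, deviance = dev,
                                sigma2 = variances$sigma2)
    rel_dev <- abs(dev - dev_prev) / (abs(dev) + 0.1)
    # components that have collapsed to (near) zero keep decaying
    # geometrically without affecting the fit; exclude them from the
    # variance-change criterion
    ov <- unlist(variances); nv <- unlist(new_var)
    active <- pmax(ov, nv) > 1e-6 * vy
    active[length(active)] <- TRUE # residual always active
    rel_var <- max(abs(nv[active] - ov[active]) / (ov[active] + floor_v))
    variances_prev <- variances
    variances <- new_var
    if (rel_dev < tol && rel_var < vtol) {
      converged <- TRUE
      variances <- variances_prev
      break
    }
    dev_prev <- dev
  }
  if (!converged) {
    warning("REML did not converge in ", max_iter,
            " iterations; returning last iterate")
    hs <- henderson_solve(spec, variances)
  }
  pinned <- names(variances)[unlist(variances) <= floor_v * (1 + 1e-12)]
  dev <- .reml_deviance(spec, hs, variances, ed)
  structure(
    c(hs, list(variances = variances, ed = ed, deviance = dev,
               converged = converged, pinned = pinned,
               iterations = dplyr::bind_rows(log[!vapply(log, is.null, TRUE)]),
               spec = spec)),
    class = "lmm_fit")
}

# diagonal of C^{-1} via solves against the identity (sparse Cholesky)
.inv_diag <- function(hs) {
  n <- nrow(hs$C)
  Inv <- Matrix::solve(hs$chol, Matrix::Diagonal(n), system = "A")
  Matrix::diag(Inv)
}

# -2 REML log-likelihood (constant (N - p) log(2*pi) omitted):
#   log|V| + log|X' V^-1 X| + y' P y
# computed via the MME factorisation:
#   = N log s2 - sum(log w) + sum_g q_g log s2_g + log|C| + (y'R^-1 y - sol'rhs)
.reml_deviance <- function(spec, hs, variances, ed) {
  s2 <- variances$sigma2
  w <- spec$weights
  ldetC <- 2 * Matrix::determinant(hs$chol, sqrt = TRUE)$modulus[1]
  ldetG <- 0
  for (g in hs$groups) ldetG <- ldetG + hs$q_g[[g]] * log(variances[[g]])
  yRy <- sum(w * spec$y^2) / s2
  # sol' rhs = fitted' W y / sigma^2
  rhsdot <- sum(w * spec$y * hs$fitted) / s2
  as.numeric(spec$N * log(s2) - sum(log(w)) + ldetG + ldetC + yRy - rhsdot)
}

#' Prediction error variance of linear combinations
#'
#' For a matrix `L` mapping the stacked coefficient vector
#' \eqn{(\beta, u)} to quantities of interest, returns
#' \eqn{L C^{-1} L^T}, the (co)variance of \eqn{L[(\hat\beta;\hat u) -
#' (\beta; u)]}, computed by sparse solves (never a full inversion when `L`
#' is thin).
#'
#' @param fit an `lmm_fit` (or the list returned by [henderson_solve()]).
#' @param L dense or sparse matrix with `ncol = p + q` (coefficients in fixed,
#'   then group order).
#' @param diag_only return only the diagonal (variances).
#' @export
prediction_error_variance <- function(fit, L, diag_only = FALSE) {
  n <- nrow(fit$C)
  L <- .as_sparse(L)
  if (ncol(L) != n) stop("L must have ", n, " columns (p + q)")
  S <- fit$solve_C(Matrix::t(L))
  V <- L %*% S
  if (diag_only) Matrix::diag(V) else as.matrix(V)
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> N =", x$spec$N, " fixed:", x$p,
      " groups:", length(x$groups), "\n")
  cat("  -2 REML loglik:", format(x$deviance), " converged:", x$converged, "\n")
  v <- unlist(x$variances)
  cat("  variances:\n")
  for (nm in names(v)) cat(sprintf("    %-18s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#'
#' One row per variance component with its estimate and effective dimension.
#' @param x an `lmm_fit`.
#' @param ... unused.
#' @export
tidy.lmm_fit <- function(x, ...) {
  groups <- x$groups
  tibble::tibble(
    component = c(groups, "residual"),
    variance = c(vapply(groups, function(g) x$variances[[g]], numeric(1)),
                 x$variances$sigma2),
    effective_dim = c(as.numeric(x$ed[groups]), NA_real_),
    n_coef = c(vapply(groups, function(g) x$q_g[[g]], integer(1)), NA_integer_)
  )
}

#' @rdname tidy.lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$spec$N, n_fixed = x$p,
    n_random = sum(unlist(x$q_g)),
    n_variance_components = length(x$groups) + 1L,
    deviance = x$deviance,
    converged = x$converged,
    iterations = nrow(x$iterations)
  )
}
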
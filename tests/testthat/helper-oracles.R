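# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Textbook Cox-de Boor recursion for a single B-spline basis function
# B_{j,d}(x) on knot vector k (0-based degree d), independent of splineDesign.
deboor_basis <- function(knots, j, d, x) {
  if (d == 0) {
    return(as.numeric(x >= knots[j] & x < knots[j + 1]))
  }
  a <- 0
  den1 <- knots[j + d] - knots[j]
  if (den1 > 0) a <- (x - knots[j]) / den1 * deboor_basis(knots, j, d - 1, x)
  den2 <- knots[j + d + 1] - knots[j + 1]
  if (den2 > 0) {
    a <- a + (knots[j + d + 1] - x) / den2 * deboor_basis(knots, j + 1, d - 1, x)
  }
  a
}

deboor_matrix <- function(knots, dim, degree, x) {
  sapply(seq_len(dim), function(j) deboor_basis(knots, j, degree, x))
}

# Dense GLS / BLUP formulas for a mixed model y = Xb + sum Z_g u_g + e,
# V = sum s2_g Z_g Z_g' + s2 diag(1/w).
dense_gls <- function(y, X, Zs, s2_g, s2, w = rep(1, length(y))) {
  V <- s2 * diag(1 / w)
  for (g in seq_along(Zs)) V <- V + s2_g[g] * tcrossprod(as.matrix(Zs[[g]]))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  u <- lapply(seq_along(Zs), function(g)
    s2_g[g] * t(as.matrix(Zs[[g]])) %*% Vi %*% resid)
  list(beta = as.numeric(beta), u = u, V = V, Vi = Vi)
}

# -2 REML log-likelihood with explicit dense V (constant omitted, matching
# the package's convention).
dense_reml_deviance <- function(y, X, Zs, s2_g, s2, w = rep(1, length(y))) {
  d <- dense_gls(y, X, Zs, s2_g, s2, w)
  XtViX <- t(X) %*% d$Vi %*% X
  r <- y - X %*% d$beta
  as.numeric(determinant(d$V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% d$Vi %*% r)
}

# numeric REML optimisation over log variances (dense, brute force)
dense_reml_optim <- function(y, X, Zs, w = rep(1, length(y)),
                             init = rep(0, length(Zs) + 1)) {
  obj <- function(lp) {
    dense_reml_deviance(y, X, Zs, exp(lp[-length(lp)]), exp(lp[length(lp)]), w)
  }
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(s2_g = exp(opt$par[-length(opt$par)]),
       s2 = exp(opt$par[length(opt$par)]),
       deviance = opt$value)
}

quiet_fit <- function(expr) suppressWarnings(expr)
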
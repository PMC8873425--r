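#' B-spline basis specification
#'
#' Defines a cubic B-spline basis with equally spaced knots over a closed
#' domain, together with the order of the difference penalty used when the
#' basis enters a P-spline. Boundary knots are replicated `degree` times so
#' that the basis spans the full domain.
#'
#' @param domain numeric length-2, the interval \eqn{[a, b]} the basis lives on.
#' @param dim number of basis functions (>= degree + 1).
#' @param degree spline degree; cubic (3) throughout the package.
#' @param penalty_order order of the difference penalty on the coefficients
#'   (second differences by default).
#' @return An object of class `basis_spec`.
#' @examples
#' sp <- basis_spec(c(0, 10), dim = 8)
#' B <- bspline_basis(sp, seq(0, 10, by = 0.5))
#' rowSums(B) # partition of unity
#' @export
basis_spec <- function(domain, dim, degree = 3L, penalty_order = 2L) {
  stopifnot(length(domain) == 2, is.finite(domain), domain[2] > domain[1])
  dim <- as.integer(dim)
  degree <- as.integer(degree)
  penalty_order <- as.integer(penalty_order)
  if (dim < degree + 1L) {
    stop("basis dimension must be at least degree + 1 (got ", dim, ")")
  }
  if (penalty_order >= dim) {
    stop("penalty order must be smaller than the basis dimension")
  }
  # dim basis functions of given degree need dim - degree interior segments;
  # equally spaced knots extended degree-fold beyond each boundary, so the
  # penalty null space maps exactly onto {1, t} (Greville abscissae are
  # linear in the coefficient index)
  nseg <- dim - degree
  dx <- (domain[2] - domain[1]) / nseg
  knots <- domain[1] + ((-degree):(nseg + degree)) * dx
  # pin the boundary knots exactly, guarding against rounding in dx
  knots[degree + 1L] <- domain[1]
  knots[degree + 1L + nseg] <- domain[2]
  structure(
    list(domain = as.numeric(domain), dim = dim, degree = degree,
         penalty_order = penalty_order, knots = knots),
    class = "basis_spec"
  )
}

#' @exportS3Method base::print
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> cubic=%s dim=%d domain=[%g, %g] penalty order %d\n",
              x$degree == 3L, x$dim, x$domain[1], x$domain[2], x$penalty_order))
  invisible(x)
}

#' Evaluate a B-spline basis
#'
#' @param spec a [basis_spec()].
#' @param times numeric vector of evaluation points.
#' @param clamp if `TRUE`, points outside the domain are moved to the nearest
#'   boundary; if `FALSE` (default) they raise an error. Curves are never
#'   extrapolated.
#' @param deriv derivative order (0 = function values, 1 = first derivative).
#' @return a `length(times) x dim` matrix of basis evaluations.
#' @export
bspline_basis <- function(spec, times, clamp = FALSE, deriv = 0L) {
  stopifnot(inherits(spec, "basis_spec"), is.numeric(times))
  a <- spec$domain[1]; b <- spec$domain[2]
  eps <- 1e-10 * (b - a)
  out <- times < a - eps | times > b + eps
  if (any(out)) {
    if (!clamp) {
      stop("evaluation points outside the basis domain [", a, ", ", b,
           "]; curves are not extrapolated (set clamp = TRUE to clamp)")
    }
    times <- pmin(pmax(times, a), b)
  }
  # splineDesign wants points strictly inside the extended knot range;
  # nudge exact right-boundary hits into the last interval.
  tt <- pmin(pmax(times, a), b)
  splines::splineDesign(spec$knots, tt, ord = spec$degree + 1L,
                        derivs = rep(deriv, length(tt)), outer.ok = FALSE)
}

#' First-derivative B-spline basis
#'
#' Rows evaluate the first derivative of each basis function (degree-reduction
#' formula, as implemented by `splineDesign`).
#'
#' @inheritParams bspline_basis
#' @return a `length(times) x dim` matrix.
#' @export
derivative_basis <- function(spec, times, clamp = FALSE) {
  bspline_basis(spec, times, clamp = clamp, deriv = 1L)
}

#' Difference matrix
#'
#' The `order`-th order difference operator as a dense
#' `(b - order) x b` matrix, the building block of the P-spline penalty
#' `t(D) %*% D`.
#'
#' @param b number of coefficients.
#' @param order difference order (< b).
#' @export
difference_matrix <- function(b, order) {
  b <- as.integer(b); order <- as.integer(order)
  if (order >= b) stop("difference order must be < number of coefficients")
  diff(diag(b), differences = order)
}

#' Greville abscissae
#'
#' Knot averages at which the B-spline basis reproduces the identity:
#' a spline with coefficients `greville(spec)` equals `f(t) = t`.
#'
#' @param spec a [basis_spec()].
#' @export
greville <- function(spec) {
  k <- spec$knots; d <- spec$degree
  vapply(seq_len(spec$dim), function(j) mean(k[(j + 1):(j + d)]), numeric(1))
}

#' P-spline to mixed-model reparameterisation
#'
#' Splits a penalised B-spline fit into an unpenalised linear part
#' `[1 | t]` and a random part with `b - 2` columns carrying an identity
#' penalty, via the spectral decomposition of the penalty `t(D) %*% D`:
#' random columns are `B U L^(-1/2)` for the eigenvectors `U` with positive
#' eigenvalues `L`. A penalised least-squares fit with smoothing parameter
#' `lambda` then coincides with the mixed-model fit at variance ratio
#' `lambda = sigma^2 / sigma_u^2`.
#'
#' The linear covariate is rescaled to `(t - a) / (b - a)` for numerical
#' balance; the span of `[X | Z]` equals the span of the raw basis either way.
#'
#' @param spec a [basis_spec()] with penalty order 2.
#' @return an object of class `mm_basis` with elements `spec`, `U` and
#'   `d` (positive eigenvectors/eigenvalues of the penalty), and evaluators
#'   `X(times)`, `Z(times)` and their derivatives.
#' @export
mm_transform <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$penalty_order != 2L) {
    stop("the mixed-model reparameterisation is implemented for penalty order 2")
  }
  D <- difference_matrix(spec$dim, spec$penalty_order)
  P <- crossprod(D)
  e <- eigen(P, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  U <- e$vectors[, pos, drop = FALSE]
  d <- e$values[pos]
  # transform raw B-spline coefficients -> random effects and back
  Tmat <- U %*% diag(1 / sqrt(d), length(d))
  structure(
    list(spec = spec, U = U, d = d, Tmat = Tmat,
         n_random = sum(pos)),
    class = "mm_basis"
  )
}

#' @rdname mm_transform
#' @param mm an `mm_basis`.
#' @param times evaluation points.
#' @param deriv derivative order (0 or 1).
#' @param clamp clamp out-of-domain points instead of erroring.
#' @export
mm_design_fixed <- function(mm, times, deriv = 0L, clamp = FALSE) {
  a <- mm$spec$domain[1]; b <- mm$spec$domain[2]
  ts <- (times - a) / (b - a)
  if (deriv == 0L) cbind(1, ts)
  else cbind(0, rep(1 / (b - a), length(times)))
}

#' @rdname mm_transform
#' @export
mm_design_random <- function(mm, times, deriv = 0L, clamp = FALSE) {
  B <- bspline_basis(mm$spec, times, clamp = clamp, deriv = deriv)
  B %*% mm$Tmat
}

#' Map mixed-model coefficients back to raw B-spline coefficients
#'
#' Given the linear coefficients `beta = (b0, b1)` (on the rescaled time
#' `(t - a)/(b - a)`) and the random coefficients `u`, returns coefficients
#' `c` such that the spline `B(t) c` equals `X(t) beta + Z(t) u` exactly
#' (B-splines reproduce linear functions through the Greville abscissae).
#'
#' @param mm an `mm_basis`.
#' @param beta length-2 linear coefficients.
#' @param u random coefficients (length `dim - 2`).
#' @export
mm_to_spline_coef <- function(mm, beta, u) {
  sp <- mm$spec
  a <- sp$domain[1]; b <- sp$domain[2]
  g <- (greville(sp) - a) / (b - a)
  as.numeric(beta[1] + beta[2] * g + mm$Tmat %*% u)
}

#' Exact integral of a B-spline curve
#'
#' Integrates `sum_j coef_j B_j(t)` over `[lo, hi]` exactly via the
#' antiderivative spline: the indefinite integral of a degree-`d` spline is a
#' degree-`d + 1` spline whose coefficients are scaled cumulative sums of the
#' original ones.
#'
#' @param spec a [basis_spec()].
#' @param coef spline coefficients (length `spec$dim`).
#' @param interval integration interval, contained in the domain; defaults to
#'   the full domain.
#' @return the integral (scalar).
#' @export
integrate_curve <- function(spec, coef, interval = spec$domain) {
  stopifnot(inherits(spec, "basis_spec"), length(coef) == spec$dim)
  a <- spec$domain[1]; b <- spec$domain[2]
  eps <- 1e-10 * (b - a)
  if (interval[1] < a - eps || interval[2] > b + eps) {
    stop("integration interval must lie within the basis domain")
  }
  interval <- pmin(pmax(interval, a), b)
  d <- spec$degree
  k <- spec$knots
  # antiderivative spline: degree d+1 on knots extended one step each side
  dx <- k[2] - k[1]
  k2 <- c(k[1] - dx, k, k[length(k)] + dx)
  A <- cumsum(coef * (k[seq_len(spec$dim) + d + 1L] - k[seq_len(spec$dim)]) / (d + 1))
  # antiderivative basis has spec$dim + 1 functions; first coefficient is 0
  co2 <- c(0, A)
  Bend <- splines::splineDesign(k2, pmin(pmax(interval, a), b), ord = d + 2L,
                                outer.ok = FALSE)
  vals <- as.numeric(Bend %*% co2)
  vals[2] - vals[1]
}
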
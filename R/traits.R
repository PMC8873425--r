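#' Maximum of an estimated curve
#'
#' Global maximum of each unit's curve over its evaluation grid, refined by a
#' three-point quadratic interpolation around the grid maximum (exact for a
#' locally quadratic curve; interior maxima are located to well below one
#' grid step).
#'
#' @param curves a `curve_set` tibble from [evaluate_curves()] (kind
#'   `"curve"`).
#' @return tibble with one row per unit: `unit`, `population`, `time`,
#'   `value`.
#' @export
max_trait <- function(curves) {
  stopifnot(nrow(curves) > 0)
  curves |>
    dplyr::group_by(.data$unit, .data$population) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      j <- which.max(df$estimate)
      ref <- .quad_refine(df$time, df$estimate, j)
      tibble::tibble(time = ref[1], value = ref[2])
    }) |>
    dplyr::ungroup()
}

# 3-point quadratic refinement around grid index j; falls back to the grid
# point at the boundary or for degenerate curvature
.quad_refine <- function(t, y, j) {
  n <- length(t)
  if (j <= 1 || j >= n) return(c(t[j], y[j]))
  t3 <- t[(j - 1):(j + 1)]; y3 <- y[(j - 1):(j + 1)]
  co <- tryCatch(solve(cbind(1, t3, t3^2), y3), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] >= 0) return(c(t[j], y[j]))
  tm <- -co[2] / (2 * co[3])
  if (tm < t3[1] || tm > t3[3]) return(c(t[j], y[j]))
  unname(c(tm, co[1] + co[2] * tm + co[3] * tm^2))
}

#' Local extrema of estimated derivative curves
#'
#' Detects interior local minima and maxima of each unit's (derivative)
#' curve from sign changes of its numerical differences, refined by
#' three-point quadratic interpolation. Endpoints are excluded; an empty
#' result is allowed.
#'
#' @param deriv a `curve_set` from [evaluate_derivatives()].
#' @return tibble: `unit`, `population`, `time`, `value`,
#'   `type` (`"min"`/`"max"`), ordered by time within unit.
#' @export
derivative_extrema <- function(deriv) {
  deriv |>
    dplyr::group_by(.data$unit, .data$population) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      y <- df$estimate; t <- df$time; n <- length(y)
      if (n < 3) return(tibble::tibble(time = numeric(0), value = numeric(0),
                                       type = character(0)))
      d <- diff(y)
      out <- list()
      for (j in 2:(n - 1)) {
        if (d[j - 1] > 0 && d[j] <= 0) {
          r <- .quad_refine(t, y, j)
          out[[length(out) + 1]] <- tibble::tibble(time = r[1], value = r[2],
                                                   type = "max")
        } else if (d[j - 1] < 0 && d[j] >= 0) {
          r <- .quad_refine(t, -y, j)
          out[[length(out) + 1]] <- tibble::tibble(time = r[1], value = -r[2],
                                                   type = "min")
        }
      }
      empty <- tibble::tibble(time = numeric(0), value = numeric(0),
                              type = character(0))
      dplyr::bind_rows(c(list(empty), out))
    }) |>
    dplyr::ungroup()
}

#' Maximum growth rates within time windows
#'
#' For each unit and each named window, the largest derivative value inside
#' the window: the highest interior local maximum from
#' [derivative_extrema()], or — when the window contains no interior
#' maximum — the windowed grid maximum, flagged via `interior = FALSE`.
#'
#' @param deriv a `curve_set` from [evaluate_derivatives()].
#' @param windows named list of time intervals, e.g.
#'   `list(maxSpeed1 = c(95, 110))`.
#' @return tibble: `unit`, `population`, `window`, `time`, `value`,
#'   `interior`.
#' @export
max_speeds <- function(deriv, windows) {
  if (is.null(names(windows)) || any(!nzchar(names(windows)))) {
    stop("windows must be a named list of intervals")
  }
  tr <- range(deriv$time)
  for (w in windows) {
    if (w[1] < tr[1] - 1e-9 || w[2] > tr[2] + 1e-9) {
      stop("window [", w[1], ", ", w[2], "] outside the curve domain")
    }
  }
  ext <- derivative_extrema(deriv)
  purrr::imap_dfr(windows, function(win, nm) {
    deriv |>
      dplyr::group_by(.data$unit, .data$population) |>
      dplyr::group_modify(function(df, key) {
        ex <- ext[ext$unit == key$unit & ext$type == "max" &
                    ext$time >= win[1] & ext$time <= win[2], ]
        if (nrow(ex) > 0) {
          j <- which.max(ex$value)
          tibble::tibble(time = ex$time[j], value = ex$value[j],
                         interior = TRUE)
        } else {
          sel <- df$time >= win[1] & df$time <= win[2]
          j <- which.max(df$estimate[sel])
          tibble::tibble(time = df$time[sel][j], value = df$estimate[sel][j],
                         interior = FALSE)
        }
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(window = nm, .after = "population")
  })
}

#' Area under genotype deviation curves
#'
#' Signed area under the estimated genotype-specific deviations f_pg over an
#' interval, computed as an exact spline integral: the fitted deviation
#' (random intercept + slope + smooth part) is re-expressed in the raw
#' B-spline basis and integrated via the antiderivative spline. A positive
#' area indicates performance above the population mean over the interval.
#'
#' @param fit a [fit_growth()] result.
#' @param genotypes genotype ids (default all).
#' @param interval integration interval; default the full measured range.
#' @return tibble: `genotype`, `population`, `auc`.
#' @export
deviation_auc <- function(fit, genotypes = NULL, interval = NULL) {
  design <- fit$design
  if (is.null(genotypes)) genotypes <- design$gtab$genotype
  tr <- range(design$times)
  if (is.null(interval)) interval <- tr
  if (interval[1] < tr[1] - 1e-9 || interval[2] > tr[2] + 1e-9) {
    stop("interval outside the measured time range")
  }
  sol <- .hier_sol(fit)
  uc <- design$unit_cols
  purrr::map_dfr(genotypes, function(gid) {
    g <- match(gid, design$gtab$genotype)
    if (is.na(g)) stop("unknown genotype: ", gid)
    beta <- sol[c(uc$gen_int[g], uc$gen_slope[g])]
    u <- sol[uc$gen_smooth[[g]]]
    co <- mm_to_spline_coef(design$mm_gen, beta, u)
    tibble::tibble(genotype = gid,
                   population = design$gtab$population[g],
                   auc = integrate_curve(design$mm_gen$spec, co, interval))
  })
}

#' Genotype trait table
#'
#' One row per genotype with the time-independent attributes extracted from
#' its estimated growth curve and first derivative: the curve maximum
#' (`maxTrait`), the maximum growth rate in each requested window
#' (`maxSpeed<k>`), and the signed area under the genotype deviation (`auc`).
#'
#' @param fit a [fit_growth()] result.
#' @param windows named list of derivative windows (see [max_speeds()]);
#'   `NULL` extracts a single global `maxSpeed`.
#' @param grid_n evaluation grid resolution.
#' @param auc_interval interval for the deviation area (default full range).
#' @return a `trait_table` tibble.
#' @export
build_trait_table <- function(fit, windows = NULL, grid_n = NULL,
                              auc_interval = NULL) {
  design <- fit$design
  if (is.null(grid_n)) grid_n <- design$config$grid_n
  grid <- seq(design$times[1], design$times[length(design$times)],
              length.out = grid_n)
  curves <- evaluate_curves(fit, "genotype", grid = grid, se = FALSE)
  deriv <- evaluate_derivatives(fit, "genotype", grid = grid, se = FALSE)
  if (is.null(windows)) windows <- list(maxSpeed = range(grid))
  mt <- max_trait(curves) |>
    dplyr::rename(maxTrait_time = "time", maxTrait_value = "value")
  ms <- max_speeds(deriv, windows) |>
    dplyr::select("unit", "population", "window", "time", "value") |>
    tidyr::pivot_wider(names_from = "window",
                       values_from = c("value", "time"),
                       names_glue = "{window}_{.value}")
  auc <- deviation_auc(fit, interval = auc_interval)
  out <- mt |>
    dplyr::left_join(ms, by = c("unit", "population")) |>
    dplyr::left_join(auc, by = c(unit = "genotype", population = "population")) |>
    dplyr::rename(genotype = "unit")
  class(out) <- unique(c("trait_table", class(out)))
  out
}
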
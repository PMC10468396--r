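# Conversion factor from wax-dipping weight increment to skeletal surface
# area (cm^2 per g of second-coating wax).
WAX_CM2_PER_G <- 34.32

#' Coral surface area from paraffin wax dipping
#'
#' Converts the weight increment of the second wax coating of a dipped coral
#' skeleton into skeletal surface area via the standard regression
#' `area (cm^2) = 34.32 (cm^2/g) x mass (g)`.
#'
#' @param mass_increment Weight increment of the second coating (g, >= 0).
#' @return Surface area in cm^2.
#' @examples
#' wax_area(1.00)  # 34.32 cm^2
#' @export
wax_area <- function(mass_increment) {
  stopifnot(is.numeric(mass_increment))
  if (any(mass_increment < 0)) {
    stop("negative wax mass increment: check the weighings", call. = FALSE)
  }
  WAX_CM2_PER_G * mass_increment
}

#' Coral surface area from aluminium-foil wrapping
#'
#' Converts the weight of a foil cut and molded to a colony's surface into
#' area, given the areal density (g/cm^2) of the foil obtained by weighing
#' pieces of known area.
#'
#' @param foil_mass Foil mass (g, >= 0).
#' @param areal_density Foil areal density (g/cm^2, > 0); see
#'   [foil_areal_density()].
#' @return Surface area in cm^2.
#' @examples
#' foil_area(0.30, areal_density = 0.006)  # 50 cm^2
#' @export
foil_area <- function(foil_mass, areal_density) {
  stopifnot(is.numeric(foil_mass), is.numeric(areal_density))
  if (any(foil_mass < 0)) stop("negative foil mass", call. = FALSE)
  if (length(areal_density) != 1L || areal_density <= 0) {
    stop("`areal_density` must be a single positive value", call. = FALSE)
  }
  foil_mass / areal_density
}

#' Foil areal density from calibration weighings
#'
#' Least-squares slope through the origin of mass against area for foil
#' pieces of known area, giving g/cm^2.
#'
#' @param areas Known areas of calibration pieces (cm^2, > 0).
#' @param masses Measured masses (g).
#' @return Areal density in g/cm^2.
#' @examples
#' foil_areal_density(c(10, 20), c(0.06, 0.12))  # 0.006 g/cm^2
#' @export
foil_areal_density <- function(areas, masses) {
  stopifnot(length(areas) == length(masses), length(areas) >= 1,
            all(areas > 0))
  sum(areas * masses) / sum(areas^2)
}

#' Anchor a visible-area series to the measured final total area
#'
#' The total 3D surface area is measured destructively only at the end of an
#' experiment. Intermediate total areas are extrapolated by scaling the
#' visible (photographic) area series so that the final time point equals the
#' measured total area; ratios between any two time points are preserved.
#'
#' @param timecourse A data frame with columns `day` and `visible_area_cm2`.
#' @param final_total_area Measured total area at the last time point (cm^2).
#' @return The timecourse with a `total_area` column appended.
#' @examples
#' tc <- tibble::tibble(day = c(0, 100, 203), visible_area_cm2 = c(10, 20, 30))
#' scale_visible_area(tc, final_total_area = 60)
#' @export
scale_visible_area <- function(timecourse, final_total_area) {
  stopifnot(is.data.frame(timecourse),
            all(c("day", "visible_area_cm2") %in% names(timecourse)),
            final_total_area > 0)
  va <- timecourse$visible_area_cm2
  final_visible <- va[which.max(timecourse$day)]
  if (!is.finite(final_visible) || final_visible <= 0) {
    stop("final visible area must be positive to anchor the series",
         call. = FALSE)
  }
  timecourse$total_area <- va * final_total_area / final_visible
  timecourse
}

#' Calibration of symbiont density against image brightness
#'
#' Fits `density = a * exp(b * mgv)` to paired (MGV, density) observations by
#' linear least squares on log density. MGV is the mean grey value of a
#' standardized colony photograph; denser symbiont populations make the
#' tissue darker, so `b` is negative. The r-squared is reported on the log
#' scale, the scale of the fit.
#'
#' @param mgv Mean grey values (same length as `density`, >= 3 pairs, not all
#'   identical).
#' @param density Symbiont densities (cells/cm^2, all > 0).
#' @return An object of class `calibration_curve` with fields `a`
#'   (cells/cm^2 at MGV 0), `b` (per MGV unit), `r2`, `n`.
#' @examples
#' mgv <- c(60, 100, 140, 180)
#' dens <- 2e6 * exp(-0.011 * mgv)
#' fit_mgv_calibration(mgv, dens)
#' @export
fit_mgv_calibration <- function(mgv, density) {
  stopifnot(length(mgv) == length(density))
  if (length(mgv) < 3L) stop("need at least 3 calibration pairs", call. = FALSE)
  if (any(density <= 0)) stop("all densities must be positive", call. = FALSE)
  if (stats::var(mgv) == 0) {
    stop("degenerate design: all MGV values identical", call. = FALSE)
  }
  fit <- stats::lm(log(density) ~ mgv)
  a <- exp(unname(stats::coef(fit)[1L]))
  b <- unname(stats::coef(fit)[2L])
  if (b >= 0) {
    warning("fitted calibration slope is non-negative; ",
            "density should decrease with brightness", call. = FALSE)
  }
  ld <- log(density)
  ss_tot <- sum((ld - mean(ld))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(a = a, b = b, r2 = r2, n = length(mgv)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("MGV calibration: density = %.4g * exp(%.4g * MGV), r2 = %.3f (n = %d)\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Symbiont density from mean grey value
#'
#' Evaluates a fitted [calibration curve][fit_mgv_calibration]:
#' `a * exp(b * mgv)`, strictly decreasing in MGV for `b < 0`. Values outside
#' the 8-bit 0-255 range are accepted with a warning (the measurement itself
#' is not bounded by the calibration).
#'
#' @param mgv Mean grey value(s).
#' @param curve A `calibration_curve` object, or a list with `a` and `b`.
#' @return Density in cells/cm^2.
#' @export
density_from_mgv <- function(mgv, curve) {
  stopifnot(is.numeric(mgv), is.list(curve), !is.null(curve$a),
            !is.null(curve$b))
  if (any(mgv < 0 | mgv > 255)) {
    warning("MGV outside [0, 255]", call. = FALSE)
  }
  curve$a * exp(curve$b * mgv)
}

#' Mean grey value from symbiont density (calibration inverse)
#'
#' @param density Density in cells/cm^2 (> 0).
#' @param curve A `calibration_curve` object, or a list with `a` and `b`.
#' @return MGV such that [density_from_mgv()] returns `density`.
#' @export
mgv_from_density <- function(density, curve) {
  stopifnot(all(density > 0), curve$b != 0)
  log(density / curve$a) / curve$b
}

#' Fit a growth or decline curve to a colony time course
#'
#' Fits one of the standard families used for colony area, mass and symbiont
#' density time courses:
#' \describe{
#'   \item{exp_increase / exp_decrease}{`y = y0 * exp(k * t)` with `k > 0`
#'     (increase) or `k < 0` (decrease).}
#'   \item{saturation}{`y = y0 + A * (1 - exp(-k * t))`.}
#'   \item{linear}{`y = a + b * t` by ordinary least squares.}
#'   \item{constant}{horizontal fit through the sample mean; `r2 = 0` by
#'     convention.}
#' }
#' Nonlinear families are fitted by Levenberg-Marquardt least squares with
#' starting values from a log-linear (exponential) or range-based
#' (saturation) heuristic. The r-squared is `1 - SS_res/SS_tot` on the
#' original scale.
#'
#' @param days Time points.
#' @param y Observed values.
#' @param family One of `"exp_increase"`, `"exp_decrease"`, `"saturation"`,
#'   `"linear"`, `"constant"`.
#' @return A list with `family`, `params` (named list), `r2`, `fitted`.
#' @examples
#' t <- 0:100
#' fit_growth_curve(t, 2 * exp(0.005 * t), "exp_increase")$params$k  # 0.005
#' @export
fit_growth_curve <- function(days, y,
                             family = c("exp_increase", "exp_decrease",
                                        "saturation", "linear", "constant")) {
  family <- match.arg(family)
  stopifnot(length(days) == length(y), all(is.finite(days)),
            all(is.finite(y)))
  npar <- switch(family, constant = 1L, linear = 2L, exp_increase = 2L,
                 exp_decrease = 2L, saturation = 3L)
  if (length(days) < npar + 1L) {
    stop(sprintf("family '%s' needs at least %d points", family, npar + 1L),
         call. = FALSE)
  }
  df <- data.frame(t = days, y = y)
  ss_tot <- sum((y - mean(y))^2)
  finish <- function(params, fitted) {
    ss_res <- sum((y - fitted)^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    list(family = family, params = params, r2 = r2, fitted = fitted)
  }

  if (family == "constant") {
    m <- mean(y)
    out <- finish(list(mean = m), rep(m, length(y)))
    out$r2 <- 0  # a mean-only model explains no variance by convention
    return(out)
  }
  if (family == "linear") {
    fit <- stats::lm(y ~ t, data = df)
    co <- stats::coef(fit)
    return(finish(list(intercept = unname(co[1L]), slope = unname(co[2L])),
                  unname(stats::fitted(fit))))
  }
  if (family %in% c("exp_increase", "exp_decrease")) {
    if (any(y <= 0)) {
      stop("exponential families require positive observations", call. = FALSE)
    }
    lfit <- stats::lm(log(y) ~ t, data = df)
    start <- list(y0 = exp(unname(stats::coef(lfit)[1L])),
                  k = unname(stats::coef(lfit)[2L]))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 * exp(k * t), data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop(sprintf("exponential fit did not converge: %s", conditionMessage(e)),
             call. = FALSE)
      })
    co <- as.list(stats::coef(fit))
    if (family == "exp_increase" && co$k < 0) {
      warning("best exponential fit has a negative rate", call. = FALSE)
    }
    if (family == "exp_decrease" && co$k > 0) {
      warning("best exponential fit has a positive rate", call. = FALSE)
    }
    return(finish(co, unname(stats::fitted(fit))))
  }
  # saturation: y = y0 + A * (1 - exp(-k * t))
  rng <- diff(range(days))
  start <- list(y0 = y[which.min(days)], A = diff(range(y)),
                k = if (rng > 0) 3 / rng else 1)
  if (start$A == 0) start$A <- max(abs(y)) * 0.1 + 1e-8
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * (1 - exp(-k * t)), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(sprintf("saturation fit did not converge: %s", conditionMessage(e)),
           call. = FALSE)
    })
  finish(as.list(stats::coef(fit)), unname(stats::fitted(fit)))
}

#' Linear correlation between two series
#'
#' Ordinary least squares of `y` on `x` with a two-sided t-test on the slope,
#' as used for the digested-symbiont versus area-increase relationships.
#'
#' @param x Predictor series (>= 3 points, not constant).
#' @param y Response series.
#' @return A list with `slope`, `intercept`, `r2`, `p` (two-sided p-value for
#'   the slope), `n`.
#' @examples
#' linear_correlation(1:10, 2 * (1:10) + 1)
#' @export
linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("need at least 3 points for a slope test", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("`x` is constant", call. = FALSE)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  se_slope <- sqrt(ss_res / (n - 2) / sxx)
  # exact fits give se 0: the slope is then known with certainty (p = 0)
  tval <- if (se_slope == 0) {
    if (slope == 0) 0 else Inf * sign(slope)
  } else {
    slope / se_slope
  }
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, r2 = r2, p = p, n = n)
}
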
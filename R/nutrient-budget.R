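#' Nutrient drawdown series from a pulse incubation
#'
#' Concentrations measured at fixed minutes within one closed 2-h incubation,
#' together with the tank volume. A second nutrient spike is typically
#' delivered at 60 min, so the concentration may jump upward between
#' consecutive samples.
#'
#' @param minutes Sampling times (min), strictly increasing.
#' @param conc Concentrations at `minutes` (µM, >= 0).
#' @param volume Tank volume (L, > 0).
#' @param label `"treatment"` or `"control"`.
#' @return An object of class `drawdown_series`.
#' @export
drawdown_series <- function(minutes, conc, volume,
                            label = c("treatment", "control")) {
  label <- match.arg(label)
  stopifnot(length(minutes) == length(conc), length(minutes) >= 1,
            all(is.finite(minutes)), all(is.finite(conc)))
  if (any(diff(minutes) <= 0)) {
    stop("`minutes` must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("`volume` must be a single positive number (L)", call. = FALSE)
  }
  structure(list(minutes = minutes, conc = conc, volume = volume,
                 label = label),
            class = "drawdown_series")
}

#' @export
print.drawdown_series <- function(x, ...) {
  cat(sprintf("Drawdown series (%s), %d samples over %g-%g min, V = %g L\n",
              x$label, length(x$minutes), min(x$minutes), max(x$minutes),
              x$volume))
  invisible(x)
}

#' Integrate nutrient removal over a pulse incubation
#'
#' Sums the decline in nutrient amount (concentration change times volume)
#' over consecutive sampling intervals of the treatment incubation, with the
#' control series subtracted as background. Intervals across which the
#' treatment concentration *rises* are re-spike boundaries and are excluded
#' (a spike is not negative uptake). Intervals where the treatment declines
#' but the control declines faster yield negative net removal; these are
#' retained with a warning so that averaging across measurement days stays
#' unbiased.
#'
#' @param treatment A [drawdown_series] from the nutrient-spiked tank.
#' @param control A [drawdown_series] from the nutrient-limited control tank;
#'   interpolated onto the treatment grid if the grids differ.
#' @return Net removal in µmol. Attribute `excluded_intervals` gives the
#'   number of spike intervals excluded.
#' @examples
#' trt <- drawdown_series(c(0, 60, 120), c(10, 7.5, 5), volume = 3.5)
#' ctl <- drawdown_series(c(0, 60, 120), c(0.7, 0.7, 0.7), volume = 3.5,
#'                        label = "control")
#' integrate_removal(trt, ctl)  # 17.5 umol
#' @export
integrate_removal <- function(treatment, control) {
  stopifnot(inherits(treatment, "drawdown_series"),
            inherits(control, "drawdown_series"))
  if (length(treatment$minutes) < 2L) {
    stop("treatment series needs at least two samples", call. = FALSE)
  }
  if (!isTRUE(all.equal(treatment$volume, control$volume))) {
    stop("treatment and control volumes differ", call. = FALSE)
  }
  ctl_conc <- if (identical(treatment$minutes, control$minutes)) {
    control$conc
  } else {
    stats::approx(control$minutes, control$conc, xout = treatment$minutes,
                  rule = 2)$y
  }
  d_trt <- -diff(treatment$conc)       # decline > 0 means uptake
  d_ctl <- -diff(ctl_conc)
  spike <- d_trt < 0                   # concentration rose: re-spike boundary
  net <- (d_trt - d_ctl)[!spike]
  if (any(net < 0)) {
    warning("negative net removal in some intervals (control declined faster);",
            " retained unclamped", call. = FALSE)
  }
  out <- sum(net) * treatment$volume
  attr(out, "excluded_intervals") <- sum(spike)
  out
}

#' Area-normalized nutrient uptake rate
#'
#' @param removal Integrated removal over one incubation (µmol).
#' @param area Colony surface area (cm^2, > 0).
#' @param duration Incubation duration (h, > 0).
#' @return Uptake rate in µmol cm^-2 h^-1.
#' @examples
#' area_normalized_rate(17.5, area = 50, duration = 2)  # 0.175
#' @export
area_normalized_rate <- function(removal, area, duration) {
  stopifnot(is.numeric(removal))
  if (!is.numeric(area) || area <= 0) stop("`area` must be > 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be > 0", call. = FALSE)
  }
  removal / (area * duration)
}

#' Total uptake over an experiment, corrected for colony growth
#'
#' Accumulates an area-normalized uptake rate over all pulse days of an
#' experiment, evaluating the colony area on each pulse day by linear
#' interpolation of the observed area series (the area-growth correction:
#' larger colonies take up more per pulse). Pulse days are days `d` in
#' `0..n_days-1` with `(d mod 7) < pulses_per_week`.
#'
#' @param rate Uptake rate (µmol cm^-2 h^-1, >= 0).
#' @param area_series Data frame with columns `day` and `total_area` (cm^2)
#'   (falls back to `visible_area_cm2` if `total_area` is absent).
#' @param schedule A [pulse_schedule].
#' @param n_days Length of the experiment window (days).
#' @return Total uptake in µmol.
#' @export
accumulate_experiment <- function(rate, area_series, schedule = pulse_schedule(),
                                  n_days) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0,
            is.data.frame(area_series), "day" %in% names(area_series),
            n_days >= 1)
  area_col <- if ("total_area" %in% names(area_series)) {
    area_series$total_area
  } else if ("visible_area_cm2" %in% names(area_series)) {
    area_series$visible_area_cm2
  } else {
    stop("`area_series` needs a `total_area` or `visible_area_cm2` column",
         call. = FALSE)
  }
  days <- 0:(n_days - 1L)
  if (min(area_series$day) > min(days) || max(area_series$day) < max(days)) {
    stop("area series does not cover the experiment window", call. = FALSE)
  }
  pulse_days <- days[days %% 7 < schedule$pulses_per_week]
  if (length(pulse_days) == 0L) return(0)
  area_at <- stats::approx(area_series$day, area_col, xout = pulse_days)$y
  sum(rate * area_at * schedule$pulse_hours)
}

#' Per-compartment N and P budget ledger
#'
#' Collects the µmol amounts entering the mass balance: dissolved uptake from
#' the water and the particulate organic gains of symbiont and host tissue.
#' A gain exceeding the corresponding uptake violates mass balance and is
#' flagged with a warning (not an error: measurement noise can produce it).
#'
#' @param uptake_n,uptake_p Dissolved inorganic uptake from the water (µmol).
#' @param symbiont_gain_n,symbiont_gain_p Symbiont tissue gains (µmol).
#' @param host_gain_n,host_gain_p Host tissue gains (µmol).
#' @param area_ref Reference colony area (cm^2), for per-area reporting.
#' @return An object of class `budget_ledger`.
#' @export
budget_ledger <- function(uptake_n, uptake_p, symbiont_gain_n, symbiont_gain_p,
                          host_gain_n, host_gain_p, area_ref = NA_real_) {
  vals <- c(uptake_n = uptake_n, uptake_p = uptake_p,
            symbiont_gain_n = symbiont_gain_n,
            symbiont_gain_p = symbiont_gain_p,
            host_gain_n = host_gain_n, host_gain_p = host_gain_p)
  if (any(vals < 0)) stop("ledger amounts must be non-negative", call. = FALSE)
  flag <- (symbiont_gain_n + host_gain_n > uptake_n) ||
    (symbiont_gain_p + host_gain_p > uptake_p)
  if (flag) {
    warning("tissue gains exceed dissolved uptake; mass-balance sanity flag set",
            call. = FALSE)
  }
  structure(c(as.list(vals), list(area_ref = area_ref, balance_flag = flag)),
            class = "budget_ledger")
}

#' @export
print.budget_ledger <- function(x, ...) {
  cat("N/P budget ledger (umol):\n")
  cat(sprintf("  uptake        N %8.3g   P %8.3g\n", x$uptake_n, x$uptake_p))
  cat(sprintf("  symbiont gain N %8.3g   P %8.3g\n",
              x$symbiont_gain_n, x$symbiont_gain_p))
  cat(sprintf("  host gain     N %8.3g   P %8.3g\n",
              x$host_gain_n, x$host_gain_p))
  if (isTRUE(x$balance_flag)) cat("  [!] gains exceed uptake\n")
  invisible(x)
}

#' Conversion efficiency of dissolved nutrients into tissue
#'
#' Fraction of the dissolved inorganic nutrient taken up from the water that
#' ends up as particulate organic N or P in a tissue compartment, reported as
#' a percentage.
#'
#' @param gain Tissue gain (µmol, >= 0).
#' @param uptake Dissolved uptake (µmol, > 0).
#' @return Efficiency in percent.
#' @examples
#' conversion_efficiency(4.8, 121)   # ~4.0 % (symbiont N)
#' conversion_efficiency(0.14, 5.7)  # ~2.5 % (symbiont P)
#' @export
conversion_efficiency <- function(gain, uptake) {
  stopifnot(is.numeric(gain), is.numeric(uptake))
  if (any(uptake <= 0)) stop("`uptake` must be positive", call. = FALSE)
  if (any(gain < 0)) stop("`gain` must be non-negative", call. = FALSE)
  100 * gain / uptake
}

#' Budget closure: digested-symbiont nutrients versus host gain
#'
#' Ratio of the N (and P) contained in the digested symbiont fraction to the
#' N (and P) gained by the host tissue. Ratios >= 1 mean digestion alone can
#' supply the host's growth.
#'
#' @param ledger A [budget_ledger] (host gains must be positive).
#' @param digested_n,digested_p Nutrient content of the digested symbiont
#'   fraction (µmol).
#' @return A list with `ratio_n` and `ratio_p`.
#' @examples
#' led <- budget_ledger(121, 5.7, 4.8, 0.14, 8.4, 0.35)
#' budget_closure(led, digested_n = 25.2, digested_p = 0.665)
#' @export
budget_closure <- function(ledger, digested_n, digested_p) {
  stopifnot(inherits(ledger, "budget_ledger"))
  if (ledger$host_gain_n <= 0 || ledger$host_gain_p <= 0) {
    stop("host gains must be positive to form closure ratios", call. = FALSE)
  }
  list(ratio_n = digested_n / ledger$host_gain_n,
       ratio_p = digested_p / ledger$host_gain_p)
}
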
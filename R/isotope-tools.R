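#' 15N/14N ratio of atmospheric N2, the reference for the delta-15N scale
#' @format A length-one numeric (dimensionless isotope ratio).
#' @export
R_AIR_N2 <- 0.0036765

#' delta-15N from isotope ratios
#'
#' `delta15N = ((R_sample / R_standard) - 1) * 1000`, in per mil, where R is
#' the heavy-to-light isotope ratio (15N/14N). The standard defaults to
#' atmospheric N2.
#'
#' @param r_sample Sample 15N/14N ratio(s).
#' @param r_standard Standard ratio (> 0); default atmospheric N2.
#' @return delta-15N in per mil.
#' @examples
#' delta15n_from_ratio(1.005 * R_AIR_N2)  # 5 per mil
#' @export
delta15n_from_ratio <- function(r_sample, r_standard = R_AIR_N2) {
  if (!is.numeric(r_standard) || length(r_standard) != 1L || r_standard <= 0) {
    stop("`r_standard` must be a single positive ratio", call. = FALSE)
  }
  ((r_sample / r_standard) - 1) * 1000
}

#' Isotope ratio from delta-15N (inverse of [delta15n_from_ratio])
#'
#' @param delta delta-15N in per mil.
#' @inheritParams delta15n_from_ratio
#' @return 15N/14N ratio(s).
#' @export
ratio_from_delta15n <- function(delta, r_standard = R_AIR_N2) {
  if (!is.numeric(r_standard) || length(r_standard) != 1L || r_standard <= 0) {
    stop("`r_standard` must be a single positive ratio", call. = FALSE)
  }
  (delta / 1000 + 1) * r_standard
}

#' Enrichment fold of labelled samples over controls
#'
#' Ratio of mean treated delta-15N to mean control delta-15N, the summary
#' used to show that 15N-pulse treatments enriched host and symbiont tissue
#' by orders of magnitude over controls. Defined on the delta scale, so the
#' control mean must be positive; for controls at or below 0 per mil compute
#' the ratio of isotope ratios via [ratio_from_delta15n()] instead.
#'
#' @param treated Numeric vector of treated delta-15N values (per mil).
#' @param control Numeric vector of control delta-15N values (per mil).
#' @return Fold enrichment (dimensionless).
#' @examples
#' enrichment_fold(c(1150, 1250), c(4, 6))  # 240
#' @export
enrichment_fold <- function(treated, control) {
  if (length(treated) == 0L || length(control) == 0L) {
    stop("`treated` and `control` must be non-empty", call. = FALSE)
  }
  m_ctl <- mean(control)
  if (!is.finite(m_ctl) || m_ctl <= 0) {
    stop("control mean delta-15N is not positive; fold is undefined on the ",
         "delta scale (use ratio_from_delta15n and compare ratios)",
         call. = FALSE)
  }
  mean(treated) / m_ctl
}

#' Two-endmember mixing endmembers
#'
#' Guano and zooplankton delta-15N signatures framing the linear mixing
#' model, with an optional trophic discrimination offset subtracted from the
#' sample before mixing (default 0: no explicit offset is applied).
#'
#' @param delta_guano Guano endmember (per mil).
#' @param delta_zoo Zooplankton endmember (per mil); must differ from
#'   `delta_guano`.
#' @param trophic_offset Discrimination offset (per mil, default 0).
#' @return An object of class `mixing_endmembers`.
#' @export
mixing_endmembers <- function(delta_guano, delta_zoo, trophic_offset = 0) {
  stopifnot(is.numeric(delta_guano), is.numeric(delta_zoo),
            length(delta_guano) == 1L, length(delta_zoo) == 1L)
  if (delta_guano == delta_zoo) {
    stop("endmembers must differ", call. = FALSE)
  }
  structure(list(delta_guano = delta_guano, delta_zoo = delta_zoo,
                 trophic_offset = trophic_offset),
            class = "mixing_endmembers")
}

#' Guano-derived fraction from a two-endmember delta-15N mixing model
#'
#' Linear source attribution: the fraction of a sample's nitrogen traceable
#' to the guano endmember is
#' `f = (delta - offset - delta_zoo) / (delta_guano - delta_zoo)`.
#' Samples outside the endmember interval give f outside \[0, 1\] and are
#' flagged, not clamped.
#'
#' @param sample_delta Sample delta-15N value(s) (per mil).
#' @param endmembers A [mixing_endmembers] object.
#' @return Numeric vector of fractions with attribute `out_of_range`
#'   (logical, per sample).
#' @examples
#' em <- mixing_endmembers(delta_guano = 13, delta_zoo = 5)
#' mixing_fraction(9, em)  # 0.5
#' @export
mixing_fraction <- function(sample_delta, endmembers) {
  stopifnot(inherits(endmembers, "mixing_endmembers"),
            is.numeric(sample_delta))
  f <- (sample_delta - endmembers$trophic_offset - endmembers$delta_zoo) /
    (endmembers$delta_guano - endmembers$delta_zoo)
  attr(f, "out_of_range") <- f < 0 | f > 1
  f
}

#' Mixing-model summary for a field isotope dataset
#'
#' Estimates the guano-derived fraction of host nitrogen from a table of
#' field isotope samples (as produced by [generate_field_isotopes()]):
#' endmembers are the arithmetic means of the guano and zooplankton samples,
#' the group estimate is the mixing fraction of the mean host delta-15N, and
#' per-sample fractions are reported with out-of-range flags.
#'
#' @param samples Data frame with columns `compartment` and `delta15N_permil`.
#' @param trophic_offset Discrimination offset passed to
#'   [mixing_endmembers()].
#' @return A list with `f_hat`, `endmembers`, `per_sample_f`, `flags`, `n`.
#' @export
mixing_report <- function(samples, trophic_offset = 0) {
  stopifnot(is.data.frame(samples),
            all(c("compartment", "delta15N_permil") %in% names(samples)))
  d <- function(comp) samples$delta15N_permil[samples$compartment == comp]
  for (comp in c("host", "guano", "zooplankton")) {
    if (length(d(comp)) == 0L) {
      stop(sprintf("no '%s' samples in the dataset", comp), call. = FALSE)
    }
  }
  em <- mixing_endmembers(mean(d("guano")), mean(d("zooplankton")),
                          trophic_offset)
  per_sample <- mixing_fraction(d("host"), em)
  f_hat <- mixing_fraction(mean(d("host")), em)
  list(f_hat = as.numeric(f_hat), endmembers = em,
       per_sample_f = as.numeric(per_sample),
       flags = attr(per_sample, "out_of_range"),
       n = length(per_sample))
}
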
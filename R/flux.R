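#' Epoch table constructor
#'
#' Convenience builder for the per-epoch retreat-rate table used by the
#' flux-budget arithmetic: contiguous, non-overlapping year spans with a
#' mean retreat rate each.
#'
#' @param year_from,year_to Numeric vectors of epoch limits.
#' @param rate_m_per_a Mean retreat rate in each epoch (m/a, >= 0).
#' @return data.frame with an added `duration_a` column.
#' @examples
#' epochs <- epoch_rates(c(1939, 1995), c(1995, 2015), c(1.16, 5.76))
#' weighted_mean_rate(epochs)  # 2.37 m/a
#' @export
epoch_rates <- function(year_from, year_to, rate_m_per_a) {
  stopifnot(length(year_from) == length(year_to),
            length(year_to) == length(rate_m_per_a),
            all(year_to > year_from), all(rate_m_per_a >= 0))
  o <- order(year_from)
  year_from <- year_from[o]; year_to <- year_to[o]
  rate_m_per_a <- rate_m_per_a[o]
  if (length(year_from) > 1 &&
      !isTRUE(all.equal(year_from[-1], year_to[-length(year_to)])))
    stop("epochs must be contiguous and non-overlapping")
  data.frame(year_from, year_to, rate_m_per_a,
             duration_a = year_to - year_from)
}

#' Duration-weighted mean retreat rate
#'
#' @param epochs data.frame from [epoch_rates()].
#' @return Rate in m/a.
#' @export
weighted_mean_rate <- function(epochs) {
  if (nrow(epochs) == 0) stop("empty epoch list")
  sum(epochs$rate_m_per_a * epochs$duration_a) / sum(epochs$duration_a)
}

#' Share of cumulative retreat (or melt) contributed by one epoch
#'
#' With a fixed boundary length, cumulative retreat distance is
#' proportional to melted volume, so this is also each epoch's share of the
#' total melt.
#'
#' @param epochs data.frame from [epoch_rates()].
#' @param target_epoch Row index of the epoch of interest.
#' @return Percentage in \[0, 100\].
#' @export
epoch_share <- function(epochs, target_epoch) {
  stopifnot(target_epoch >= 1, target_epoch <= nrow(epochs))
  tot <- sum(epochs$rate_m_per_a * epochs$duration_a)
  if (tot == 0) stop("total retreat is zero; shares undefined")
  100 * epochs$rate_m_per_a[target_epoch] * epochs$duration_a[target_epoch] / tot
}

#' Annual melt volume as a percentage of lake volume
#'
#' @param annual_melt_m3 Annual melt input (m3/a).
#' @param lake_volume_m3 Lake volume (m3), > 0. Default 8.72e8 m3
#'   (0.872 km3).
#' @return Percentage.
#' @export
melt_fraction_of_lake <- function(annual_melt_m3, lake_volume_m3 = 8.72e8) {
  if (lake_volume_m3 <= 0) stop("lake volume must be positive")
  100 * annual_melt_m3 / lake_volume_m3
}

#' Volumetric cryoconite flux into the lake
#'
#' The melting ice front sweeps `swept_area_m2_per_a` of glacier surface
#' into the lake each year; the fraction `coverage_fraction` of that
#' surface is cryoconite holes carrying a sediment/biota layer of the given
#' thickness, so the volumetric flux is the product of the three.
#'
#' @param coverage_fraction Cryoconite coverage as a fraction in \[0, 1\].
#' @param thickness_m Mean cryoconite layer thickness (default 0.01 m).
#' @param swept_area_m2_per_a Glacier surface area delivered to the lake
#'   per year (m2/a).
#' @return Flux in m3/a.
#' @export
cryoconite_flux <- function(coverage_fraction, thickness_m = 0.01,
                            swept_area_m2_per_a) {
  stopifnot(coverage_fraction >= 0, thickness_m >= 0,
            swept_area_m2_per_a >= 0)
  if (coverage_fraction > 1) stop("coverage_fraction must be <= 1")
  coverage_fraction * thickness_m * swept_area_m2_per_a
}

#' Cryoconite flux as percentages of annual melt and of lake volume
#'
#' @param flux_m3_per_a Volumetric cryoconite flux (m3/a).
#' @param annual_melt_m3_per_a Annual melt volume (m3/a), > 0.
#' @param lake_volume_m3 Lake volume (m3), > 0.
#' @return Named list `pct_of_melt`, `pct_of_lake`.
#' @export
flux_fractions <- function(flux_m3_per_a, annual_melt_m3_per_a,
                           lake_volume_m3 = 8.72e8) {
  if (annual_melt_m3_per_a <= 0 || lake_volume_m3 <= 0)
    stop("denominators must be positive")
  list(pct_of_melt = 100 * flux_m3_per_a / annual_melt_m3_per_a,
       pct_of_lake = 100 * flux_m3_per_a / lake_volume_m3)
}

#' Full flux budget from its components
#'
#' Combines epoch rates, coverage extremes and the flux constants into one
#' report: weighted mean rate, per-epoch shares, low/high cryoconite flux
#' and their fractions of annual melt and lake volume.
#'
#' @param epochs data.frame from [epoch_rates()].
#' @param coverage_low,coverage_high Coverage fractions bounding the flux.
#' @param swept_area_m2_per_a Swept area per year (m2/a); typically
#'   weighted mean rate times reference boundary length.
#' @param annual_melt_m3_per_a Annual melt volume (m3/a).
#' @param thickness_m Cryoconite layer thickness (m).
#' @param lake_volume_m3 Lake volume (m3).
#' @return List of class `flux_budget`.
#' @export
flux_budget <- function(epochs, coverage_low, coverage_high,
                        swept_area_m2_per_a, annual_melt_m3_per_a,
                        thickness_m = 0.01, lake_volume_m3 = 8.72e8) {
  stopifnot(coverage_low <= coverage_high)
  f_low <- cryoconite_flux(coverage_low, thickness_m, swept_area_m2_per_a)
  f_high <- cryoconite_flux(coverage_high, thickness_m, swept_area_m2_per_a)
  fr <- flux_fractions(f_high, annual_melt_m3_per_a, lake_volume_m3)
  structure(list(
    weighted_rate_m_per_a = weighted_mean_rate(epochs),
    epoch_share_pct = vapply(seq_len(nrow(epochs)),
                             function(i) epoch_share(epochs, i), numeric(1)),
    flux_low_m3_per_a = f_low, flux_high_m3_per_a = f_high,
    pct_of_annual_melt = fr$pct_of_melt, pct_of_lake_volume = fr$pct_of_lake,
    melt_pct_of_lake = melt_fraction_of_lake(annual_melt_m3_per_a,
                                             lake_volume_m3),
    inputs = list(thickness_m = thickness_m, lake_volume_m3 = lake_volume_m3,
                  swept_area_m2_per_a = swept_area_m2_per_a,
                  annual_melt_m3_per_a = annual_melt_m3_per_a,
                  coverage_low = coverage_low, coverage_high = coverage_high)),
    class = "flux_budget")
}

#' @export
print.flux_budget <- function(x, ...) {
  cat(sprintf("Weighted retreat rate: %.2f m/a\n", x$weighted_rate_m_per_a))
  cat(sprintf("Cryoconite flux: %.2f - %.2f m3/a\n",
              x$flux_low_m3_per_a, x$flux_high_m3_per_a))
  cat(sprintf("Max flux = %.3g%% of annual melt, %.3g%% of lake volume\n",
              x$pct_of_annual_melt, x$pct_of_lake_volume))
  invisible(x)
}
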
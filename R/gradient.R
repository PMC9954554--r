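#' Immunodrop indicator
#'
#' The immunodrop at rank `r` is the ratio of CD8+ density in the stromal
#' band `-r` to the paired epithelial band `r`, `ID(r) = rho[-r] / rho[r]`.
#' Values above 1 mean the density drops on entering the epithelium. The
#' result is undefined (`NA`, with a `reason` attribute) when the epithelial
#' band density is zero or either band has zero area.
#'
#' @param profile a [band_density_profile()].
#' @param r positive band rank; both `-r` and `r` must be present.
#' @param eps optional pseudocount added to both densities before forming
#'   the ratio (default 0, i.e. off); when positive it removes the
#'   zero-denominator case at the cost of shrinking extreme ratios.
#' @return A single number (dimensionless), or `NA` with attribute `reason`.
#' @export
immunodrop <- function(profile, r, eps = 0) {
  stopifnot(inherits(profile, "band_density_profile"))
  if (!.is_count(r)) stop("`r` must be a positive integer", call. = FALSE)
  if (!all(c(-r, r) %in% profile$rank))
    stop("ranks -", r, " and ", r, " must be present in the profile",
         call. = FALSE)
  lo <- profile[profile$rank == -r, ]
  hi <- profile[profile$rank == r, ]
  if (!lo$defined || !hi$defined)
    return(structure(NA_real_, reason = "zero-area band"))
  num <- lo$density_per_mm2 + eps
  den <- hi$density_per_mm2 + eps
  if (den == 0) return(structure(NA_real_, reason = "zero-denominator"))
  num / den
}

#' Center-of-mass indicator
#'
#' The density-weighted mean band rank over the interface zone of half-width
#' `half_width` bands on each side: `CM = sum(r_i * rho_i) / sum(rho_i)`
#' over ranks `-R'..-1, 1..R'`. Negative values indicate CD8+ mass skewed
#' toward the stroma. Undefined (`NA`, reason attribute) when the total
#' density is zero.
#'
#' @param profile a [band_density_profile()].
#' @param half_width positive integer number of bands per side; the profile
#'   must contain all ranks up to `half_width` on both sides.
#' @return A single number in `[-half_width, half_width]`, or `NA` with
#'   attribute `reason`.
#' @export
center_of_mass <- function(profile, half_width) {
  stopifnot(inherits(profile, "band_density_profile"))
  if (!.is_count(half_width))
    stop("`half_width` must be a positive integer", call. = FALSE)
  need <- .rank_levels(half_width)
  if (!all(need %in% profile$rank))
    stop("`half_width` exceeds the profile's rank range", call. = FALSE)
  sub <- profile[profile$rank %in% need, ]
  if (any(!sub$defined))
    return(structure(NA_real_, reason = "zero-area band"))
  tot <- sum(sub$density_per_mm2)
  if (tot == 0) return(structure(NA_real_, reason = "zero total density"))
  sum(sub$rank * sub$density_per_mm2) / tot
}

#' Gradient indicators over a grid of interface-zone widths
#'
#' Evaluates the immunodrop at every band pair and the center of mass at
#' every interface-zone half-width representable in the profile, over widths
#' from 20 to 300 um by default (clipped to the profile's range). Variant
#' labels carry the band interval in micrometers, e.g. `"ID 10-20 um"` for
#' `ID(2)` and `"CM 0-20 um"` for the center of mass over ranks -2..2.
#'
#' @param profile a [band_density_profile()].
#' @param widths_um interface-zone widths (one side, micrometers); must be
#'   multiples of the profile's band width and within its range. `NULL`
#'   (default) uses `seq(20, 300, by = 10)` clipped to the profile.
#' @return A data frame of class `gradient_indicators` with columns
#'   `indicator` ("ID"/"CM"), `variant_label`, `rank` (band rank or
#'   half-width), `width_um`, `value`, `defined`, `reason`.
#' @export
variant_grid <- function(profile, widths_um = NULL) {
  stopifnot(inherits(profile, "band_density_profile"))
  w <- attr(profile, "band_width_um")
  Rmax <- max(profile$rank)
  if (is.null(widths_um)) {
    widths_um <- seq(2 * w, 300, by = w)
    widths_um <- widths_um[widths_um <= Rmax * w]
  }
  ratio <- widths_um / w
  if (any(abs(ratio - round(ratio)) > 1e-8))
    stop("`widths_um` must be multiples of the band width", call. = FALSE)
  if (any(ratio > Rmax))
    stop("requested width exceeds the profile's rank range", call. = FALSE)
  Rgrid <- sort(unique(as.integer(round(ratio))))
  rows <- list()
  for (r in seq_len(max(Rgrid))) {
    v <- immunodrop(profile, r)
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = "ID",
      variant_label = sprintf("ID %g-%g um", (r - 1) * w, r * w),
      rank = r, width_um = r * w,
      value = as.numeric(v), defined = !is.na(v),
      reason = if (is.na(v)) attr(v, "reason") else "")
  }
  for (Rp in seq_len(max(Rgrid))) {
    v <- center_of_mass(profile, Rp)
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = "CM",
      variant_label = sprintf("CM 0-%g um", Rp * w),
      rank = Rp, width_um = Rp * w,
      value = as.numeric(v), defined = !is.na(v),
      reason = if (is.na(v)) attr(v, "reason") else "")
  }
  structure(do.call(rbind, rows),
            class = c("gradient_indicators", "data.frame"))
}
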
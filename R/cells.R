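#' Construct a cell centroid set
#'
#' Cell centroids in the slide's micrometer coordinate frame (`x` along
#' columns, `y` along rows, origin at the top-left raster corner), each
#' flagged CD8 positive or negative. Only CD8+ cells enter density
#' computations; negatives are retained for I/O completeness.
#'
#' @param x_um,y_um numeric centroid coordinates in micrometers.
#' @param cd8_positive logical (or 0/1) marker-positivity flag.
#' @return A `cell_set`: a data frame with columns `x_um`, `y_um`,
#'   `cd8_positive`.
#' @export
cell_set <- function(x_um, y_um, cd8_positive = TRUE) {
  x_um <- as.numeric(x_um); y_um <- as.numeric(y_um)
  n <- length(x_um)
  if (length(y_um) != n)
    stop("`x_um` and `y_um` must have equal length", call. = FALSE)
  if (n && (!all(is.finite(x_um)) || !all(is.finite(y_um))))
    stop("cell coordinates must be finite", call. = FALSE)
  cd8_positive <- rep_len(as.logical(cd8_positive), n)
  structure(data.frame(x_um = x_um, y_um = y_um, cd8_positive = cd8_positive),
            class = c("cell_set", "data.frame"))
}

#' Read cell centroids from CSV
#'
#' @param path CSV with columns `x_um`, `y_um`, `cd8_positive` (0/1); other
#'   column names can be mapped via `columns`.
#' @param columns named character vector mapping the canonical names to the
#'   file's column names.
#' @return A [cell_set()].
#' @export
read_cells_csv <- function(path, columns = c(x_um = "x_um", y_um = "y_um",
                                             cd8_positive = "cd8_positive")) {
  d <- utils::read.csv(path)
  miss <- setdiff(columns, names(d))
  if (length(miss))
    stop("cell CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cell_set(d[[columns[["x_um"]]]], d[[columns[["y_um"]]]],
           d[[columns[["cd8_positive"]]]] != 0)
}

# pixel (row, col) containing each point; 0 marks out-of-raster points
.cells_to_pixels <- function(cells, nr, nc, px) {
  col <- floor(cells$x_um / px) + 1L
  row <- floor(cells$y_um / px) + 1L
  col[cells$x_um == nc * px] <- nc   # right/bottom raster edge belongs inside
  row[cells$y_um == nr * px] <- nr
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  list(row = ifelse(inside, row, 0L), col = ifelse(inside, col, 0L),
       inside = inside)
}

#' Count CD8+ cells per interface-zone band
#'
#' Each CD8+ centroid contributes one count to the band rank of the pixel
#' containing it. Centroids on sentinel pixels (artifact, background,
#' outside the interface zone) contribute to no band; centroids outside the
#' raster bounds are excluded and reported, not fatal.
#'
#' @param cells a [cell_set()] in the same micrometer frame as the mask.
#' @param band_map a [compute_band_map()] result.
#' @return Named integer vector of counts over ranks `-R..-1, 1..R`, with
#'   attributes `n_cd8` (total CD8+ input cells), `n_outside` (CD8+ cells on
#'   sentinel pixels) and `n_excluded` (CD8+ cells off the raster).
#' @export
assign_cells_to_bands <- function(cells, band_map) {
  stopifnot(inherits(cells, "cell_set"), inherits(band_map, "band_map"))
  pos <- cells[cells$cd8_positive, , drop = FALSE]
  nr <- nrow(band_map$rank_raster); nc <- ncol(band_map$rank_raster)
  loc <- .cells_to_pixels(pos, nr, nc, band_map$pixel_size_um)
  n_excluded <- sum(!loc$inside)
  if (n_excluded > 0L)
    message(n_excluded, " CD8+ centroid(s) outside raster bounds excluded")
  ranks <- rep(NA_integer_, nrow(pos))
  if (any(loc$inside))
    ranks[loc$inside] <- band_map$rank_raster[
      cbind(loc$row[loc$inside], loc$col[loc$inside])]
  lv <- .rank_levels(band_map$max_rank)
  counts <- table(factor(ranks, levels = lv))
  out <- as.integer(counts)
  names(out) <- names(counts)
  attr(out, "n_cd8") <- nrow(pos)
  attr(out, "n_outside") <- sum(loc$inside & is.na(ranks))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-band CD8+ density profile
#'
#' Densities are counts divided by band areas, in cells/mm^2. Bands with
#' zero area have undefined density (`NA`, `defined = FALSE`).
#'
#' @param counts named nonnegative integer vector keyed by signed rank, as
#'   from [assign_cells_to_bands()].
#' @param areas_mm2 named nonnegative areas keyed by the same ranks, as from
#'   [compute_band_map()] (`$areas_mm2`).
#' @param band_width_um band width carried along for variant labeling.
#' @return A `band_density_profile`: data frame with columns `rank`, `count`,
#'   `area_mm2`, `density_per_mm2`, `defined`.
#' @export
band_density_profile <- function(counts, areas_mm2, band_width_um = 10) {
  if (is.null(names(counts)) || is.null(names(areas_mm2)) ||
      !setequal(names(counts), names(areas_mm2)))
    stop("`counts` and `areas_mm2` must be keyed by identical rank sets",
         call. = FALSE)
  areas_mm2 <- areas_mm2[names(counts)]
  if (any(counts < 0) || any(areas_mm2 < 0))
    stop("counts and areas must be nonnegative", call. = FALSE)
  rank <- as.integer(names(counts))
  o <- order(rank)
  rank <- rank[o]
  count <- as.numeric(counts)[o]
  area <- as.numeric(areas_mm2)[o]
  defined <- area > 0
  dens <- ifelse(defined, count / area, NA_real_)
  structure(data.frame(rank = rank, count = count, area_mm2 = area,
                       density_per_mm2 = dens, defined = defined),
            band_width_um = band_width_um,
            class = c("band_density_profile", "data.frame"))
}

# profile constructor from raw density values (used by tests and examples)
#' Build a density profile directly from per-band densities
#'
#' Convenience constructor for analyses that start from band densities
#' rather than counts and areas (all bands get unit area).
#'
#' @param densities named numeric vector keyed by signed rank.
#' @param band_width_um band width in micrometers.
#' @return A `band_density_profile`.
#' @export
profile_from_densities <- function(densities, band_width_um = 10) {
  rank <- as.integer(names(densities))
  if (anyNA(rank)) stop("`densities` must be named by signed ranks", call. = FALSE)
  counts <- as.numeric(densities)
  names(counts) <- names(densities)
  areas <- rep(1, length(counts))
  names(areas) <- names(counts)
  band_density_profile(counts, areas, band_width_um = band_width_um)
}

#' Absolute CD8+ densities per tissue compartment
#'
#' Densities (cells/mm^2) over the whole epithelial and stromal compartments
#' (artifact and background pixels excluded from both counts and areas) and
#' over the interface zone (pixels with |rank| <= R).
#'
#' @inheritParams assign_cells_to_bands
#' @param mask the [tissue_mask()] the band map was computed from.
#' @return A list of class `compartment_densities` with elements
#'   `epithelial_density`, `stromal_density`, `overall_iz_density` (each `NA`
#'   when its compartment has zero area), plus the underlying counts and
#'   areas.
#' @export
compartment_densities <- function(cells, mask, band_map) {
  stopifnot(inherits(cells, "cell_set"), inherits(mask, "tissue_mask"),
            inherits(band_map, "band_map"))
  pos <- cells[cells$cd8_positive, , drop = FALSE]
  nr <- nrow(mask$labels); nc <- ncol(mask$labels)
  px <- mask$pixel_size_um
  loc <- .cells_to_pixels(pos, nr, nc, px)
  idx <- cbind(loc$row[loc$inside], loc$col[loc$inside])
  comp_at <- band_map$compartment[idx]
  iz_at <- !is.na(band_map$rank_raster[idx])
  a_px2 <- px^2 * 1e-6
  area_epi <- sum(band_map$compartment == 1L) * a_px2
  area_str <- sum(band_map$compartment == -1L) * a_px2
  area_iz <- sum(!is.na(band_map$rank_raster)) * a_px2
  dens <- function(count, area) if (area > 0) count / area else NA_real_
  structure(list(
    epithelial_density = dens(sum(comp_at == 1L), area_epi),
    stromal_density = dens(sum(comp_at == -1L), area_str),
    overall_iz_density = dens(sum(iz_at), area_iz),
    counts = c(epithelium = sum(comp_at == 1L), stroma = sum(comp_at == -1L),
               iz = sum(iz_at)),
    areas_mm2 = c(epithelium = area_epi, stroma = area_str, iz = area_iz)),
    class = "compartment_densities")
}

#' Write a band density profile to CSV
#'
#' @param profile a [band_density_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
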
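#' Default label codes for tissue masks
#'
#' Integer codes used in label rasters: 0 background, 1 epithelium, 2 stroma,
#' 3 artifact. All mask readers accept an alternative mapping with the same
#' four names.
#'
#' @export
default_label_codes <- function() {
  c(background = 0L, epithelium = 1L, stroma = 2L, artifact = 3L)
}

#' Construct a labeled tissue mask
#'
#' A tissue mask is the geometric substrate of the interface-zone analysis:
#' an integer label raster (epithelium / stroma / artifact / background) with
#' a known physical pixel size in micrometers.
#'
#' @param labels integer matrix of label codes; rows are image rows (y),
#'   columns are image columns (x).
#' @param pixel_size_um micrometers per pixel side (default 0.5, the scale of
#'   slides digitized at 20x magnification).
#' @param label_codes named integer vector mapping the four class names
#'   (`background`, `epithelium`, `stroma`, `artifact`) to raster codes.
#' @return An object of class `tissue_mask`: a list with elements `labels`,
#'   `pixel_size_um` and `label_codes`.
#' @examples
#' m <- matrix(c(1, 1, 2, 2), 2, 2)
#' mask <- tissue_mask(m, pixel_size_um = 0.5)
#' dim(mask$labels)
#' @export
tissue_mask <- function(labels, pixel_size_um = 0.5,
                        label_codes = default_label_codes()) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  req <- c("background", "epithelium", "stroma", "artifact")
  if (!all(req %in% names(label_codes)))
    stop("`label_codes` must name all of: ", paste(req, collapse = ", "),
         call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || !all(labels %in% label_codes))
    stop("every pixel must carry exactly one known label code", call. = FALSE)
  structure(
    list(labels = labels,
         pixel_size_um = as.numeric(pixel_size_um),
         label_codes = vapply(label_codes[req], as.integer, integer(1))),
    class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$label_codes,
                      labels = names(x$label_codes)))
  cat(sprintf("tissue_mask: %d x %d px at %g um/px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  print(tab)
  invisible(x)
}

# logical masks per compartment
.mask_is <- function(mask, what) {
  mask$labels == mask$label_codes[[what]]
}

#' Read a tissue mask from a PNG or TIFF label image
#'
#' Single-channel images are interpreted as integer label codes. PNG and TIFF
#' store intensities in `[0, 1]`; codes are recovered by scaling with 255 (or
#' 65535 for 16-bit content) and rounding.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @inheritParams tissue_mask
#' @return A [tissue_mask()].
#' @export
read_mask <- function(path, pixel_size_um = 0.5,
                      label_codes = default_label_codes()) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  codes <- round(img * 255)
  if (max(codes) > max(label_codes)) codes <- round(img * 65535)
  tissue_mask(matrix(as.integer(codes), nrow(img), ncol(img)),
              pixel_size_um = pixel_size_um, label_codes = label_codes)
}

#' Write a tissue mask as an 8-bit grayscale image
#'
#' @param mask a [tissue_mask()].
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  img <- mask$labels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported mask format: ", ext, call. = FALSE))
  invisible(path)
}

#' Rasterize GeoJSON polygon annotations into a tissue mask
#'
#' Reads a GeoJSON FeatureCollection whose features are (Multi)Polygons in
#' micrometer coordinates carrying a `class` property (`epithelium`,
#' `stroma` or `artifact`), and rasterizes them at a stated resolution with
#' even-odd scanline filling. Later features overwrite earlier ones where
#' they overlap; unclaimed pixels keep the `background` code.
#'
#' @param path GeoJSON file path.
#' @param pixel_size_um target resolution in micrometers per pixel.
#' @param width_um,height_um canvas extent; defaults to the annotation
#'   bounding box.
#' @inheritParams tissue_mask
#' @return A [tissue_mask()].
#' @export
read_mask_geojson <- function(path, pixel_size_um,
                              width_um = NULL, height_um = NULL,
                              label_codes = default_label_codes()) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("GeoJSON must be a FeatureCollection", call. = FALSE)
  polys <- list()     # list of (matrix ring, class)
  for (f in gj$features) {
    cls <- f$properties$class
    if (is.null(cls) || !cls %in% c("epithelium", "stroma", "artifact"))
      stop("feature property 'class' must be epithelium/stroma/artifact",
           call. = FALSE)
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (poly in rings) {
      ringmats <- lapply(poly, function(r)
        do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]]))))
      polys[[length(polys) + 1L]] <- list(rings = ringmats, class = cls)
    }
  }
  if (length(polys) == 0L) stop("no polygon features found", call. = FALSE)
  allxy <- do.call(rbind, unlist(lapply(polys, `[[`, "rings"),
                                 recursive = FALSE))
  if (is.null(width_um)) width_um <- max(allxy[, 1])
  if (is.null(height_um)) height_um <- max(allxy[, 2])
  nc <- max(1L, ceiling(width_um / pixel_size_um))
  nr <- max(1L, ceiling(height_um / pixel_size_um))
  labels <- matrix(label_codes[["background"]], nr, nc)
  for (p in polys) {
    inside <- matrix(FALSE, nr, nc)
    for (ring in p$rings)
      inside <- xor(inside, .rasterize_ring(ring, nr, nc, pixel_size_um))
    labels[inside] <- label_codes[[p$class]]
  }
  tissue_mask(labels, pixel_size_um = pixel_size_um,
              label_codes = label_codes)
}

# even-odd scanline fill of one ring; pixel centers at ((j-0.5), (i-0.5))*px
.rasterize_ring <- function(ring, nr, nc, px) {
  out <- matrix(FALSE, nr, nc)
  x <- ring[, 1] / px
  y <- ring[, 2] / px
  n <- length(x)
  if (n < 3L) return(out)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  for (i in seq_len(nr)) {
    yc <- i - 0.5
    crossing <- numeric(0)
    for (k in seq_len(length(x) - 1L)) {
      y0 <- y[k]; y1 <- y[k + 1L]
      if ((y0 <= yc) != (y1 <= yc)) {
        crossing <- c(crossing, x[k] + (yc - y0) / (y1 - y0) * (x[k + 1L] - x[k]))
      }
    }
    if (length(crossing) >= 2L) {
      crossing <- sort(crossing)
      for (k in seq(1L, length(crossing) - 1L, by = 2L)) {
        j0 <- max(1L, ceiling(crossing[k] + 0.5))
        j1 <- min(nc, floor(crossing[k + 1L] + 0.5))
        if (j0 <= j1) out[i, j0:j1] <- TRUE
      }
    }
  }
  out
}
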
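test_that("a straight epithelium-stroma interface is traced at its exact length", {
  mask <- half_plane_mask(n = 200, px = 0.5)
  ifc <- extract_interface(mask)
  expect_length(ifc$boundaries, 1L)
  expect_equal(interface_lengths(ifc), 200 * 0.5)
  expect_false(ifc$boundaries[[1]]$closed)
})

test_that("a circular epithelial island is traced within 2% of its circumference", {
  mask <- disk_mask(n = 240, r_px = 100, px = 0.5)   # radius 50 um
  ifc <- extract_interface(mask)
  expect_length(ifc$boundaries, 1L)
  expect_true(ifc$boundaries[[1]]$closed)
  expect_equal(interface_lengths(ifc), 2 * pi * 50, tolerance = 0.02)
})

test_that("epithelium touching only background or artifact yields no interface", {
  m <- matrix(CODES[["background"]], 30, 30)
  m[10:20, 10:20] <- CODES[["epithelium"]]
  m[1, 1] <- CODES[["stroma"]]               # isolated stroma, not adjacent
  ifc <- extract_interface(tissue_mask(m, 1))
  expect_length(ifc$boundaries, 0L)
  m[10:20, 21] <- CODES[["artifact"]]        # artifact edge adds nothing
  expect_length(extract_interface(tissue_mask(m, 1))$boundaries, 0L)
})

test_that("interface extraction requires both compartments and a pixel size", {
  m <- matrix(CODES[["epithelium"]], 10, 10)
  expect_error(extract_interface(tissue_mask(m, 1)), "stroma")
  expect_error(tissue_mask(matrix(1L, 2, 2), pixel_size_um = 0), "positive")
  expect_error(tissue_mask(matrix(9L, 2, 2)), "label")
})

test_that("short-boundary filtering keeps polylines at or above the threshold", {
  # four parallel epithelium strips of controlled interface lengths
  lengths_px <- c(500, 999, 1000, 2500)      # 1 um/px -> lengths in um
  nr <- 20; nc <- 2600
  m <- matrix(CODES[["background"]], nr, nc)
  for (k in seq_along(lengths_px)) {
    r <- 4 * k
    m[r, seq_len(lengths_px[k])] <- CODES[["epithelium"]]
    m[r + 1, seq_len(lengths_px[k])] <- CODES[["stroma"]]
  }
  ifc <- extract_interface(tissue_mask(m, 1))
  expect_setequal(round(interface_lengths(ifc)), lengths_px)
  kept <- filter_short_boundaries(ifc, 1000)
  expect_setequal(round(interface_lengths(kept)), c(1000, 2500))
  expect_length(filter_short_boundaries(ifc, 0)$boundaries, 4L)
  empty <- filter_short_boundaries(ifc, 1e9)
  expect_length(empty$boundaries, 0L)
  expect_length(filter_short_boundaries(empty, 1000)$boundaries, 0L)
  expect_error(filter_short_boundaries(ifc, -1), "nonnegative")
})

test_that("band ranks follow the signed half-open ceiling convention", {
  # interface at x = 40 um (px = 4, epithelium in columns 1-10)
  m <- matrix(CODES[["stroma"]], 20, 20)
  m[, 1:10] <- CODES[["epithelium"]]
  mask <- tissue_mask(m, 4)
  bm <- compute_band_map(mask, extract_interface(mask), 10, 40)
  expect_identical(bm$rank_raster[10, 11], -1L)   # d = 2
  expect_identical(bm$rank_raster[10, 13], -1L)   # d = 10 exactly: 10 in (0, 10]
  expect_identical(bm$rank_raster[10, 14], -2L)   # d = 14: in (10, 20]
  expect_identical(bm$rank_raster[10, 8], 1L)     # d = 10 exactly, epithelial side
  expect_identical(bm$rank_raster[10, 7], 2L)     # d = 14
})

test_that("a stroma pixel 15 um from the interface gets rank -2", {
  m2 <- matrix(CODES[["stroma"]], 12, 40)
  m2[, 1:20] <- CODES[["epithelium"]]
  mask2 <- tissue_mask(m2, 1)                 # interface at x = 20, px = 1
  bm2 <- compute_band_map(mask2, extract_interface(mask2), 10, 20)
  expect_identical(bm2$rank_raster[6, 35], -2L)  # center x = 34.5, d = 14.5
  expect_identical(bm2$rank_raster[6, 36], -2L)  # center x = 35.5, d = 15.5
})

test_that("half-plane band areas equal band width x interface length", {
  mask <- half_plane_mask(n = 200, px = 0.5)   # interface length 100 um
  ifc <- extract_interface(mask)
  bm <- compute_band_map(mask, ifc, 10, 50)
  expected <- 10 * 100 * 1e-6                  # mm^2 per band
  one_row <- 100 * 0.5 * 1e-6                  # one pixel-row of slack
  for (r in as.character(c(-5:-1, 1:5)))
    expect_lt(abs(bm$areas_mm2[[r]] - expected), one_row + 1e-12)
})

test_that("band areas account for every pixel (area conservation)", {
  mask <- blob_mask(n = 96, px = 4, seed = 3)
  ifc <- extract_interface(mask)
  bm <- compute_band_map(mask, ifc)
  px2 <- mask$pixel_size_um^2 * 1e-6
  in_iz <- sum(!is.na(bm$rank_raster))
  outside <- sum(is.na(bm$rank_raster))
  expect_identical(in_iz + outside, length(mask$labels))
  expect_equal(sum(bm$areas_mm2), in_iz * px2)
})

test_that("rank sign always matches the tissue compartment", {
  for (seed in 1:4) {
    mask <- blob_mask(n = 80, px = 4, seed = seed)
    bm <- compute_band_map(mask, extract_interface(mask))
    rk <- bm$rank_raster
    expect_true(all(rk[!is.na(rk)] != 0L))
    expect_true(all(sign(rk[!is.na(rk)]) == bm$compartment[!is.na(rk)]))
    # positive ranks only on epithelium, negative only on stroma
    expect_true(all(bm$compartment[which(rk > 0)] == 1L))
    expect_true(all(bm$compartment[which(rk < 0)] == -1L))
  }
})

test_that("widening the interface zone never changes ranks already inside it", {
  mask <- blob_mask(n = 80, px = 4, seed = 9)
  ifc <- extract_interface(mask)
  narrow <- compute_band_map(mask, ifc, 10, 80)
  wide <- compute_band_map(mask, ifc, 10, 150)
  inside <- !is.na(narrow$rank_raster)
  expect_identical(narrow$rank_raster[inside], wide$rank_raster[inside])
})

test_that("band-map parameters are validated", {
  mask <- half_plane_mask(n = 20, px = 1)
  ifc <- extract_interface(mask)
  expect_error(compute_band_map(mask, ifc, 10, 155), "multiple")
  expect_error(compute_band_map(mask, ifc, -10, 150), "positive")
})

test_that("an empty interface set yields an all-sentinel band map", {
  mask <- half_plane_mask(n = 20, px = 1)
  empty <- filter_short_boundaries(extract_interface(mask), 1e9)
  bm <- compute_band_map(mask, empty)
  expect_true(bm$empty)
  expect_true(all(is.na(bm$rank_raster)))
  expect_true(all(bm$areas_mm2 == 0))
})

test_that("band map exports round-trip through TIFF and CSV", {
  mask <- half_plane_mask(n = 40, px = 1)
  bm <- compute_band_map(mask, extract_interface(mask), 10, 20)
  tf <- tempfile(fileext = ".tif"); cf <- tempfile(fileext = ".csv")
  write_band_map(bm, tf, cf)
  enc <- round(tiff::readTIFF(tf) * 255) - 128
  expect_identical(as.integer(enc[20, 19]), bm$rank_raster[20, 19])
  expect_true(all(enc[is.na(bm$rank_raster)] == -128))
  tab <- read.csv(cf)
  expect_equal(tab$area_mm2, as.numeric(bm$areas_mm2))
})
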
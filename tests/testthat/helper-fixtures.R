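# Fixtures are built in code: small label rasters, random blob masks, and a
# brute-force nearest-boundary-distance oracle kept independent of the
# package's distance-transform path.

CODES <- default_label_codes()

# vertical half-plane mask: epithelium in columns 1..split, stroma right
half_plane_mask <- function(n = 200, split = n %/% 2, px = 0.5) {
  m <- matrix(CODES[["stroma"]], n, n)
  m[, seq_len(split)] <- CODES[["epithelium"]]
  tissue_mask(m, px)
}

# epithelium disk of radius r_px pixels centered in stroma
disk_mask <- function(n, r_px, px = 0.5) {
  cc <- (n + 1) / 2
  m <- matrix(CODES[["stroma"]], n, n)
  m[(row(m) - cc)^2 + (col(m) - cc)^2 <= r_px^2] <- CODES[["epithelium"]]
  tissue_mask(m, px)
}

# random smoothed-noise blob mask, optionally with background/artifact areas
blob_mask <- function(n = 96, px = 4, seed = 1, with_other = TRUE) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  k <- 9
  f <- apply(f, 2, function(v) stats::filter(v, rep(1 / k, k), circular = TRUE))
  f <- t(apply(f, 1, function(v) stats::filter(v, rep(1 / k, k), circular = TRUE)))
  labs <- matrix(CODES[["stroma"]], n, n)
  labs[f > 0.05] <- CODES[["epithelium"]]
  if (with_other && runif(1) < 0.5) {
    labs[seq_len(6), seq_len(10)] <- CODES[["background"]]
    labs[n - seq_len(5) + 1, n - seq_len(8) + 1] <- CODES[["artifact"]]
  }
  tissue_mask(labs, px)
}

# Brute-force oracle: minimum Euclidean distance from every pixel center to
# every boundary segment (all segments are axis-aligned), then the same
# ceiling band rule. Independent of the package's upsampled distance
# transform.
oracle_band_ranks <- function(mask, interfaces, band_width_um = 10,
                              max_width_um = 150) {
  px <- mask$pixel_size_um
  labs <- mask$labels
  nr <- nrow(labs); nc <- ncol(labs)
  xc <- as.vector((col(labs) - 0.5) * px)
  yc <- as.vector((row(labs) - 0.5) * px)
  dmin <- rep(Inf, nr * nc)
  for (b in interfaces$boundaries) {
    V <- b$vertices_um
    for (k in seq_len(nrow(V) - 1L)) {
      x0 <- V[k, 1]; y0 <- V[k, 2]; x1 <- V[k + 1, 1]; y1 <- V[k + 1, 2]
      if (x0 == x1) {
        dx <- abs(xc - x0)
        dy <- pmax(0, min(y0, y1) - yc, yc - max(y0, y1))
      } else {
        dy <- abs(yc - y0)
        dx <- pmax(0, min(x0, x1) - xc, xc - max(x0, x1))
      }
      dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    }
  }
  d <- matrix(dmin, nr, nc)
  comp <- matrix(0L, nr, nc)
  comp[labs == mask$label_codes[["epithelium"]]] <- 1L
  comp[labs == mask$label_codes[["stroma"]]] <- -1L
  rk <- matrix(NA_integer_, nr, nc)
  mag <- pmax(1L, ceiling(d / band_width_um - 1e-9))
  inside <- comp != 0L & d <= max_width_um
  rk[inside] <- mag[inside] * comp[inside]
  list(rank = rk, distance_um = d)
}

# compare pipeline vs oracle ranks: exact away from band edges, one rank of
# slack for oracle distances within half a pixel of a band edge
expect_ranks_match_oracle <- function(bm, oracle, px, band_width_um = 10) {
  expect_identical(is.na(bm$rank_raster), is.na(oracle$rank))
  diff <- abs(bm$rank_raster - oracle$rank)
  near_edge <- abs(oracle$distance_um -
                     round(oracle$distance_um / band_width_um) *
                     band_width_um) <= px / 2
  expect_true(all(diff[!is.na(diff) & !near_edge] == 0))
  expect_true(all(diff[!is.na(diff) & near_edge] <= 1))
}

# uniform band profile over ranks -R..R
uniform_profile <- function(R = 15, value = 100, w = 10) {
  d <- rep(value, 2 * R)
  names(d) <- c(seq(-R, -1), seq(1, R))
  profile_from_densities(d, band_width_um = w)
}

# profile from a named density vector (signed-rank names)
named_profile <- function(..., w = 10) {
  v <- c(...)
  profile_from_densities(v, band_width_um = w)
}

# brute-force Harrell's C: explicit double loop over all pairs
oracle_harrell_c <- function(risks, times, events) {
  n <- length(risks)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}
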
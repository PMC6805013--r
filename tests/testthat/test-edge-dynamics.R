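# boundary extraction, index alignment, edge maps, and cross-correlation

test_that("a circle boundary is recovered to sub-pixel accuracy, CCW", {
  mask <- disk_mask(128, 128, 64, 64, 50)
  b <- extract_boundary(mask, P = 1000, pixel_size = 1)
  r <- sqrt((b[, "y"] - 64)^2 + (b[, "x"] - 64)^2)
  expect_true(all(abs(r - 50) < 0.75))
  # even arc-length spacing ~ 2*pi*50/1000
  seg <- sqrt(diff(b[, "x"])^2 + diff(b[, "y"])^2)
  expect_true(all(abs(seg - 2 * pi * 50 / 1000) / (2 * pi * 50 / 1000) < 0.05))
  # CCW orientation contract: positive signed area
  expect_gt(serpentine:::polygon_area(b[, "x"], b[, "y"]), 0)
  # default is 1000 points
  expect_equal(nrow(extract_boundary(mask)), 1000)
})

test_that("masks with holes or multiple components are rejected", {
  holey <- disk_mask(64, 64, 32, 32, 20) & !disk_mask(64, 64, 32, 32, 6)
  expect_error(extract_boundary(holey), "hole")
  two <- disk_mask(64, 64, 16, 16, 8) | disk_mask(64, 64, 48, 48, 8)
  expect_error(extract_boundary(two), "multiple")
})

test_that("index alignment inverts a known rotation and matches the oracle", {
  mask <- disk_mask(96, 96, 48, 48, 30)
  b <- extract_boundary(mask, P = 200, pixel_size = 1)
  rot <- function(bd, k) {
    idx <- ((seq_len(nrow(bd)) - 1 - k) %% nrow(bd)) + 1
    out <- bd[idx, , drop = FALSE]
    attributes(out) <- attributes(bd)
    out
  }
  cur <- rot(b, 17) # cur_{i} = b_{i-17}: aligning needs shift -17... or +17
  aligned <- align_boundary_indices(b, cur)
  expect_equal(unclass(aligned)[, ], unclass(b)[, ], tolerance = 1e-9)
  expect_equal(attr(aligned, "shift"), align_shift_oracle(b, cur))

  # pure translation much smaller than the radius: zero shift, per oracle
  mask2 <- disk_mask(96, 96, 49, 49.5, 30)
  b2 <- extract_boundary(mask2, P = 200, pixel_size = 1)
  al2 <- align_boundary_indices(b, b2)
  expect_equal(attr(al2, "shift"), align_shift_oracle(b, b2))
  # essentially no rotation: at most one index of 200 (raster staircases of
  # the two translated circles differ at the half-pixel level)
  expect_lte(abs(attr(al2, "shift")), 1)
})

test_that("alignment composes to the total rotation on a rotating shape", {
  # an elliptical mask rotated in steps; frame-to-frame shifts accumulate
  H <- 128
  ell <- function(theta) {
    rows <- matrix(seq_len(H), H, H)
    cols <- t(rows)
    xr <- (cols - 64) * cos(theta) + (64 - rows) * sin(theta)
    yr <- -(cols - 64) * sin(theta) + (64 - rows) * cos(theta)
    (xr / 40)^2 + (yr / 24)^2 <= 1
  }
  P <- 360
  steps <- seq(0, 0.5, by = 0.1)
  prev <- extract_boundary(ell(0), P = P, pixel_size = 1)
  total <- 0
  for (th in steps[-1]) {
    cur <- extract_boundary(ell(th), P = P, pixel_size = 1)
    al <- align_boundary_indices(prev, cur)
    total <- total + attr(al, "shift")
    prev <- al
  }
  # 0.5 rad of rotation in index units (full circle = P indices)
  expect_equal(abs(total), 0.5 / (2 * pi) * P, tolerance = 0.15 * P / (2 * pi))
})

test_that("edge velocity is zero for a static mask and signed for growth", {
  static <- stack_from(
    lapply(1:5, function(t) disk_mask(96, 96, 48, 48, 25)),
    pixel_size = 0.2, frame_interval = 1
  )
  v <- edge_velocity_map(static, P = 200)
  expect_true(all(abs(v[, 2:4]) < 1e-6))
  expect_true(all(is.nan(v[, c(1, 5)])))

  # disk growing 1 px/frame: outward front speed = pixel_size/frame_interval
  grow <- stack_from(
    lapply(1:7, function(t) disk_mask(96, 96, 48, 48, 18 + t)),
    pixel_size = 0.2, frame_interval = 1
  )
  vg <- edge_velocity_map(grow, P = 200)
  core <- vg[, 2:6]
  # analytic front speed, up to pixel discretization: the bulk of the map
  # sits within 10% and no point strays beyond 20%
  expect_lt(abs(median(core) - 0.2) / 0.2, 0.03)
  expect_gt(mean(abs(core - 0.2) / 0.2 < 0.1), 0.95)
  expect_true(all(abs(core - 0.2) / 0.2 < 0.2))

  shrink <- stack_from(
    lapply(1:5, function(t) disk_mask(96, 96, 48, 48, 28 - t)),
    pixel_size = 0.2, frame_interval = 1
  )
  vs <- edge_velocity_map(shrink, P = 200)
  expect_true(all(vs[, 2:4] < 0))
})

test_that("velocity integrates to the net normal displacement", {
  radii <- 18 + (1:9)
  st <- stack_from(
    lapply(radii, function(r) disk_mask(96, 96, 48, 48, r)),
    pixel_size = 0.2, frame_interval = 1
  )
  v <- edge_velocity_map(st, P = 100)
  # sum of v dt over interior frames approximates the radius change (px 2..8
  # covers 7 of the 8 one-pixel steps)
  net <- rowSums(v[, 2:8]) * 1
  expect_true(all(abs(net - 7 * 0.2) / (7 * 0.2) < 0.15))
})

test_that("edge fluorescence interpolates images exactly where linear", {
  mask <- disk_mask(64, 64, 32, 32, 20)
  st <- stack_from(list(mask, mask, mask), pixel_size = 1, frame_interval = 1)
  bnd <- align_boundaries(st, P = 80)

  # spatially uniform image
  mv_u <- cell_movie(list(s = array(3.7, c(64, 64, 3))), 1, 1)
  fu <- edge_fluorescence_map(bnd, mv_u, "s")
  expect_true(all(abs(fu - 3.7) < 1e-9))

  # linear ramp: bilinear interpolation is exact
  ramp <- outer(seq_len(64), seq_len(64), function(r, c) 2 * r + 5 * c)
  mv_r <- cell_movie(list(s = array(ramp, c(64, 64, 3))), 1, 1)
  fr <- edge_fluorescence_map(bnd, mv_r, "s")
  b <- bnd[[1]]
  expect_equal(fr[, 2], 2 * b[, "y"] + 5 * b[, "x"], tolerance = 1e-9)
})

test_that("correlating a map with itself peaks exactly at offset zero", {
  k <- generate_kymograph_pair(P = 80, Tn = 90, lag = 0, noise_sd = 0.02, seed = 9)
  xc <- correlate_maps(k$velocity, k$velocity, max_offset = 10)
  expect_equal(xc$offset_frames[which.max(xc$r)], 0)
  expect_equal(max(xc$r), 1, tolerance = 1e-12)
})

test_that("independent noise maps give |r| < 0.03 at all offsets", {
  set.seed(77)
  a <- edge_map(matrix(rnorm(100 * 100), 100), "velocity")
  b <- edge_map(matrix(rnorm(100 * 100), 100), "fluorescence")
  xc <- correlate_maps(a, b, max_offset = 5)
  expect_true(all(abs(xc$r) < 0.03))
})

test_that("pooled correlation averages curves and locates the argmax", {
  mk <- function(peak) {
    structure(
      tibble::tibble(
        offset_frames = -5:5, offset_s = -5:5,
        r = exp(-((-5:5) - peak)^2 / 4), n_pairs = 100L
      ),
      class = c("edge_xcorr", class(tibble::tibble()))
    )
  }
  same <- pool_correlations(list(mk(-2), mk(-2)))
  expect_equal(same$mean_r, mk(-2)$r)
  expect_true(all(same$ci_hi - same$ci_lo < 1e-9))

  two <- pool_correlations(list(mk(-2), mk(-4)))
  expect_equal(attr(two, "peak_offset_s"), -3)

  # a missing offset reduces that offset's n
  c3 <- mk(-2)
  c3$r[1] <- NA
  pooled <- pool_correlations(list(mk(-2), c3))
  expect_equal(pooled$n_cells[1], 1L)
  expect_equal(pooled$n_cells[2], 2L)

  # single curve: CI missing
  one <- pool_correlations(list(mk(0)))
  expect_true(all(is.na(one$ci_lo)))
})
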
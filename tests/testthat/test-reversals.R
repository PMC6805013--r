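# protrusion components, reversal calling, zone edges, and the rotation null

test_that("a single suprathreshold band yields one component", {
  v <- matrix(0, 60, 40)
  v[20:30, ] <- 0.3
  comps <- detect_protrusion_components(edge_map(v, "velocity"),
    smooth_sigma = c(1, 1), v_thresh = 0.15
  )
  expect_equal(length(unique(comps$component)), 1)
  # all-subthreshold map gives an empty table
  empty <- detect_protrusion_components(edge_map(v * 0.1, "velocity"),
    smooth_sigma = c(1, 1), v_thresh = 0.15
  )
  expect_equal(nrow(empty), 0)
})

test_that("component labelling is invariant to circular rotation", {
  k <- generate_kymograph_pair(
    P = 80, Tn = 70, lag = 0, noise_sd = 0,
    reversal_plan = c(30), seed = 4
  )
  c1 <- detect_protrusion_components(k$velocity, smooth_sigma = c(2, 1))
  vrot <- unclass(k$velocity)[c(21:80, 1:20), ]
  c2 <- detect_protrusion_components(edge_map(vrot, "velocity"),
    smooth_sigma = c(2, 1)
  )
  expect_equal(length(unique(c1$component)), length(unique(c2$component)))
  expect_equal(nrow(c1), nrow(c2))
  expect_setequal(
    paste(((c1$position - 1 - 20) %% 80) + 1, c1$frame),
    paste(c2$position, c2$frame)
  )
})

test_that("centre-of-mass tracking unwraps motion across the wrap", {
  # band advancing 2 indices/frame, crossing position 0
  P <- 60
  Tn <- 25
  v <- matrix(0, P, Tn)
  for (t in seq_len(Tn)) {
    ctr <- ((50 + 2 * (t - 1)) %% P)
    for (d in -4:4) v[(ctr + d) %% P + 1, t] <- 0.3
  }
  comps <- detect_protrusion_components(edge_map(v, "velocity"),
    smooth_sigma = c(0, 0), v_thresh = 0.15
  )
  traj <- track_component_com(comps, comps$component[1])
  # unwrapped trajectory is linear with slope 2/P per frame
  slopes <- diff(traj$unwrapped)
  expect_true(all(abs(slopes - 2 / P) < 1e-9))
  # symmetric band: COM at the band midpoint
  expect_equal(traj$frac[1], 50 / P, tolerance = 1e-9)
})

test_that("a triangle-wave trajectory yields reversals at its extremes", {
  frames <- 1:61
  pos <- 0.5 + 0.2 * (2 / pi) * asin(sin(2 * pi * frames / 20)) # triangle wave
  traj <- structure(
    tibble::tibble(frame = frames, frac = pos %% 1, unwrapped = pos),
    class = c("com_trajectory", class(tibble::tibble())),
    component = 1L, P = 100
  )
  ev <- call_reversals(traj, min_reversals = 3)
  # brute-force extremum oracle
  oracle <- which(diff(sign(diff(pos))) != 0) + 1
  expect_equal(nrow(ev), length(oracle))
  expect_true(all(abs(ev$frame - frames[oracle]) <= 1))

  # a monotone trajectory yields no events
  mono <- structure(
    tibble::tibble(
      frame = 1:30, frac = (1:30) / 100,
      unwrapped = (1:30) / 100
    ),
    class = c("com_trajectory", class(tibble::tibble())),
    component = 1L, P = 100
  )
  expect_equal(nrow(call_reversals(mono, min_reversals = 1)), 0)
})

test_that("reversal count is invariant under time reversal", {
  set.seed(5)
  walk <- cumsum(rnorm(50, sd = 0.02))
  mk <- function(x) {
    structure(
      tibble::tibble(frame = seq_along(x), frac = x %% 1, unwrapped = x),
      class = c("com_trajectory", class(tibble::tibble())),
      component = 1L, P = 100
    )
  }
  n_fwd <- nrow(call_reversals(mk(walk), min_reversals = 0))
  n_rev <- nrow(call_reversals(mk(rev(walk)), min_reversals = 0))
  expect_equal(n_fwd, n_rev)
})

test_that("zone edges localize a planted step zone exactly", {
  P <- 100
  Tn <- 30
  f <- matrix(10, P, Tn)
  f[21:50, ] <- 200 # zone occupies fractions [0.2, 0.5)
  zones <- rac_zone_edges(edge_map(f, "fluorescence"), smooth_sigma = c(0, 0))
  expect_equal(sort(unique(zones$frac)), c(0.2, 0.5))
  expect_equal(nrow(zones), 2 * Tn)

  # two disjoint zones -> 4 edges per frame
  f2 <- matrix(10, P, Tn)
  f2[11:20, ] <- 200
  f2[61:90, ] <- 200
  z2 <- rac_zone_edges(edge_map(f2, "fluorescence"), smooth_sigma = c(0, 0))
  expect_equal(nrow(z2), 4 * Tn)
})

test_that("reversal-to-edge distances follow circle geometry, max 50%", {
  zones <- structure(
    tibble::tibble(frame = c(1L, 1L), frac = c(0, 0.5)),
    class = c("zone_edge_set", class(tibble::tibble())),
    P = 100, perimeter_um = 60
  )
  ev <- function(frac) {
    structure(
      tibble::tibble(
        component = 1L, frame = 1L, frac = frac,
        dir_prev = -1, dir_new = 1
      ),
      class = c("reversal_events", class(tibble::tibble()))
    )
  }
  expect_equal(reversal_zone_distance(ev(0), zones)$distance_pct, 0)
  # event at 0.25 sits exactly between edges at 0 and 0.5: 25%
  expect_equal(reversal_zone_distance(ev(0.25), zones)$distance_pct, 25)
  # many random events: never above 50%
  set.seed(3)
  d <- vapply(runif(50), function(p) {
    reversal_zone_distance(ev(p), zones)$distance_pct
  }, numeric(1))
  expect_true(all(d <= 50))
})

test_that("rotation null pools n_rotations x n_events distances", {
  set.seed(8)
  zones <- structure(
    tibble::tibble(frame = rep(1:5, each = 2), frac = rep(c(0.1, 0.4), 5)),
    class = c("zone_edge_set", class(tibble::tibble())),
    P = 100, perimeter_um = 60
  )
  events <- structure(
    tibble::tibble(
      component = 1L, frame = rep(1:5, 2), frac = runif(10),
      dir_prev = -1, dir_new = 1
    ),
    class = c("reversal_events", class(tibble::tibble()))
  )
  null <- rotation_null(events, zones, n_rotations = 20, seed = 6)
  expect_equal(nrow(null), 20 * 10)
  # a zero rotation reproduces the observed distances
  obs <- reversal_zone_distance(events, zones)
  rz <- zones
  rz$frac <- (zones$frac + 0) %% 1
  expect_equal(reversal_zone_distance(events, rz)$distance_pct,
    obs$distance_pct)
})

test_that("antipodal-edge zone yields a null uniform on [0, 25%], mean 12.5%", {
  # analytic order statistic: distance to the nearer of two antipodal edges
  # of a uniformly rotated zone is U(0, 25% of perimeter)
  zones <- structure(
    tibble::tibble(frame = 1L, frac = c(0.25, 0.75)),
    class = c("zone_edge_set", class(tibble::tibble())),
    P = 1000, perimeter_um = 60
  )
  events <- structure(
    tibble::tibble(
      component = 1L, frame = 1L, frac = 0.1,
      dir_prev = -1, dir_new = 1
    ),
    class = c("reversal_events", class(tibble::tibble()))
  )
  null <- rotation_null(events, zones, n_rotations = 4000, seed = 2)
  expect_equal(mean(null$distance_pct), 12.5, tolerance = 0.5)
  expect_lt(max(null$distance_pct), 25 + 1e-9)
  q <- unname(stats::quantile(null$distance_pct, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(6.25, 12.5, 18.75), tolerance = 0.1)
})

test_that("planted serpentine kymographs are recovered with high fidelity", {
  k <- generate_kymograph_pair(
    P = 150, Tn = 160, lag = 0, noise_sd = 0.03,
    reversal_plan = c(35, 70, 105, 140), seed = 10,
    band_speed = 0.006
  )
  ev <- find_reversals(k$velocity,
    smooth_sigma = c(3, 2), v_thresh = 0.15,
    min_reversals = 3
  )
  truth <- k$ground_truth$reversals
  # recall: every planted reversal matched by a call within 6 frames and 3%
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(ev$frame - truth$frame[i]) <= 6 &
      serpentine:::circular_dist_frac(ev$frac, truth$frac[i]) <= 0.03)
  }, logical(1))
  expect_gte(mean(matched), 0.9)
  # precision: every call near a planted reversal
  good <- vapply(seq_len(nrow(ev)), function(i) {
    any(abs(truth$frame - ev$frame[i]) <= 6 &
      serpentine:::circular_dist_frac(truth$frac, ev$frac[i]) <= 0.03)
  }, logical(1))
  expect_gte(mean(good), 0.9)
})

test_that("events planted on zone edges beat the rotation null", {
  set.seed(21)
  edges <- c(0.15, 0.55)
  zones <- structure(
    tibble::tibble(frame = rep(1:8, each = 2), frac = rep(edges, 8)),
    class = c("zone_edge_set", class(tibble::tibble())),
    P = 400, perimeter_um = 60
  )
  events <- structure(
    tibble::tibble(
      component = 1L, frame = rep(1:8, 2),
      frac = rep(edges, each = 8) + rnorm(16, sd = 0.002),
      dir_prev = -1, dir_new = 1
    ),
    class = c("reversal_events", class(tibble::tibble()))
  )
  obs <- reversal_zone_distance(events, zones)
  null <- rotation_null(events, zones, n_rotations = 50, seed = 4)
  expect_lt(
    median(obs$distance_pct),
    stats::quantile(null$distance_pct, 0.01)
  )
})
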
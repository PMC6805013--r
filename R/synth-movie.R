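# ground-truthed synthetic two-channel movies
#
# Channel "body" is a filled cell-body marker; channel "sensor" carries a
# cytosolic background plus a boundary-localized intensity focus whose
# angular concentration is calibrated, frame by frame, so that the
# normalized-distance polarity score of the noise-free image equals the
# requested target exactly. The focus is a von-Mises-shaped ring segment:
# one width parameter maps monotonically onto both polarity scores.

#' Specification of a synthetic cell movie
#'
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param pixel_size micrometres per pixel.
#' @param image_shape `c(H, W)` in pixels.
#' @param cell_radius cell radius in micrometres.
#' @param motion_model `"stationary"`, `"straight"` or `"random_walk"`.
#' @param speed straight-line speed in um/s (motion model `"straight"`).
#' @param step_sd per-frame random-walk step s.d. in um (`"random_walk"`).
#' @param direction heading in radians for `"straight"` motion.
#' @param polarity_profile target normalized-distance polarity per frame:
#'   a single number, a vector of length `n_frames`, or a function of the
#'   frame time in seconds returning a value in `[0, 1)`.
#' @param focus_width angular s.d. of the boundary focus, radians.
#' @param focus_angle direction of the focus, radians (for moving cells the
#'   focus tracks the heading by default; this sets the stationary case).
#' @param bleb_track optional data frame with columns `frame` and `angle`
#'   (radians): transient boundary bumps emulating protrusions.
#' @param sensor_noise_sd additive Gaussian noise s.d. (a.u.) on both
#'   channels.
#' @param background_level camera background (a.u.) outside the cell.
#' @param seed integer seed; identical seeds give bit-identical movies.
#' @return an object of class `synthetic_movie_spec`.
#' @export
synthetic_movie_spec <- function(n_frames = 30, frame_interval = 10,
                                 pixel_size = 0.2, image_shape = c(128, 128),
                                 cell_radius = 8, motion_model = "stationary",
                                 speed = 0.1, step_sd = 0.5, direction = 0,
                                 polarity_profile = 0.2, focus_width = 0.35,
                                 focus_angle = 0, bleb_track = NULL,
                                 sensor_noise_sd = 0, background_level = 10,
                                 seed = 1) {
  stopifnot(
    n_frames >= 1, frame_interval > 0, pixel_size > 0,
    length(image_shape) == 2, all(image_shape >= 16), cell_radius > 0,
    motion_model %in% c("stationary", "straight", "random_walk"),
    focus_width > 0, sensor_noise_sd >= 0
  )
  structure(
    list(
      n_frames = as.integer(n_frames), frame_interval = frame_interval,
      pixel_size = pixel_size, image_shape = as.integer(image_shape),
      cell_radius = cell_radius, motion_model = motion_model, speed = speed,
      step_sd = step_sd, direction = direction,
      polarity_profile = polarity_profile, focus_width = focus_width,
      focus_angle = focus_angle, bleb_track = bleb_track,
      sensor_noise_sd = sensor_noise_sd, background_level = background_level,
      seed = as.integer(seed)
    ),
    class = "synthetic_movie_spec"
  )
}

# resolve the polarity profile to one target value per frame
profile_values <- function(spec) {
  p <- spec$polarity_profile
  tt <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  if (is.function(p)) {
    v <- vapply(tt, p, numeric(1))
  } else if (length(p) == 1) {
    v <- rep(p, spec$n_frames)
  } else {
    stopifnot(length(p) == spec$n_frames)
    v <- p
  }
  if (any(v < 0 | v >= 1)) stop("polarity targets must lie in [0, 1)")
  v
}

#' Generate a two-channel synthetic cell movie with ground truth
#'
#' @param spec a [synthetic_movie_spec()].
#' @return a list with elements `movie` (a [cell_movie()]) and
#'   `ground_truth` (a list holding the per-frame centroid in 0-based pixel
#'   coordinates, the per-frame target polarity, and the focus geometry).
#' @export
generate_cell_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  H <- spec$image_shape[1]
  W <- spec$image_shape[2]
  Tn <- spec$n_frames
  rad_px <- spec$cell_radius / spec$pixel_size
  targets <- profile_values(spec)

  local_seed(spec$seed, {
    # centroid path (1-based pixel-centre coordinates)
    path <- matrix(0, Tn, 2) # row, col
    start <- c((H + 1) / 2, (W + 1) / 2)
    step_px <- switch(spec$motion_model,
      stationary = c(0, 0),
      straight = spec$speed * spec$frame_interval / spec$pixel_size *
        c(-sin(spec$direction), cos(spec$direction)),
      random_walk = NULL
    )
    path[1, ] <- start
    for (t in seq_len(Tn)[-1]) {
      if (spec$motion_model == "random_walk") {
        path[t, ] <- path[t - 1, ] +
          rnorm(2, sd = spec$step_sd / spec$pixel_size)
      } else {
        path[t, ] <- path[t - 1, ] + step_px
      }
    }
    margin <- 2 * rad_px
    if (any(path[, 1] < margin | path[, 1] > H + 1 - margin |
      path[, 2] < margin | path[, 2] > W + 1 - margin)) {
      stop("cell would exit the frame; enlarge image_shape or reduce motion")
    }

    # heading per frame (focus direction); angle measured in (x = col,
    # y = -row) convention so that angle 0 points along +column
    heading <- rep(spec$focus_angle, Tn)
    if (spec$motion_model != "stationary") {
      d <- rbind(path[2, ] - path[1, ], diff(path))
      mv <- sqrt(rowSums(d^2)) > 1e-9
      heading[mv] <- atan2(-d[mv, 1], d[mv, 2])
    }

    body <- array(0, c(H, W, Tn))
    sensor <- array(0, c(H, W, Tn))
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    sigma_ring <- 0.5 / spec$pixel_size # ring thickness, px (0.5 um)
    kappa <- 1 / spec$focus_width^2
    realized <- numeric(Tn)

    for (t in seq_len(Tn)) {
      dr <- rows - path[t, 1]
      dc <- cols - path[t, 2]
      r <- sqrt(dr^2 + dc^2)
      rad_t <- matrix(rad_px, H, W)
      if (!is.null(spec$bleb_track)) {
        bt <- spec$bleb_track
        phi <- atan2(-dr, dc)
        for (k in seq_len(nrow(bt))) {
          if (abs(bt$frame[k] - t) <= 2) {
            amp <- (1 / spec$pixel_size) * exp(-(bt$frame[k] - t)^2 / 2)
            rad_t <- rad_t + amp * exp(8 * (cos(phi - bt$angle[k]) - 1))
          }
        }
      }
      inside <- r <= rad_t
      ring <- exp(-(r - rad_t)^2 / (2 * sigma_ring^2)) * inside
      phi <- atan2(-dr, dc)
      focus <- ring * exp(kappa * (cos(phi - heading[t]) - 1))

      # calibrate the focus amplitude so the noise-free distance score hits
      # the target exactly on this frame's footprint
      npx <- sum(inside)
      c_bin <- c(sum(rows[inside]), sum(cols[inside])) / npx
      L <- footprint_major_axis(inside)
      beta <- targets[t] * 0.5 * L
      # unpolarized mass inside the footprint: camera background + cytosol +
      # uniform rim (all centred on the binary centroid by symmetry)
      base <- (spec$background_level + 50) * npx + 30 * sum(ring)
      M_f <- sum(focus)
      m_f <- c(sum(focus * (rows - c_bin[1])), sum(focus * (cols - c_bin[2])))
      d_f <- sqrt(sum(m_f^2)) / M_f
      if (beta >= d_f) {
        stop(sprintf(
          "target polarity %.2f unreachable with focus_width %.2f",
          targets[t], spec$focus_width
        ))
      }
      a <- beta * base / (M_f * (d_f - beta))

      sensor_t <- spec$background_level + inside * 50 + 30 * ring + a * focus
      body_t <- spec$background_level + 100 * inside
      realized[t] <- targets[t]
      body[, , t] <- body_t
      sensor[, , t] <- sensor_t
    }

    if (spec$sensor_noise_sd > 0) {
      body <- pmax(body + rnorm(length(body), sd = spec$sensor_noise_sd), 0)
      sensor <- pmax(sensor + rnorm(length(sensor), sd = spec$sensor_noise_sd), 0)
    }

    movie <- cell_movie(
      channels = list(body = body, sensor = sensor),
      pixel_size = spec$pixel_size, frame_interval = spec$frame_interval
    )
    gt <- list(
      centroid = tibble(
        frame = seq_len(Tn),
        row = path[, 1] - 1, col = path[, 2] - 1 # 0-based
      ),
      polarity = tibble(frame = seq_len(Tn), target = targets),
      heading = heading,
      focus_width = spec$focus_width,
      reversals = spec$bleb_track
    )
    list(movie = movie, ground_truth = gt)
  })
}

# major-axis length (px) of the ellipse with the same normalized second
# central moments as a binary footprint
footprint_major_axis <- function(footprint) {
  idx <- which(footprint, arr.ind = TRUE)
  n <- nrow(idx)
  mu <- colMeans(idx)
  dr <- idx[, 1] - mu[1]
  dc <- idx[, 2] - mu[2]
  # +1/12 per axis: variance of the uniform distribution within a pixel
  cov <- matrix(c(
    mean(dr^2) + 1 / 12, mean(dr * dc),
    mean(dr * dc), mean(dc^2) + 1 / 12
  ), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  4 * sqrt(ev[1])
}
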
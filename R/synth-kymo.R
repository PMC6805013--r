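# ground-truthed synthetic kymograph pairs
#
# A protrusive band translates along the periodic boundary-position axis and
# reverses direction at planned frames; the matching fluorescence map is the
# smoothed velocity band delayed by a known number of frames. Together they
# give the cross-correlation and reversal detectors a test surface with
# exactly known lag, reversal times, and reversal positions.

#' Generate a matched edge-velocity / edge-fluorescence kymograph pair
#'
#' @param P number of boundary positions (periodic axis).
#' @param Tn number of frames.
#' @param lag temporal shift of the fluorescence map relative to the
#'   velocity map, in frames; positive lag delays fluorescence, so the
#'   pooled cross-correlation peaks at `-lag` under the convention that a
#'   negative offset shifts fluorescence back in time. Must satisfy
#'   `|lag| < Tn / 4`.
#' @param reversal_plan integer vector of frames (in `(1, Tn)`) at which the
#'   travelling band reverses direction.
#' @param noise_sd additive Gaussian noise s.d. on the velocity map, in the
#'   same um/s units as the band; fluorescence noise is scaled accordingly.
#' @param seed integer seed.
#' @param band_speed band drift along the boundary, fraction of perimeter
#'   per frame.
#' @param band_width angular width (s.d.) of the band, fraction of perimeter.
#' @param band_amp peak edge velocity of the band, um/s.
#' @param start_frac starting position of the band centre, in `[0, 1)`.
#' @param frame_interval seconds per frame (calibration carried on the maps).
#' @param perimeter_um boundary perimeter in micrometres.
#' @return list with `velocity` and `fluorescence` (both [edge_map()]s) and
#'   `ground_truth` (lag, band-centre trajectory, reversal times/positions,
#'   and the per-frame fluorescence zone interval).
#' @export
generate_kymograph_pair <- function(P = 200, Tn = 120, lag = 0,
                                    reversal_plan = integer(0), noise_sd = 0,
                                    seed = 1, band_speed = 0.01,
                                    band_width = 0.04, band_amp = 0.3,
                                    start_frac = 0.5, frame_interval = 1,
                                    perimeter_um = 60) {
  stopifnot(P >= 4, Tn >= 4, abs(lag) < Tn / 4)
  reversal_plan <- sort(as.integer(reversal_plan))
  if (length(reversal_plan) &&
    (min(reversal_plan) <= 1 || max(reversal_plan) >= Tn)) {
    stop("reversal_plan frames must lie strictly inside (1, Tn)")
  }

  # band-centre trajectory on a padded time axis (needed to shift cleanly)
  pad <- ceiling(Tn / 4) + 2
  tt <- seq(1 - pad, Tn + pad)
  dir_of <- function(t) {
    # direction flips at each planned reversal; +1 before the first
    1 - 2 * (findInterval(t - 1e-9, reversal_plan) %% 2)
  }
  centre <- numeric(length(tt))
  centre[1] <- (start_frac - band_speed * pad * dir_of(tt[1])) %% 1
  for (i in seq_along(tt)[-1]) {
    centre[i] <- (centre[i - 1] + band_speed * dir_of(tt[i])) %% 1
  }

  frac <- (seq_len(P) - 1) / P
  band <- function(i) {
    d <- circular_dist_frac(frac, centre[i])
    band_amp * exp(-d^2 / (2 * band_width^2))
  }
  vel_ext <- vapply(seq_along(tt), band, numeric(P))
  sm_ext <- gauss_smooth_map(vel_ext, sigma_pos = P * band_width / 2,
                             sigma_time = 1)

  idx_now <- pad + seq_len(Tn)
  vel <- vel_ext[, idx_now]
  fluo_scale <- 1000 / band_amp
  fluo <- fluo_scale * sm_ext[, idx_now - lag]

  local_seed(seed, {
    if (noise_sd > 0) {
      vel <- vel + rnorm(length(vel), sd = noise_sd)
      fluo <- fluo + rnorm(length(fluo), sd = noise_sd * fluo_scale)
    }
    NULL
  })

  centre_now <- centre[idx_now]
  gt <- list(
    lag = lag,
    centre = tibble(frame = seq_len(Tn), frac = centre_now),
    reversals = tibble(
      frame = reversal_plan,
      frac = centre_now[reversal_plan]
    ),
    zone = tibble(
      frame = seq_len(Tn),
      lo = (centre_now - 2 * band_width) %% 1,
      hi = (centre_now + 2 * band_width) %% 1
    )
  )
  list(
    velocity = edge_map(vel, "velocity", frame_interval = frame_interval,
                        perimeter_um = perimeter_um),
    fluorescence = edge_map(fluo, "fluorescence",
                            frame_interval = frame_interval,
                            perimeter_um = perimeter_um),
    ground_truth = gt
  )
}
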
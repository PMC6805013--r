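# single-cell polarity scores
#
# Two complementary measures of how asymmetrically a biosensor signal is
# distributed over a cell footprint:
#
# * normalized distance: the offset between the intensity-weighted centroid
#   and the binary-footprint centroid, divided by half the major-axis length
#   of the ellipse with the footprint's normalized second central moments.
#   0 = signal distributed symmetrically; ~1 = all signal at one rim point.
# * angular distribution: the intensity-weighted mean cosine of pixel angles
#   measured against the direction of the intensity centroid. 0 = uniform
#   ring; 1 = all signal on a single ray from the cell centre.

#' Normalized-distance polarity score
#'
#' @param footprint logical/binary matrix marking the cell footprint.
#' @param intensity numeric matrix of the same size, non-negative on the
#'   footprint.
#' @param weighted_L if `TRUE`, the normalizing major axis is computed from
#'   intensity-weighted rather than binary second moments. The binary
#'   footprint is the default so the normalization does not depend on the
#'   signal being scored.
#' @return scalar score (>= 0; ~<= 1 on convex footprints; not clamped).
#' @export
polarity_distance <- function(footprint, intensity, weighted_L = FALSE) {
  idx <- which(footprint > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty footprint")
  w <- intensity[footprint > 0]
  if (any(w < 0)) stop("negative intensity inside footprint")
  tot <- sum(w)
  if (tot <= 0) stop("zero total intensity: weighted centroid undefined")
  c_bin <- colMeans(idx)
  c_w <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / tot
  d <- sqrt(sum((c_w - c_bin)^2))
  L <- if (weighted_L) {
    weighted_major_axis(idx, w)
  } else {
    footprint_major_axis(footprint > 0)
  }
  d / (0.5 * L)
}

weighted_major_axis <- function(idx, w) {
  w <- w / sum(w)
  mu <- c(sum(idx[, 1] * w), sum(idx[, 2] * w))
  dr <- idx[, 1] - mu[1]
  dc <- idx[, 2] - mu[2]
  cov <- matrix(c(
    sum(w * dr^2) + 1 / 12, sum(w * dr * dc),
    sum(w * dr * dc), sum(w * dc^2) + 1 / 12
  ), 2, 2)
  4 * sqrt(eigen(cov, symmetric = TRUE)$values[1])
}

#' Angular-distribution polarity score
#'
#' The reference vector runs from the geometric (unweighted) footprint
#' centre to the intensity-weighted centroid. Each footprint pixel
#' contributes its intensity times the cosine of the angle between its own
#' direction from the centre and the reference vector; the sum is divided
#' by the total intensity. When the weighted centroid coincides with the
#' geometric centre the reference direction is undefined and the score is
#' defined as 0 (an unpolarized cell). Pixels lying exactly at the
#' geometric centre carry no direction and are excluded from both sums.
#'
#' @inheritParams polarity_distance
#' @return scalar score in `[-1, 1]`.
#' @export
polarity_angular <- function(footprint, intensity) {
  idx <- which(footprint > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty footprint")
  w <- intensity[footprint > 0]
  if (any(w < 0)) stop("negative intensity inside footprint")
  tot <- sum(w)
  if (tot <= 0) stop("zero total intensity: weighted centroid undefined")
  c_bin <- colMeans(idx)
  c_w <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / tot
  ref <- c_w - c_bin
  if (sqrt(sum(ref^2)) < 1e-12) {
    return(0)
  }
  ref <- ref / sqrt(sum(ref^2))
  vr <- idx[, 1] - c_bin[1]
  vc <- idx[, 2] - c_bin[2]
  len <- sqrt(vr^2 + vc^2)
  keep <- len > 1e-12
  cosang <- (vr[keep] * ref[1] + vc[keep] * ref[2]) / len[keep]
  sum(w[keep] * cosang) / sum(w[keep])
}

#' Polarity time course over tracked cells
#'
#' Computes both polarity scores for every tracked cell at every frame,
#' using the propagated biosensor region as footprint and the
#' dark-subtracted biosensor channel as intensity. Frames listed in
#' `omit_frames` (e.g. frames swamped by the uncaging UV flash) are flagged
#' and excluded from the population summary. The time axis is re-zeroed at
#' the stimulus frame.
#'
#' @param tracks a `cell_tracks` tibble whose labels refer to `masks`.
#' @param masks the propagated biosensor [mask_stack()].
#' @param movie the [cell_movie()].
#' @param channel biosensor channel name.
#' @param stim_frame frame at which the stimulus is applied (time 0).
#' @param omit_frames integer frames to flag as omitted.
#' @return object of class `polarity_trace`: list with tibbles `cells`
#'   (per cell x frame scores) and `summary` (population mean and 95% CI
#'   per timepoint, omitted frames absent).
#' @export
polarity_timecourse <- function(tracks, masks, movie, channel = "sensor",
                                stim_frame = 1, omit_frames = integer(0)) {
  stopifnot(inherits(masks, "mask_stack"), inherits(movie, "cell_movie"))
  dt <- movie$frame_interval
  rows <- lapply(seq_len(nrow(tracks)), function(i) {
    fr <- tracks$frame[i]
    lab <- tracks$label[i]
    fp <- masks$labels[, , fr] == lab
    if (!any(fp)) {
      return(NULL)
    }
    img <- dark_subtracted(movie, channel, fr)
    tibble(
      track_id = tracks$track_id[i], frame = fr,
      t_s = (fr - stim_frame) * dt,
      score_distance = polarity_distance(fp, img),
      score_angular = polarity_angular(fp, img),
      omitted = fr %in% omit_frames
    )
  })
  cells <- dplyr::bind_rows(rows)
  summary <- cells |>
    dplyr::filter(!.data$omitted) |>
    dplyr::group_by(.data$frame, .data$t_s) |>
    dplyr::summarise(
      mean_distance = t_ci(.data$score_distance)[["mean"]],
      ci_lo_distance = t_ci(.data$score_distance)[["lo"]],
      ci_hi_distance = t_ci(.data$score_distance)[["hi"]],
      mean_angular = t_ci(.data$score_angular)[["mean"]],
      ci_lo_angular = t_ci(.data$score_angular)[["lo"]],
      ci_hi_angular = t_ci(.data$score_angular)[["hi"]],
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  structure(list(cells = cells, summary = summary), class = "polarity_trace")
}

#' @export
print.polarity_trace <- function(x, ...) {
  cat(sprintf(
    "<polarity_trace> %d cells, %d timepoints (%d omitted rows)\n",
    length(unique(x$cells$track_id)), length(unique(x$cells$frame)),
    sum(x$cells$omitted)
  ))
  invisible(x)
}

#' @method tidy polarity_trace
#' @export
tidy.polarity_trace <- function(x, ...) x$cells

#' @method glance polarity_trace
#' @export
glance.polarity_trace <- function(x, ...) {
  ok <- !x$cells$omitted
  tibble(
    n_cells = length(unique(x$cells$track_id)),
    n_timepoints = length(unique(x$cells$frame)),
    mean_distance = mean(x$cells$score_distance[ok]),
    mean_angular = mean(x$cells$score_angular[ok])
  )
}
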
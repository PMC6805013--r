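# boundary kymographs: P x T maps of edge velocity or edge fluorescence

#' Boundary kymograph (edge map)
#'
#' A `P x T` matrix of a boundary-attached quantity: rows index `P` evenly
#' spaced positions along the closed cell outline (periodic axis), columns
#' index frames. Velocity maps are in um/s with `NaN` in the first and last
#' columns (centred differences need both neighbours); fluorescence maps are
#' in arbitrary units.
#'
#' @param mat numeric `P x T` matrix.
#' @param kind `"velocity"` or `"fluorescence"`.
#' @param frame_interval seconds per frame.
#' @param perimeter_um boundary perimeter in micrometres (scalar or per
#'   frame), used to convert circular fractions to physical distance.
#' @return an object of class `edge_map` (a matrix with attributes).
#' @export
edge_map <- function(mat, kind = c("velocity", "fluorescence"),
                     frame_interval = 1, perimeter_um = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(mat))
  structure(mat,
    kind = kind, frame_interval = frame_interval,
    perimeter_um = perimeter_um, class = c("edge_map", "matrix", "array")
  )
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf(
    "<edge_map:%s> %d positions x %d frames, %.3g s/frame\n",
    attr(x, "kind"), nrow(x), ncol(x), attr(x, "frame_interval")
  ))
  invisible(x)
}

#' Turn an edge map into a long tibble
#'
#' @param x an [edge_map()].
#' @param ... unused.
#' @return tibble with columns `position`, `frac`, `frame`, `t_s`, `value`.
#' @method tidy edge_map
#' @export
tidy.edge_map <- function(x, ...) {
  P <- nrow(x)
  Tn <- ncol(x)
  tibble(
    position = rep(seq_len(P), Tn),
    frac = rep((seq_len(P) - 1) / P, Tn),
    frame = rep(seq_len(Tn), each = P),
    t_s = rep((seq_len(Tn) - 1) * attr(x, "frame_interval"), each = P),
    value = as.vector(unclass(x))
  )
}

#' Extract a sub-pixel cell boundary as an arc-length parameterized curve
#'
#' The half-level contour of the binary mask is fit with periodic cubic
#' splines and resampled to `P` points evenly spaced in arc length, oriented
#' counter-clockwise (positive signed area in (x, y) = (col, row) * pixel
#' coordinates).
#'
#' @param mask_frame binary matrix containing a single simply connected
#'   region.
#' @param P number of boundary points.
#' @param pixel_size micrometres per pixel.
#' @return a `P x 2` matrix (columns `x`, `y`, micrometres) of class
#'   `cell_boundary`, with the perimeter (um) as attribute `perimeter_um`.
#' @export
extract_boundary <- function(mask_frame, P = 1000, pixel_size = 1) {
  m <- (mask_frame > 0) * 1L
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp == 0) stop("empty mask")
  if (ncomp > 1) stop("mask has multiple connected components")
  filled <- EBImage::fillHull(EBImage::Image(m))
  if (any(filled != m)) stop("mask region has holes")

  ct <- grDevices::contourLines(
    x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m, levels = 0.5
  )
  if (length(ct) != 1) stop("expected a single closed contour")
  # contourLines: x follows the first matrix index (rows)
  ry <- ct[[1]]$x
  cx <- ct[[1]]$y
  if (ry[1] == ry[length(ry)] && cx[1] == cx[length(cx)]) {
    ry <- ry[-length(ry)]
    cx <- cx[-length(cx)]
  }
  # CCW in (x = col, y = row) coordinates
  if (polygon_area(cx, ry) < 0) {
    ry <- rev(ry)
    cx <- rev(cx)
  }
  # light circular smoothing of the marching-squares staircase so the
  # periodic spline does not ripple at pixel period
  n0 <- length(ry)
  if (n0 >= 13) {
    hw <- 4L
    sm <- function(v) {
      out <- v
      for (d in setdiff(seq(-hw, hw), 0)) {
        out <- out + v[((seq_len(n0) - 1 + d) %% n0) + 1]
      }
      out / (2 * hw + 1)
    }
    ry <- sm(ry)
    cx <- sm(cx)
  }

  # periodic spline through the contour, chord-length parameterized
  n <- length(ry)
  s <- c(0, cumsum(sqrt(diff(c(cx, cx[1]))^2 + diff(c(ry, ry[1]))^2)))
  per <- s[n + 1]
  sx <- stats::splinefun(s, c(cx, cx[1]), method = "periodic")
  sy <- stats::splinefun(s, c(ry, ry[1]), method = "periodic")
  # dense resample, then invert arc length for even spacing
  sd_ <- seq(0, per, length.out = 20 * P + 1)
  xd <- sx(sd_)
  yd <- sy(sd_)
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  target <- seq(0, arc[length(arc)], length.out = P + 1)[-(P + 1)]
  xi <- stats::approx(arc, xd, xout = target)$y
  yi <- stats::approx(arc, yd, xout = target)$y

  # canonical index origin: point 1 sits at polar angle zero about the
  # centroid, so the parameterization does not depend on where the contour
  # tracer happened to start
  ang <- atan2(yi - mean(yi), xi - mean(xi))
  first <- which.min(abs(ang))
  roll <- c(seq(first, P), seq_len(first - 1))
  xi <- xi[roll]
  yi <- yi[roll]

  out <- cbind(x = xi * pixel_size, y = yi * pixel_size)
  structure(out,
    class = c("cell_boundary", "matrix", "array"),
    perimeter_um = arc[length(arc)] * pixel_size,
    pixel_size = pixel_size, P = P
  )
}

#' Align the point indices of consecutive boundaries
#'
#' Re-indexes `cur` by the circular shift minimizing the summed squared
#' distance to `prev`, computed over all `P` shifts via FFT
#' cross-correlation. Orientation is preserved; ties are broken toward the
#' smaller absolute shift, then toward the negative shift.
#'
#' @param prev,cur `cell_boundary` objects with the same `P`.
#' @return `cur` circularly re-indexed; the applied shift is attached as
#'   attribute `shift`.
#' @export
align_boundary_indices <- function(prev, cur) {
  P <- nrow(prev)
  stopifnot(nrow(cur) == P)
  # sum_i |prev_i - cur_{i+k}|^2 = const - 2 * sum_i prev_i . cur_{i+k}
  cc <- function(a, b) Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / P
  score <- cc(prev[, 1], cur[, 1]) + cc(prev[, 2], cur[, 2])
  k_all <- seq(0, P - 1)
  k_signed <- ifelse(k_all > P / 2, k_all - P, k_all)
  best <- max(score)
  cand <- which(score >= best - 1e-9 * max(abs(score), 1))
  ord <- cand[order(abs(k_signed[cand]), k_signed[cand])]
  k <- k_all[ord[1]]
  idx <- ((seq_len(P) - 1 + k) %% P) + 1
  out <- cur[idx, , drop = FALSE]
  attributes(out) <- attributes(cur)
  attr(out, "shift") <- k_signed[ord[1]]
  out
}

#' Extract and index-align boundaries for every frame of a mask stack
#'
#' @param masks binary `H x W x T` array (one cell) or a [mask_stack()]
#'   whose positive labels are treated as one region per frame.
#' @param P boundary points per frame.
#' @param pixel_size micrometres per pixel (taken from the mask stack when
#'   one is given).
#' @return list of `cell_boundary` objects (NULL for frames with no region),
#'   class `boundary_stack`.
#' @export
align_boundaries <- function(masks, P = 1000, pixel_size = NULL) {
  if (inherits(masks, "mask_stack")) {
    pixel_size <- pixel_size %||% masks$pixel_size
    arr <- masks$labels > 0
  } else {
    pixel_size <- pixel_size %||% 1
    arr <- masks > 0
  }
  Tn <- dim(arr)[3]
  out <- vector("list", Tn)
  prev <- NULL
  for (t in seq_len(Tn)) {
    if (!any(arr[, , t])) next
    b <- extract_boundary(arr[, , t], P = P, pixel_size = pixel_size)
    if (!is.null(prev)) b <- align_boundary_indices(prev, b)
    out[[t]] <- b
    prev <- b
  }
  structure(out, class = "boundary_stack", pixel_size = pixel_size, P = P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed distance transform in pixels, positive inside the mask; the
# half-pixel shift puts the zero level on the mask boundary so the field has
# unit slope across it (distmap alone jumps from +1 to -1 between pixels)
signed_distance <- function(mask) {
  m <- (mask > 0) * 1L
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1L - m))
  ifelse(m > 0, din - 0.5, 0.5 - dout)
}

#' Edge-velocity kymograph from a mask sequence
#'
#' For each aligned boundary point at frame `t`, the normal edge velocity is
#' the centred difference of the signed distance transforms of the masks at
#' `t - 1` and `t + 1`, interpolated bilinearly at the point and divided by
#' `2 * frame_interval`. The distance transform is signed positive inside
#' the mask, so outward extension gives positive velocity.
#'
#' @inheritParams align_boundaries
#' @param frame_interval seconds per frame (from the mask stack when given).
#' @param boundaries optionally, a precomputed [align_boundaries()] result.
#' @return an [edge_map()] of kind `"velocity"` (um/s); columns 1 and T are
#'   `NaN`. The boundaries used are attached as attribute `boundaries`.
#' @export
edge_velocity_map <- function(masks, P = 1000, pixel_size = NULL,
                              frame_interval = NULL, boundaries = NULL) {
  if (inherits(masks, "mask_stack")) {
    pixel_size <- pixel_size %||% masks$pixel_size
    frame_interval <- frame_interval %||% masks$frame_interval
    arr <- masks$labels > 0
  } else {
    pixel_size <- pixel_size %||% 1
    frame_interval <- frame_interval %||% 1
    arr <- masks > 0
  }
  Tn <- dim(arr)[3]
  if (Tn < 3) stop("need at least 3 frames for centred differences")
  if (is.null(boundaries)) {
    boundaries <- align_boundaries(arr, P = P, pixel_size = pixel_size)
  }
  P <- attr(boundaries, "P")
  sdt <- lapply(seq_len(Tn), function(t) {
    if (any(arr[, , t])) signed_distance(arr[, , t]) else NULL
  })
  # signed distance (um) from the frame-t boundary points to the sub-pixel
  # contour of frame s: magnitude from the nearest polygon point, sign from
  # the pixel-level signed field (the pixel field alone carries up to half a
  # pixel of metric anisotropy, too coarse for centred differences)
  sd_to <- function(b, s) {
    bs <- boundaries[[s]]
    d2 <- outer(b[, "x"], bs[, "x"], "-")^2 + outer(b[, "y"], bs[, "y"], "-")^2
    mag <- sqrt(apply(d2, 1, min))
    sgn <- sign(bilinear(sdt[[s]], b[, "y"] / pixel_size,
                         b[, "x"] / pixel_size))
    sgn[sgn == 0] <- 1
    mag * sgn
  }
  v <- matrix(NaN, P, Tn)
  for (t in seq(2, Tn - 1)) {
    b <- boundaries[[t]]
    if (is.null(b) || is.null(boundaries[[t - 1]]) ||
      is.null(boundaries[[t + 1]]) ||
      is.null(sdt[[t - 1]]) || is.null(sdt[[t + 1]])) {
      next
    }
    v[, t] <- (sd_to(b, t + 1) - sd_to(b, t - 1)) / (2 * frame_interval)
  }
  per <- vapply(boundaries, function(b) {
    if (is.null(b)) NA_real_ else attr(b, "perimeter_um")
  }, numeric(1))
  out <- edge_map(v, "velocity", frame_interval = frame_interval,
                  perimeter_um = mean(per, na.rm = TRUE))
  attr(out, "boundaries") <- boundaries
  out
}

#' Edge-fluorescence kymograph
#'
#' Bilinear interpolation of the dark-subtracted channel at each aligned
#' boundary point, each frame.
#'
#' @param boundaries a [align_boundaries()] result (or the attribute
#'   attached to an [edge_velocity_map()]).
#' @param movie a [cell_movie()].
#' @param channel channel name.
#' @return an [edge_map()] of kind `"fluorescence"`.
#' @export
edge_fluorescence_map <- function(boundaries, movie, channel) {
  if (inherits(boundaries, "edge_map")) {
    boundaries <- attr(boundaries, "boundaries")
  }
  stopifnot(inherits(boundaries, "boundary_stack"))
  P <- attr(boundaries, "P")
  px <- attr(boundaries, "pixel_size")
  Tn <- n_frames(movie)
  f <- matrix(NaN, P, Tn)
  for (t in seq_len(Tn)) {
    b <- boundaries[[t]]
    if (is.null(b)) next
    img <- dark_subtracted(movie, channel, t)
    f[, t] <- bilinear(img, b[, "y"] / px, b[, "x"] / px)
  }
  per <- vapply(boundaries, function(b) {
    if (is.null(b)) NA_real_ else attr(b, "perimeter_um")
  }, numeric(1))
  edge_map(f, "fluorescence", frame_interval = movie$frame_interval,
           perimeter_um = mean(per, na.rm = TRUE))
}
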
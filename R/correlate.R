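# lagged Pearson cross-correlation between edge velocity and edge
# fluorescence

#' Lagged cross-correlation between a velocity and a fluorescence map
#'
#' For each integer offset `k` in `[-max_offset, max_offset]` the Pearson
#' correlation is computed over all valid (position, time) pairs between
#' `vel[, t + k]` and `fluo[, t]`. A negative offset therefore means the
#' fluorescence signal is shifted back in time relative to velocity: a peak
#' at a negative offset says fluorescence lags velocity by that long.
#'
#' @param vel,fluo [edge_map()]s with identical dimensions.
#' @param max_offset largest |offset| in frames.
#' @return tibble of class `edge_xcorr` with columns `offset_frames`,
#'   `offset_s`, `r`, `n_pairs`; `r` is `NA` where fewer than 2 valid pairs
#'   exist.
#' @export
correlate_maps <- function(vel, fluo, max_offset = 10) {
  stopifnot(all(dim(vel) == dim(fluo)))
  Tn <- ncol(vel)
  dt <- attr(vel, "frame_interval") %||% 1
  offs <- seq(-max_offset, max_offset)
  r <- rep(NA_real_, length(offs))
  n <- integer(length(offs))
  vm <- unclass(vel)
  fm <- unclass(fluo)
  for (i in seq_along(offs)) {
    k <- offs[i]
    tv <- seq_len(Tn)
    ok <- tv + k >= 1 & tv + k <= Tn
    a <- as.vector(vm[, tv[ok] + k])
    b <- as.vector(fm[, tv[ok]])
    keep <- is.finite(a) & is.finite(b)
    n[i] <- sum(keep)
    if (n[i] >= 2 && sd(a[keep]) > 0 && sd(b[keep]) > 0) {
      r[i] <- stats::cor(a[keep], b[keep])
    }
  }
  structure(
    tibble(
      offset_frames = offs, offset_s = offs * dt,
      r = r, n_pairs = n
    ),
    class = c("edge_xcorr", "tbl_df", "tbl", "data.frame")
  )
}

#' Pool per-cell correlation curves
#'
#' Unweighted mean correlation per offset across cells with a 95% t-interval;
#' the pooled argmax offset is reported in seconds.
#'
#' @param curves list of [correlate_maps()] results on a common offset grid.
#' @return tibble of class `edge_xcorr_pooled` with columns `offset_s`,
#'   `mean_r`, `ci_lo`, `ci_hi`, `n_cells`, and the peak offset (s) as
#'   attribute `peak_offset_s`.
#' @export
pool_correlations <- function(curves) {
  stopifnot(length(curves) >= 1)
  offs <- curves[[1]]$offset_s
  for (cu in curves) {
    if (!isTRUE(all.equal(cu$offset_s, offs))) {
      stop("correlation curves must share one offset grid")
    }
  }
  rmat <- vapply(curves, function(cu) cu$r, numeric(length(offs)))
  rmat <- matrix(rmat, nrow = length(offs))
  stats_ <- t(apply(rmat, 1, t_ci))
  out <- tibble(
    offset_s = offs,
    mean_r = stats_[, "mean"],
    ci_lo = stats_[, "lo"],
    ci_hi = stats_[, "hi"],
    n_cells = as.integer(stats_[, "n"])
  )
  peak <- out$offset_s[which.max(out$mean_r)]
  structure(out,
    class = c("edge_xcorr_pooled", "tbl_df", "tbl", "data.frame"),
    peak_offset_s = if (length(peak)) peak else NA_real_
  )
}

#' @method glance edge_xcorr_pooled
#' @export
glance.edge_xcorr_pooled <- function(x, ...) {
  tibble(
    peak_offset_s = attr(x, "peak_offset_s"),
    peak_r = max(x$mean_r, na.rm = TRUE),
    n_cells = max(x$n_cells)
  )
}
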
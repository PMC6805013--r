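# centroid tracking, QC filters, and motility statistics

#' Link labelled masks into cell tracks
#'
#' Greedy nearest-centroid bipartite linking between consecutive frames,
#' gated at `max_step` micrometres: the closest remaining (previous,
#' current) pair is linked first, and labels left unlinked start new
#' tracks. Labelled regions that touch (8-adjacency) within a frame mark a
#' collision on every involved track at that frame.
#'
#' @param masks a [mask_stack()].
#' @param max_step linking gate in micrometres per frame.
#' @return tibble of class `cell_tracks`: one row per (track, frame) with
#'   0-based centroid pixel coordinates (`row`, `col`), physical coordinates
#'   (`x_um`, `y_um`), the frame's region bounding box, and a `collision`
#'   flag. Calibration is carried in attributes `pixel_size` and
#'   `frame_interval`.
#' @export
link_tracks <- function(masks, max_step = 10) {
  stopifnot(inherits(masks, "mask_stack"), max_step > 0)
  px <- masks$pixel_size
  d <- dim(masks$labels)
  Tn <- d[3]
  gate_px <- max_step / px

  frame_props <- function(t) {
    lab <- masks$labels[, , t]
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    if (!length(ids)) {
      return(NULL)
    }
    idx <- which(lab > 0, arr.ind = TRUE)
    labv <- lab[lab > 0]
    props <- lapply(ids, function(id) {
      p <- idx[labv == id, , drop = FALSE]
      c(
        row = mean(p[, 1]), col = mean(p[, 2]),
        rmin = min(p[, 1]), rmax = max(p[, 1]),
        cmin = min(p[, 2]), cmax = max(p[, 2])
      )
    })
    list(ids = ids, props = do.call(rbind, props), lab = lab)
  }

  collisions_in <- function(lab) {
    # label pairs that touch under 8-adjacency
    pairs <- list()
    H <- nrow(lab)
    W <- ncol(lab)
    shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (s in shifts) {
      r1 <- seq_len(H - abs(s[1]))
      c1 <- seq_len(W - abs(s[2]))
      a <- lab[r1 + max(s[1], 0), c1 + max(s[2], 0)]
      b <- lab[r1 + max(-s[1], 0), c1 + max(-s[2], 0)]
      hit <- a > 0 & b > 0 & a != b
      if (any(hit)) pairs[[length(pairs) + 1]] <- unique(cbind(a[hit], b[hit]))
    }
    if (!length(pairs)) {
      return(integer(0))
    }
    unique(as.vector(do.call(rbind, pairs)))
  }

  rows <- list()
  next_track <- 1L
  active <- NULL # tibble: track_id, row, col (previous frame)
  for (t in seq_len(Tn)) {
    fp <- frame_props(t)
    if (is.null(fp)) {
      active <- NULL
      next
    }
    k <- length(fp$ids)
    assigned <- rep(NA_integer_, k)
    if (!is.null(active) && nrow(active) > 0) {
      dmat <- outer(active$row, fp$props[, "row"], "-")^2 +
        outer(active$col, fp$props[, "col"], "-")^2
      dmat <- sqrt(dmat)
      dmat[dmat > gate_px] <- NA
      while (any(is.finite(dmat))) {
        ij <- arrayInd(which.min(dmat), dim(dmat))
        assigned[ij[2]] <- active$track_id[ij[1]]
        dmat[ij[1], ] <- NA
        dmat[, ij[2]] <- NA
      }
    }
    new_mask <- is.na(assigned)
    if (any(new_mask)) {
      assigned[new_mask] <- seq.int(next_track, next_track + sum(new_mask) - 1L)
      next_track <- next_track + sum(new_mask)
    }
    collided <- collisions_in(fp$lab)
    rows[[t]] <- tibble(
      track_id = assigned, frame = t, label = fp$ids,
      row = as.numeric(fp$props[, "row"]) - 1,
      col = as.numeric(fp$props[, "col"]) - 1,
      rmin = as.numeric(fp$props[, "rmin"]) - 1,
      rmax = as.numeric(fp$props[, "rmax"]) - 1,
      cmin = as.numeric(fp$props[, "cmin"]) - 1,
      cmax = as.numeric(fp$props[, "cmax"]) - 1,
      collision = fp$ids %in% collided
    )
    active <- tibble(
      track_id = assigned,
      row = fp$props[, "row"], col = fp$props[, "col"]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$x_um <- out$col * px
    out$y_um <- out$row * px
    out$t_s <- (out$frame - 1) * masks$frame_interval
  }
  structure(out,
    class = c("cell_tracks", class(tibble())),
    pixel_size = px, frame_interval = masks$frame_interval,
    fov_shape = d[1:2]
  )
}

#' Quality-control filter for cell tracks
#'
#' Removes tracks that (i) touch the edge of the field of view in any
#' frame, (ii) never achieve a maximum displacement of at least
#' `min_max_displacement` micrometres from their starting point within the
#' observation window (dead cells and debris), or (iii) carry a collision
#' flag in any frame.
#'
#' @param tracks a [link_tracks()] result.
#' @param fov_shape `c(H, W)` in pixels (taken from the tracks attribute
#'   when omitted).
#' @param window observation window in seconds, measured from each track's
#'   first frame.
#' @param min_max_displacement displacement threshold in micrometres
#'   (default 5).
#' @return the surviving tracks; per-rule removal counts are attached as
#'   attribute `removal_counts` and the removed track ids with their rule as
#'   attribute `removed`.
#' @export
qc_filter <- function(tracks, fov_shape = NULL, window = 600,
                      min_max_displacement = 5) {
  fov_shape <- fov_shape %||% attr(tracks, "fov_shape")
  dt <- attr(tracks, "frame_interval")
  removed <- list()
  by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  keep_ids <- character(0)
  for (id in names(by_track)) {
    tr <- tracks[by_track[[id]], ]
    rule <- NA_character_
    touches_edge <- any(
      tr$rmin <= 0 | tr$cmin <= 0 |
        tr$rmax >= fov_shape[1] - 1 | tr$cmax >= fov_shape[2] - 1
    )
    if (touches_edge) {
      rule <- "edge_of_fov"
    } else if (any(tr$collision)) {
      rule <- "collision"
    } else {
      in_win <- tr$t_s - tr$t_s[1] <= window
      disp <- sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2)
      if (max(disp[in_win]) < min_max_displacement) rule <- "low_displacement"
    }
    if (is.na(rule)) {
      keep_ids <- c(keep_ids, id)
    } else {
      removed[[id]] <- rule
    }
  }
  out <- tracks[tracks$track_id %in% as.integer(keep_ids), ]
  rules <- unlist(removed, use.names = FALSE)
  counts <- c(
    edge_of_fov = sum(rules == "edge_of_fov"),
    low_displacement = sum(rules == "low_displacement"),
    collision = sum(rules == "collision")
  )
  attrs <- attributes(tracks)
  for (a in c("pixel_size", "frame_interval", "fov_shape")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(tracks)
  attr(out, "removal_counts") <- counts
  attr(out, "removed") <- tibble(
    track_id = as.integer(names(removed)),
    rule = rules %||% character(0)
  )
  out
}

#' Mean squared displacement, instantaneous velocity, and persistence
#'
#' MSD is averaged over all start times within each track and then across
#' tracks (with a 95% t-interval across tracks). Instantaneous velocity is
#' the per-step path length divided by the frame interval, averaged per
#' track and reported in um/min. Persistence is the net displacement
#' divided by the total path length (dimensionless, in `[0, 1]`); it is
#' undefined (NA) for tracks with zero path length.
#'
#' @param tracks a `cell_tracks` tibble.
#' @param frame_interval seconds per frame (from the tracks attribute when
#'   omitted).
#' @return object of class `motility_summary`: list with tibbles `msd`
#'   (`lag_s`, `msd`, `ci_lo`, `ci_hi`, `n_cells`) and `cells` (`track_id`,
#'   `velocity_um_min`, `persistence`, `net_um`, `path_um`).
#' @export
compute_motility <- function(tracks, frame_interval = NULL) {
  dt <- frame_interval %||% attr(tracks, "frame_interval")
  by_track <- split(tracks, tracks$track_id)
  by_track <- Filter(function(tr) nrow(tr) >= 2, by_track)
  if (!length(by_track)) stop("need at least one track with two frames")

  per_cell_msd <- lapply(by_track, function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    vapply(seq_len(n - 1), function(lag) {
      dx <- tr$x_um[(1 + lag):n] - tr$x_um[1:(n - lag)]
      dy <- tr$y_um[(1 + lag):n] - tr$y_um[1:(n - lag)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  })
  max_lag <- max(lengths(per_cell_msd))
  msd <- lapply(seq_len(max_lag), function(lag) {
    vals <- vapply(per_cell_msd, function(v) {
      if (length(v) >= lag) v[lag] else NA_real_
    }, numeric(1))
    s <- t_ci(vals)
    tibble(
      lag_s = lag * dt, msd = s[["mean"]], ci_lo = s[["lo"]],
      ci_hi = s[["hi"]], n_cells = as.integer(s[["n"]])
    )
  })
  msd <- dplyr::bind_rows(
    tibble(lag_s = 0, msd = 0, ci_lo = 0, ci_hi = 0,
           n_cells = length(per_cell_msd)),
    dplyr::bind_rows(msd)
  )

  cells <- dplyr::bind_rows(lapply(names(by_track), function(id) {
    tr <- by_track[[id]][order(by_track[[id]]$frame), ]
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    path <- sum(steps)
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
      (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    tibble(
      track_id = as.integer(id),
      velocity_um_min = mean(steps / dt) * 60,
      persistence = if (path > 0) net / path else NA_real_,
      net_um = net, path_um = path
    )
  }))
  structure(list(msd = msd, cells = cells), class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf(
    "<motility_summary> %d cells; mean velocity %.2f um/min; mean persistence %.2f\n",
    nrow(x$cells), mean(x$cells$velocity_um_min),
    mean(x$cells$persistence, na.rm = TRUE)
  ))
  invisible(x)
}

#' @method tidy motility_summary
#' @export
tidy.motility_summary <- function(x, ...) x$cells

#' @method glance motility_summary
#' @export
glance.motility_summary <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    mean_velocity_um_min = mean(x$cells$velocity_um_min),
    mean_persistence = mean(x$cells$persistence, na.rm = TRUE),
    max_lag_s = max(x$msd$lag_s)
  )
}
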
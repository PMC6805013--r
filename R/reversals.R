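# travelling-protrusion detection, reversal calling, Rac-zone edges, and the
# rotation-randomized null for reversal-to-edge distances

#' Detect protrusive components in an edge-velocity kymograph
#'
#' The velocity map is Gaussian-smoothed (circularly along the periodic
#' position axis), binarized at `v_thresh`, and the above-threshold pixels
#' are labelled as 8-connected components with wrap-around in the position
#' axis, so a band straddling position 1/P stays one component.
#'
#' @param vel an [edge_map()] of kind `"velocity"`.
#' @param smooth_sigma `c(positions, frames)` Gaussian s.d.
#' @param v_thresh velocity threshold in um/s (default 0.15).
#' @return tibble of class `protrusion_components` with columns
#'   `component`, `position`, `frame`; the smoothed map is attached as
#'   attribute `smoothed`.
#' @export
detect_protrusion_components <- function(vel, smooth_sigma = c(5, 2),
                                         v_thresh = 0.15) {
  P <- nrow(vel)
  Tn <- ncol(vel)
  vm <- unclass(vel)
  vm[!is.finite(vm)] <- 0
  sm <- gauss_smooth_map(vm, smooth_sigma[1], smooth_sigma[2])
  fg <- which(sm > v_thresh)
  comp <- rep(NA_integer_, length(fg))
  if (length(fg)) {
    pos <- ((fg - 1) %% P) + 1
    fr <- ((fg - 1) %/% P) + 1
    id_of <- rep(NA_integer_, P * Tn)
    id_of[fg] <- seq_along(fg)
    # 8-connectivity with periodic wrap in the position axis
    nb_edges <- list()
    for (s in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
      pos2 <- ((pos - 1 + s[1]) %% P) + 1
      fr2 <- fr + s[2]
      ok <- fr2 >= 1 & fr2 <= Tn
      tgt <- (fr2[ok] - 1) * P + pos2[ok]
      hit <- !is.na(id_of[tgt])
      if (any(hit)) {
        nb_edges[[length(nb_edges) + 1]] <-
          cbind(which(ok)[hit], id_of[tgt[hit]])
      }
    }
    g <- igraph::make_graph(
      edges = if (length(nb_edges)) t(do.call(rbind, nb_edges)) else integer(0),
      n = length(fg), directed = FALSE
    )
    comp <- igraph::components(g)$membership
  }
  out <- tibble(
    component = as.integer(comp),
    position = if (length(fg)) ((fg - 1) %% P) + 1 else integer(0),
    frame = if (length(fg)) ((fg - 1) %/% P) + 1 else integer(0)
  )
  structure(out,
    class = c("protrusion_components", class(tibble())),
    P = P, Tn = Tn, smoothed = sm,
    frame_interval = attr(vel, "frame_interval"),
    perimeter_um = attr(vel, "perimeter_um")
  )
}

#' Track the circular centre of mass of one protrusive component
#'
#' Per frame, the circular mean of the member positions (unit-circle
#' embedding, unweighted) is computed and the resulting fraction sequence is
#' unwrapped into a continuous real-valued trajectory.
#'
#' @param comps a [detect_protrusion_components()] result.
#' @param component component id to track.
#' @return tibble with columns `frame`, `frac` (in `[0, 1)`), and
#'   `unwrapped` (continuous), of class `com_trajectory`.
#' @export
track_component_com <- function(comps, component) {
  P <- attr(comps, "P")
  mem <- comps[comps$component == component, ]
  if (!nrow(mem)) stop("unknown component id")
  frames <- sort(unique(mem$frame))
  if (length(frames) < 2) stop("component must span at least 2 frames")
  frac <- vapply(frames, function(f) {
    circular_mean_frac((mem$position[mem$frame == f] - 1) / P)
  }, numeric(1))
  unwrapped <- frac
  for (i in seq_along(frac)[-1]) {
    jump <- frac[i] - frac[i - 1]
    jump <- jump - round(jump) # nearest equivalent step across the wrap
    unwrapped[i] <- unwrapped[i - 1] + jump
  }
  structure(
    tibble(frame = frames, frac = frac, unwrapped = unwrapped),
    class = c("com_trajectory", class(tibble())),
    component = component, P = P
  )
}

#' Call direction reversals of a protrusion trajectory
#'
#' A reversal is a sign change of the centre-of-mass displacement between
#' consecutive frames; the event is placed at the turning frame and
#' position. Zero displacement inherits the previous direction, so plateaus
#' do not chatter. Components with fewer than `min_reversals` reversals
#' contribute no events.
#'
#' @param traj a [track_component_com()] trajectory.
#' @param min_reversals minimum number of reversals for a component to be
#'   analyzed (default 3).
#' @return tibble of class `reversal_events` with columns `component`,
#'   `frame`, `frac`, `dir_prev`, `dir_new` (possibly empty).
#' @export
call_reversals <- function(traj, min_reversals = 3) {
  disp <- diff(traj$unwrapped)
  dir <- sign(disp)
  # zero steps inherit the previous direction
  for (i in seq_along(dir)) {
    if (dir[i] == 0 && i > 1) dir[i] <- dir[i - 1]
  }
  first_move <- which(dir != 0)[1]
  if (is.na(first_move)) {
    return(empty_reversals())
  }
  if (first_move > 1) dir[seq_len(first_move - 1)] <- dir[first_move]
  flips <- which(dir[-1] != dir[-length(dir)]) + 1
  if (length(flips) < min_reversals) {
    return(empty_reversals())
  }
  tibble(
    component = attr(traj, "component"),
    frame = traj$frame[flips],
    frac = traj$frac[flips],
    dir_prev = dir[flips - 1],
    dir_new = dir[flips]
  ) |>
    structure(class = c("reversal_events", class(tibble())))
}

empty_reversals <- function() {
  structure(
    tibble(
      component = integer(0), frame = integer(0), frac = numeric(0),
      dir_prev = numeric(0), dir_new = numeric(0)
    ),
    class = c("reversal_events", class(tibble()))
  )
}

#' Reversal events of all qualifying components in a velocity map
#'
#' Convenience wrapper: detect components, track each component spanning
#' at least `min_frames` frames, and pool the reversal events.
#'
#' @inheritParams detect_protrusion_components
#' @inheritParams call_reversals
#' @param min_frames minimum component lifetime in frames.
#' @return a `reversal_events` tibble.
#' @export
find_reversals <- function(vel, smooth_sigma = c(5, 2), v_thresh = 0.15,
                           min_reversals = 3, min_frames = 5) {
  comps <- detect_protrusion_components(vel, smooth_sigma, v_thresh)
  if (!nrow(comps)) {
    return(empty_reversals())
  }
  ids <- unique(comps$component)
  evs <- lapply(ids, function(id) {
    mem <- comps[comps$component == id, ]
    if (length(unique(mem$frame)) < max(2, min_frames)) {
      return(NULL)
    }
    call_reversals(track_component_com(comps, id), min_reversals)
  })
  out <- dplyr::bind_rows(evs)
  structure(out, class = c("reversal_events", class(tibble())))
}

#' Rac-activity zone edges from a fluorescence kymograph
#'
#' The fluorescence map is smoothed and binarized with a single Otsu
#' threshold computed on the whole smoothed map (not per frame); per frame,
#' edge positions are the circular state changes of the binary signal along
#' the position axis (localized with a derivative kernel, reported at the
#' boundary fraction between the last pixel of one state and the first of
#' the next).
#'
#' @param fluo an [edge_map()] of kind `"fluorescence"`.
#' @param smooth_sigma `c(positions, frames)` Gaussian s.d.
#' @return tibble of class `zone_edge_set` with columns `frame` and `frac`;
#'   frames that are entirely one state contribute no rows.
#' @export
rac_zone_edges <- function(fluo, smooth_sigma = c(5, 2)) {
  P <- nrow(fluo)
  Tn <- ncol(fluo)
  fm <- unclass(fluo)
  fm[!is.finite(fm)] <- NA
  fill <- mean(fm, na.rm = TRUE)
  fm[is.na(fm)] <- fill
  sm <- gauss_smooth_map(fm, smooth_sigma[1], smooth_sigma[2])
  thr <- otsu_threshold(sm)
  if (is.na(thr)) {
    return(structure(tibble(frame = integer(0), frac = numeric(0)),
      class = c("zone_edge_set", class(tibble())),
      P = P, perimeter_um = attr(fluo, "perimeter_um")
    ))
  }
  bin <- sm > thr
  rows <- lapply(seq_len(Tn), function(t) {
    b <- bin[, t]
    nxt <- c(b[-1], b[1])
    tr <- which(b != nxt) # change between position i and i+1 (wrap)
    if (!length(tr)) {
      return(NULL)
    }
    tibble(frame = t, frac = (tr %% P) / P)
  })
  structure(dplyr::bind_rows(rows),
    class = c("zone_edge_set", class(tibble())),
    P = P, perimeter_um = attr(fluo, "perimeter_um")
  )
}

#' Circular distance from reversal events to the nearest zone edge
#'
#' For each event, the circular distance to the nearest zone edge at the
#' event's frame, expressed as percent of the boundary perimeter (maximum
#' 50%). Events whose frame has no zone edges are skipped and counted.
#'
#' @param events a `reversal_events` tibble.
#' @param zones a [rac_zone_edges()] result.
#' @return tibble of class `reversal_distances` with columns `component`,
#'   `frame`, `frac`, `distance_pct`; summary statistics (median, SD, MAD)
#'   as attribute `summary`, skipped-event count as attribute `n_skipped`.
#' @export
reversal_zone_distance <- function(events, zones) {
  dists <- lapply(seq_len(nrow(events)), function(i) {
    e <- zones$frac[zones$frame == events$frame[i]]
    if (!length(e)) {
      return(NULL)
    }
    tibble(
      component = events$component[i], frame = events$frame[i],
      frac = events$frac[i],
      distance_pct = 100 * min(circular_dist_frac(events$frac[i], e))
    )
  })
  out <- dplyr::bind_rows(dists)
  skipped <- nrow(events) - nrow(out)
  structure(out,
    class = c("reversal_distances", class(tibble())),
    summary = c(
      median = median(out$distance_pct),
      sd = sd(out$distance_pct),
      mad = mad(out$distance_pct)
    ),
    n_skipped = skipped
  )
}

#' Rotation-randomized null distribution of reversal-to-edge distances
#'
#' The zone-edge set is rotated by a uniform random integer position offset
#' (the same offset for every frame within one rotation) and all
#' event-to-edge distances are recomputed; this is repeated `n_rotations`
#' times and the results pooled. A planted spatial relationship between
#' reversals and zone edges survives in the observed distances but not in
#' the rotated ones.
#'
#' @inheritParams reversal_zone_distance
#' @param n_rotations number of random rotations (default 20).
#' @param seed integer seed.
#' @return tibble with columns `rotation`, `component`, `frame`, `frac`,
#'   `distance_pct`; pooled size is `n_rotations * n_events` minus skips.
#' @export
rotation_null <- function(events, zones, n_rotations = 20, seed = 1) {
  stopifnot(nrow(events) > 0)
  P <- attr(zones, "P")
  local_seed(seed, {
    offs <- sample.int(P, n_rotations, replace = TRUE) - 1L
    pooled <- lapply(seq_len(n_rotations), function(k) {
      rz <- zones
      rz$frac <- (zones$frac + offs[k] / P) %% 1
      d <- reversal_zone_distance(events, rz)
      if (nrow(d)) d$rotation <- k
      d
    })
    dplyr::bind_rows(pooled)
  })
}
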
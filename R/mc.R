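# Metropolis Monte-Carlo of a dynamically triangulated vesicle with active
# curved protein nodes
#
# Energy (units kT0, lengths l_min):
#   W   = W_A + W_b + W_d + W_F
#   W_A = (k_A/2) sum_faces (a_i/a_0 - 1)^2            stretching
#   W_b = (kappa/2) sum_vertices A_i (2 H_i - C0_i)^2  bending (area-weighted)
#   W_d = -w * sum protein pairs within r_0             protein binding
#   W_F = -F * sum protein nodes n_i . x_i              active outward force
# Moves: vertex displacement (uniform cube, half-width delta), bond flip of
# the shared edge of two adjacent triangles, and protein occupancy hops to a
# random bonded neighbour. Hard constraints (bond window, self-avoidance,
# optional plate walls) reject a proposal outright; otherwise it is accepted
# with probability min[1, exp(-dE / kT)].

#' Model parameters for the membrane simulation
#'
#' @param kappa bending modulus (kT0).
#' @param k_A stretching modulus (kT0).
#' @param w protein-protein contact energy (kT0).
#' @param force active outward force on protein nodes (kT0 / l_min).
#' @param c0 protein spontaneous curvature (1 / l_min).
#' @param rho fraction of vertices occupied by proteins.
#' @param kT reduced temperature T/T0 (default 0.7).
#' @param l_min hard-core bond minimum (sets the length unit; default 1).
#' @param l_max bond maximum, `1.7 * l_min`.
#' @param r0 protein binding range (default `l_max`).
#' @param wall_d optional gap between two hard plates at `z = +-wall_d/2`
#'   (l_min units); `Inf` disables confinement.
#' @param delta vertex-move cube half-width (l_min units).
#' @return list of class `model_params`.
#' @export
model_params <- function(kappa = 20, k_A = 1, w = 1, force = 1, c0 = 1,
                         rho = 0.11, kT = 0.7, l_min = 1, l_max = 1.7 * l_min,
                         r0 = l_max, wall_d = Inf, delta = 0.1 * l_min) {
  stopifnot(
    kappa >= 0, k_A >= 0, rho >= 0, rho <= 1, kT > 0,
    l_min > 0, l_max > l_min, wall_d > 0
  )
  l0 <- (l_min + l_max) / 2
  structure(
    list(
      kappa = kappa, k_A = k_A, w = w, force = force, c0 = c0, rho = rho,
      kT = kT, l_min = l_min, l_max = l_max, l0 = l0,
      a0 = sqrt(3) * l0^2 / 4, r0 = r0, wall_d = wall_d, delta = delta
    ),
    class = "model_params"
  )
}

params_cpp <- function(p) {
  list(
    kappa = p$kappa, k_A = p$k_A, w = p$w, force = p$force, c0 = p$c0,
    kT = p$kT, l_min = p$l_min, l_max = p$l_max, a0 = p$a0, r0 = p$r0,
    wall_d = p$wall_d
  )
}

#' Simulation state: mesh plus protein occupancy
#'
#' Assigns exactly `round(rho * V)` protein nodes uniformly at random.
#' Protein count is conserved by every Monte-Carlo move.
#'
#' @param mesh a [generate_vesicle_mesh()] result.
#' @param params a [model_params()].
#' @param seed integer seed for the occupancy draw.
#' @return object of class `sim_state`.
#' @export
sim_state <- function(mesh, params, seed = 1) {
  V <- nrow(mesh$positions)
  n_prot <- round(params$rho * V)
  protein <- rep(FALSE, V)
  if (n_prot > 0) {
    protein[local_seed(seed, sample.int(V, n_prot))] <- TRUE
  }
  st <- list(
    positions = mesh$positions, faces = mesh$faces, protein = protein,
    params = params, energy = NULL
  )
  st$energy <- energy_total(st, params)
  structure(st, class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  e <- x$energy
  cat(sprintf(
    "<sim_state> V=%d, %d proteins; W=%.2f (W_A=%.2f W_b=%.2f W_d=%.2f W_F=%.2f) kT0\n",
    nrow(x$positions), sum(x$protein), e$W, e$W_A, e$W_b, e$W_d, e$W_F
  ))
  invisible(x)
}

#' Total energy and its breakdown
#'
#' Recomputes all four energy terms from scratch for a state.
#'
#' @param state a `sim_state` (or list with `positions`, `faces`,
#'   `protein`).
#' @param params a [model_params()].
#' @return list of class `energy_breakdown` with `W_A`, `W_b`, `W_d`,
#'   `W_F`, `W` (kT0), plus `W_b_raw`, the area-unweighted bending sum kept
#'   for comparison with the weighted discretization.
#' @export
energy_total <- function(state, params = state$params) {
  e <- cpp_energy(
    state$positions, state$faces, state$protein, params_cpp(params)
  )
  structure(e, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "W = %.3f kT0 (A %.3f, b %.3f, d %.3f, F %.3f)\n",
    x$W, x$W_A, x$W_b, x$W_d, x$W_F
  ))
  invisible(x)
}

#' Attempt elementary Monte-Carlo moves of one kind
#'
#' Exposes the engine's elementary move surface: `n` proposals of the given
#' kind are made and accepted or rejected by the Metropolis rule under the
#' hard constraints.
#'
#' @param state a `sim_state`.
#' @param kind `"vertex_move"`, `"bond_flip"` or `"protein_hop"`.
#' @param params a [model_params()].
#' @param n number of attempts.
#' @param seed integer seed.
#' @return list with the updated `state` and the number `accepted`.
#' @export
attempt_move <- function(state, kind = c("vertex_move", "bond_flip",
                                         "protein_hop"),
                         params = state$params, n = 1, seed = 1) {
  kind <- match.arg(kind)
  res <- local_seed(seed, cpp_mc_attempts(
    state$positions, state$faces, state$protein, params_cpp(params),
    kind, as.integer(n), params$delta
  ))
  new_state <- state
  new_state$positions <- res$positions
  new_state$faces <- res$faces
  new_state$protein <- res$protein
  new_state$energy <- structure(res$energy, class = "energy_breakdown")
  new_state$params <- params
  list(state = new_state, accepted = res$accepted)
}

#' Run Monte-Carlo sweeps
#'
#' One sweep makes `V` vertex-move attempts, `E` bond-flip attempts, and
#' one hop attempt per protein, interleaved in random order. The energy
#' breakdown is maintained incrementally by the engine; `run_sweeps`
#' returns it as `state$energy`, and `energy_total()` recomputes it from
#' scratch for drift checks. With `debug = TRUE` the topological and hard
#' constraints are re-verified after the run and any violation aborts.
#'
#' @param state a `sim_state`.
#' @param params a [model_params()].
#' @param n_sweeps number of sweeps.
#' @param seed integer seed.
#' @param sample_every if > 0, record observables every that many sweeps
#'   (attached as attribute `samples`, a tibble).
#' @param debug verify invariants after the run.
#' @return the updated `sim_state` (with attribute `samples` when sampled
#'   and attribute `acceptance` holding per-move acceptance counts).
#' @export
run_sweeps <- function(state, params = state$params, n_sweeps = 100,
                       seed = 1, sample_every = 0, debug = FALSE) {
  res <- local_seed(seed, cpp_run_mc(
    state$positions, state$faces, state$protein, params_cpp(params),
    as.integer(n_sweeps), params$delta, as.integer(sample_every),
    TRUE, TRUE
  ))
  out <- state
  out$positions <- res$positions
  out$faces <- res$faces
  out$protein <- res$protein
  out$energy <- structure(res$energy, class = "energy_breakdown")
  out$params <- params
  attr(out, "samples") <- as_tibble(res$samples)
  attr(out, "acceptance") <- res$acceptance
  if (debug) check_state_invariants(out, params)
  out
}

check_state_invariants <- function(state, params = state$params) {
  V <- nrow(state$positions)
  Fn <- nrow(state$faces)
  if (Fn != 2 * V - 4) stop("topology violated: F != 2V - 4")
  geo <- cpp_mesh_geometry(state$positions, state$faces)
  if (nrow(geo$edges) != 3 * V - 6) stop("topology violated: E != 3V - 6")
  el <- sqrt(rowSums(
    (state$positions[geo$edges[, 1], ] - state$positions[geo$edges[, 2], ])^2
  ))
  if (min(el) <= params$l_min || max(el) >= params$l_max) {
    stop(sprintf("bond window violated: [%.4f, %.4f]", min(el), max(el)))
  }
  nb <- cpp_min_nonbonded_dist(state$positions, state$faces)
  if (nb < params$l_min) stop(sprintf("self-avoidance violated: %.4f", nb))
  if (is.finite(params$wall_d) &&
    any(abs(state$positions[, 3]) > params$wall_d / 2)) {
    stop("confinement walls violated")
  }
  e_inc <- state$energy
  e_new <- energy_total(state, params)
  rel <- abs(e_inc$W - e_new$W) / max(abs(e_new$W), 1)
  if (rel > 1e-6) stop(sprintf("energy drift %.2e relative", rel))
  invisible(TRUE)
}

#' Bare Metropolis acceptance sampling
#'
#' Draws `n` accept/reject decisions for a fixed energy change `dE` at
#' temperature `kT`; the acceptance fraction estimates
#' `min[1, exp(-dE/kT)]`.
#'
#' @param dE energy change (kT0).
#' @param kT temperature (T/T0).
#' @param n number of trials.
#' @param seed integer seed.
#' @return number of accepted trials.
#' @export
metropolis_accept <- function(dE, kT, n = 1, seed = 1) {
  local_seed(seed, cpp_metropolis_trials(dE, kT, as.integer(n)))
}

#' Membrane tension of sampled states
#'
#' The model's tension is the canonical-ensemble average of the stretching
#' energy per membrane area, `sigma = < W_A / A >`.
#'
#' @param states a list of `sim_state`s, an `mc_ensemble` tibble, or a
#'   single state.
#' @return scalar tension (kT0 / l_min^2).
#' @export
tension <- function(states) {
  if (inherits(states, "mc_ensemble")) {
    return(mean(states$W_A / states$area))
  }
  if (inherits(states, "sim_state")) states <- list(states)
  vals <- vapply(states, function(s) {
    a <- total_area(s)
    if (a <= 0) stop("zero membrane area")
    s$energy$W_A / a
  }, numeric(1))
  mean(vals)
}

total_area <- function(state) {
  sum(cpp_mesh_geometry(state$positions, state$faces)$face_area)
}

#' Gradual confinement between parallel plates
#'
#' Hard walls at `z = +-d/2` are introduced gradually: the gap is stepped
#' down from the vesicle's current z-extent to the target over `n_stages`
#' thermalization runs, so the membrane is squeezed rather than teleported
#' into an infeasible state.
#'
#' @param state a `sim_state`.
#' @param params a [model_params()]; its `wall_d` is overridden by `d`.
#' @param d target plate gap (l_min units).
#' @param sweeps_per_stage thermalization sweeps at each intermediate gap.
#' @param n_stages number of gap steps.
#' @param seed integer seed.
#' @return list with the confined `state` and the `params` (with
#'   `wall_d = d`) to use for further sweeps.
#' @export
apply_confinement <- function(state, params = state$params, d,
                              sweeps_per_stage = 200, n_stages = 6,
                              seed = 1) {
  stopifnot(d > 0)
  z_extent <- diff(range(state$positions[, 3]))
  if (d >= z_extent) {
    p <- params
    p$wall_d <- d
    return(list(state = state, params = p))
  }
  gaps <- seq(z_extent * 1.02, d, length.out = n_stages + 1)[-1]
  st <- state
  for (i in seq_along(gaps)) {
    p <- params
    p$wall_d <- gaps[i]
    # recentre z so the current shape fits the next gap
    zr <- range(st$positions[, 3])
    st$positions[, 3] <- st$positions[, 3] - mean(zr)
    if (diff(zr) >= gaps[i]) {
      st$positions[, 3] <- st$positions[, 3] * (gaps[i] * 0.98 / diff(zr))
    }
    st <- run_sweeps(st, p, n_sweeps = sweeps_per_stage, seed = seed + i)
  }
  p <- params
  p$wall_d <- d
  list(state = st, params = p)
}

#' Sample an ensemble of independent microstates
#'
#' Each replicate starts from a fresh protein assignment with its own seed,
#' is thermalized, and contributes one set of observables: the energy
#' breakdown, total area, tension contribution `W_A / A`, gyration
#' eigenvalues, and asphericity.
#'
#' @param params a [model_params()].
#' @param n_states number of independent microstates (200 reproduces the
#'   full ensemble; smaller values give quick desk-scale estimates).
#' @param n_vertices mesh size (vertices).
#' @param thermalize_sweeps sweeps before measuring.
#' @param seed integer base seed; replicate `i` uses `seed + i`.
#' @param mesh optional prebuilt [generate_vesicle_mesh()] (saves rebuild).
#' @param confine_d optional plate gap applied via [apply_confinement()].
#' @return tibble of class `mc_ensemble`, one row per state.
#' @export
sample_ensemble <- function(params, n_states = 200, n_vertices = 642,
                            thermalize_sweeps = 500, seed = 1, mesh = NULL,
                            confine_d = NULL) {
  stopifnot(n_states >= 1)
  if (is.null(mesh)) mesh <- generate_vesicle_mesh(n_vertices, seed = seed)
  rows <- vector("list", n_states)
  for (i in seq_len(n_states)) {
    st <- sim_state(mesh, params, seed = seed + i)
    ok <- tryCatch(
      {
        if (!is.null(confine_d)) {
          cf <- apply_confinement(st, params,
            d = confine_d,
            sweeps_per_stage = max(100, thermalize_sweeps %/% 5),
            seed = seed + 1000 + i
          )
          st <- run_sweeps(cf$state, cf$params,
            n_sweeps = thermalize_sweeps, seed = seed + 2000 + i
          )
        } else {
          st <- run_sweeps(st, params,
            n_sweeps = thermalize_sweeps, seed = seed + 2000 + i
          )
        }
        TRUE
      },
      error = function(e) {
        warning(sprintf("replicate %d aborted: %s", i, conditionMessage(e)))
        FALSE
      }
    )
    if (!ok) next
    a <- asphericity(st$positions)
    rows[[i]] <- tibble(
      state = i, seed = seed + i,
      W_A = st$energy$W_A, W_b = st$energy$W_b, W_d = st$energy$W_d,
      W_F = st$energy$W_F, W = st$energy$W,
      area = total_area(st), sigma = st$energy$W_A / total_area(st),
      lambda1 = a$lambda[1], lambda2 = a$lambda[2], lambda3 = a$lambda[3],
      asphericity = a$asphericity
    )
  }
  structure(dplyr::bind_rows(rows),
    class = c("mc_ensemble", class(tibble())),
    params = params, n_vertices = n_vertices
  )
}

#' @method glance mc_ensemble
#' @export
glance.mc_ensemble <- function(x, ...) {
  tibble(
    n_states = nrow(x),
    sigma_mean = mean(x$sigma), sigma_sd = sd(x$sigma),
    asphericity_mean = mean(x$asphericity),
    asphericity_sd = sd(x$asphericity),
    area_mean = mean(x$area)
  )
}
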
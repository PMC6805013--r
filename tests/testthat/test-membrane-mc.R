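# triangulated-membrane Monte Carlo: energies, curvature, moves, observables

tetra_state <- function(edge = 1.35, protein = c(TRUE, TRUE, FALSE, FALSE),
                        params = model_params(rho = 0)) {
  # regular tetrahedron with the requested edge length: the one closed mesh
  # whose faces are all equilateral
  pos <- matrix(c(
    1, 1, 1,
    1, -1, -1,
    -1, 1, -1,
    -1, -1, 1
  ), 4, 3, byrow = TRUE) * edge / (2 * sqrt(2))
  faces <- matrix(c(
    1, 3, 2,
    1, 2, 4,
    1, 4, 3,
    2, 3, 4
  ), 4, 3, byrow = TRUE)
  st <- list(positions = pos, faces = faces, protein = protein, params = params)
  st$energy <- energy_total(st, params)
  class(st) <- "sim_state"
  st
}

test_that("equilateral triangles at the rest length carry zero stretching", {
  p <- model_params(k_A = 5, w = 0, force = 0, c0 = 0, rho = 0)
  st <- tetra_state(edge = p$l0, protein = rep(FALSE, 4), params = p)
  expect_equal(st$energy$W_A, 0, tolerance = 1e-12)
})

test_that("a single bonded protein pair contributes exactly -w", {
  p <- model_params(w = 1, force = 0, c0 = 0, kappa = 0)
  st <- tetra_state(edge = 1.35, protein = c(TRUE, TRUE, FALSE, FALSE),
                    params = p)
  expect_equal(st$energy$W_d, -1, tolerance = 1e-12)
  # energy extensivity: doubling w doubles W_d; doubling F doubles W_F
  p2 <- model_params(w = 2, force = 0, c0 = 0, kappa = 0)
  expect_equal(energy_total(st, p2)$W_d, -2, tolerance = 1e-12)
  pf1 <- model_params(w = 0, force = 1, c0 = 0, kappa = 0)
  pf2 <- model_params(w = 0, force = 2, c0 = 0, kappa = 0)
  expect_equal(energy_total(st, pf2)$W_F, 2 * energy_total(st, pf1)$W_F,
    tolerance = 1e-12
  )
})

test_that("closed-sphere bending energy reproduces 8 pi kappa within 5%", {
  m <- generate_vesicle_mesh(642, seed = 1)
  p <- model_params(kappa = 20, rho = 0, c0 = 0, force = 0, w = 0)
  st <- sim_state(m, p, seed = 1)
  expect_equal(st$energy$W_b / (8 * pi * 20), 1, tolerance = 0.05)
})

test_that("discrete mean curvature matches 1/R on a relaxed sphere", {
  m <- generate_vesicle_mesh(642, seed = 1)
  g <- serpentine:::cpp_mesh_geometry(m$positions, m$faces)
  R <- sqrt(sum(g$face_area) / (4 * pi))
  expect_true(all(abs(g$H * R - 1) < 0.05))
})

test_that("tension is the ensemble mean of W_A over area and scales with k_A", {
  m <- generate_vesicle_mesh(162, seed = 1)
  p <- model_params(k_A = 1, rho = 0, c0 = 0, force = 0, w = 0)
  st <- run_sweeps(sim_state(m, p, seed = 1), p, n_sweeps = 60, seed = 2)
  sig1 <- tension(st)
  expect_equal(sig1, st$energy$W_A / serpentine:::total_area(st))
  # doubling k_A on the fixed configuration doubles sigma
  p2 <- model_params(k_A = 2, rho = 0, c0 = 0, force = 0, w = 0)
  st2 <- st
  st2$energy <- energy_total(st, p2)
  expect_equal(tension(st2), 2 * sig1, tolerance = 1e-12)
})

test_that("asphericity limits: rod 1, regular polygon 1/4, icosahedron 0", {
  rod <- cbind(seq(-3, 3, length.out = 50), 0, 0)
  expect_equal(asphericity(rod)$asphericity, 1, tolerance = 1e-12)
  th <- 2 * pi * (0:11) / 12
  poly <- cbind(cos(th), sin(th), 0)
  expect_equal(asphericity(poly)$asphericity, 1 / 4, tolerance = 1e-12)
  ico <- generate_vesicle_mesh(12, seed = 1)
  expect_equal(asphericity(ico)$asphericity, 0, tolerance = 1e-10)
  expect_error(asphericity(matrix(1, 5, 3)), "coincide")
})

test_that("Metropolis accepts downhill always, uphill at exp(-dE/kT)", {
  expect_equal(metropolis_accept(-3, 0.7, n = 1000, seed = 1), 1000)
  n <- 1e5
  kT <- 1
  acc <- metropolis_accept(2 * kT, kT, n = n, seed = 7)
  p <- exp(-2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc / n - p), 3 * se)
})

test_that("moves conserve topology, protein count, and hard constraints", {
  m <- generate_vesicle_mesh(162, seed = 2)
  p <- model_params(rho = 0.11, c0 = 1, force = 1, w = 1)
  st <- sim_state(m, p, seed = 3)
  n_prot <- sum(st$protein)
  st2 <- run_sweeps(st, p, n_sweeps = 50, seed = 4, debug = TRUE)
  expect_equal(sum(st2$protein), n_prot)
  expect_equal(nrow(st2$faces), 2 * nrow(st2$positions) - 4)
})

test_that("incremental energy matches a from-scratch recomputation", {
  m <- generate_vesicle_mesh(162, seed = 5)
  p <- model_params(rho = 0.11, c0 = 1, force = 1, w = 1)
  st <- run_sweeps(sim_state(m, p, seed = 6), p, n_sweeps = 300, seed = 7)
  scratch <- energy_total(st, p)
  expect_equal(st$energy$W, scratch$W, tolerance = 1e-6)
  for (term in c("W_A", "W_b", "W_d", "W_F")) {
    expect_equal(st$energy[[term]], scratch[[term]],
      tolerance = 1e-6 * max(1, abs(scratch$W))
    )
  }
})

test_that("single-kind attempts work and leave valid states", {
  m <- generate_vesicle_mesh(80, seed = 1)
  p <- model_params(rho = 0.2, c0 = 1, force = 1, w = 1)
  st <- sim_state(m, p, seed = 1)
  for (kind in c("vertex_move", "bond_flip", "protein_hop")) {
    out <- attempt_move(st, kind, p, n = 200, seed = 3)
    expect_gte(out$accepted, 0)
    expect_equal(sum(out$state$protein), sum(st$protein))
    serpentine:::check_state_invariants(out$state, p)
  }
})

test_that("protein hop occupancies obey detailed balance on a frozen mesh", {
  # hops on a frozen, irregular mesh: long-run site occupancy of one protein
  # follows the Boltzmann weights of the per-site energies
  m <- generate_vesicle_mesh(12, seed = 1)
  set.seed(9)
  m$positions <- m$positions + matrix(rnorm(36, sd = 0.08), 12, 3)
  p <- model_params(rho = 1 / 12, c0 = 2.5, force = 1.5, w = 0, kT = 0.7)
  st <- sim_state(m, p, seed = 1)
  counts <- integer(12)
  for (rep in 1:3000) {
    out <- attempt_move(st, "protein_hop", p, n = 3, seed = 1000 + rep)
    st <- out$state
    counts[which(st$protein)] <- counts[which(st$protein)] + 1L
  }
  site_E <- vapply(1:12, function(i) {
    pr <- rep(FALSE, 12)
    pr[i] <- TRUE
    s <- list(positions = m$positions, faces = m$faces, protein = pr)
    energy_total(s, p)$W
  }, numeric(1))
  pi_theory <- exp(-(site_E - min(site_E)) / p$kT)
  pi_theory <- pi_theory / sum(pi_theory)
  pi_emp <- counts / sum(counts)
  # crude multinomial errors on the empirical frequencies
  se <- sqrt(pi_theory * (1 - pi_theory) / sum(counts)) * 8 # autocorrelation
  expect_true(all(abs(pi_emp - pi_theory) < pmax(3 * se, 0.02)))
})

test_that("protein-free, force-free vesicles stay quasi-spherical", {
  m <- generate_vesicle_mesh(302, seed = 1)
  p <- model_params(kappa = 20, rho = 0, c0 = 0, force = 0, w = 0)
  st <- run_sweeps(sim_state(m, p, seed = 1), p,
    n_sweeps = 300, seed = 2, sample_every = 50
  )
  asph <- attr(st, "samples")$asphericity
  expect_lt(mean(asph[-1]), 0.05)
})

test_that("protein binding drives aggregation: more contacts at w=1 than w=0", {
  m <- generate_vesicle_mesh(162, seed = 3)
  contacts_after <- function(w) {
    p <- model_params(w = w, rho = 0.15, c0 = 0.5, force = 0.5)
    st <- run_sweeps(sim_state(m, p, seed = 10), p, n_sweeps = 250, seed = 11)
    # count contacts by evaluating W_d under w = 1
    -energy_total(st, model_params(w = 1, rho = 0.15))$W_d
  }
  expect_gt(contacts_after(1), contacts_after(0))
})

test_that("ensembles are reproducible and report per-state observables", {
  p <- model_params(rho = 0.11)
  e1 <- sample_ensemble(p, n_states = 3, n_vertices = 80,
                        thermalize_sweeps = 40, seed = 5)
  e2 <- sample_ensemble(p, n_states = 3, n_vertices = 80,
                        thermalize_sweeps = 40, seed = 5)
  expect_equal(e1, e2)
  expect_equal(nrow(e1), 3)
  expect_true(all(e1$asphericity >= 0 & e1$asphericity <= 1))
  expect_true(all(e1$lambda1 >= e1$lambda2 & e1$lambda2 >= e1$lambda3))
  g <- glance(e1)
  expect_equal(g$n_states, 3)
})

test_that("hard walls confine every vertex and leave far walls inactive", {
  m <- generate_vesicle_mesh(162, seed = 4)
  p <- model_params(kappa = 20, rho = 0, c0 = 0, force = 0, w = 0)
  st <- sim_state(m, p, seed = 1)
  # d far larger than the vesicle: trajectories identical to unconfined
  p_far <- p
  p_far$wall_d <- 1e4
  a <- run_sweeps(st, p, n_sweeps = 30, seed = 9)
  b <- run_sweeps(st, p_far, n_sweeps = 30, seed = 9)
  expect_identical(a$positions, b$positions)

  # gradual squeeze to a tight gap: all z inside the walls
  d <- 4
  cf <- apply_confinement(st, p, d = d, sweeps_per_stage = 60, n_stages = 5,
                          seed = 2)
  expect_true(all(abs(cf$state$positions[, 3]) <= d / 2))
  # squeezing raises asphericity above the free value
  free_asph <- asphericity(a$positions)$asphericity
  expect_gt(asphericity(cf$state$positions)$asphericity, free_asph)
})
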
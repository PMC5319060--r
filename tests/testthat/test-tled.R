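test_that("Lame conversion matches the closed forms and rejects nu >= 0.5", {
  # the phantom parenchyma values
  l <- lame_from_youngs(2e5, 0.49)
  expect_equal(l$mu, 2e5 / (2 * 1.49), tolerance = 1e-14)
  expect_equal(l$lambda, 2e5 * 0.49 / (1.49 * 0.02), tolerance = 1e-14)
  expect_equal(lame_from_youngs(1e6, 0)$lambda, 0)
  expect_error(lame_from_youngs(1e6, 0.5), "0.5")
  expect_error(lame_from_youngs(-1, 0.3), "> 0")
})

test_that("Neo-Hookean stress matches symbolic closed forms", {
  expect_equal(pk2_neo_hookean(diag(3), 1e5, 2e5), matrix(0, 3, 3),
               tolerance = 1e-15)
  # uniaxial stretch with lambda = 0: S = mu * diag(1 - 1/1.44, 0, 0)
  mu <- 7.3e4
  S <- pk2_neo_hookean(diag(c(1.2, 1, 1)), mu, 0)
  expect_equal(S, diag(c(mu * (1 - 1 / 1.44), 0, 0)), tolerance = 1e-12)
  # general F against the formula evaluated independently
  F <- matrix(c(1.05, 0.02, 0, -0.01, 0.98, 0.03, 0, 0.01, 1.02), 3, 3)
  C <- t(F) %*% F
  Sref <- 1e5 * (diag(3) - solve(C)) + 2e5 * log(det(F)) * solve(C)
  expect_equal(pk2_neo_hookean(F, 1e5, 2e5), Sref, tolerance = 1e-12)
  expect_error(pk2_neo_hookean(diag(c(0.5, 0.5, -1)), 1e5, 2e5), "inversion")
})

test_that("precomputation conserves mass and has zero-sum shape derivatives", {
  # one unit-cube element at rho 1000: each lumped nodal mass is 125 kg
  vol <- labeled_volume(array(1L, c(1, 1, 1)), spacing = c(1, 1, 1))
  cfg <- default_config()
  cfg$solver$mass_scaling <- FALSE
  pre <- precompute_tled(build_hex_mesh(vol), cfg)
  expect_equal(pre$mass, rep(125, 8), tolerance = 1e-12)
  # derivative rows sum to zero per coordinate at every quadrature point
  for (quad in c("reduced", "full")) {
    cfg$solver$quadrature <- quad
    pre2 <- precompute_tled(build_hex_mesh(block_volume(c(2, 2, 2))), cfg)
    nq <- pre2$nq
    for (q in seq_len(nq))
      expect_equal(colSums(pre2$dhdX[8 * (q - 1) + 1:8, ]), rep(0, 3),
                   tolerance = 1e-12)
  }
  # total mass equals rho * volume
  mesh <- build_hex_mesh(block_volume(c(2, 2, 2)))
  cfg$solver$quadrature <- "reduced"
  pre3 <- precompute_tled(mesh, cfg)
  expect_equal(sum(pre3$mass), 1000 * 8 * prod(mesh$spacing),
               tolerance = 1e-12)
  bad <- mesh; bad$element_label[1] <- 2L
  cfg2 <- cfg; cfg2$materials$vessel <- NULL
  expect_error(precompute_tled(bad, cfg2), "no material")
})

test_that("internal forces vanish for rigid motions and sum to zero", {
  mesh <- build_hex_mesh(block_volume(c(3, 2, 2)))
  pre <- precompute_tled(mesh, default_config())
  n <- nrow(mesh$nodes)
  # rigid translation
  u <- matrix(rep(c(1e-3, -2e-3, 5e-4), each = n), n, 3)
  expect_lt(max(abs(internal_forces(pre, u))), 1e-10)
  # small rigid rotation (exactly stress-free in total-Lagrangian + NH)
  th <- 1e-3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ur <- mesh$nodes %*% t(R) - mesh$nodes
  expect_lt(max(abs(internal_forces(pre, ur))), 1e-9 * 2e5 * prod(mesh$spacing[1:2]))
  # arbitrary deformation: free-body force balance
  set.seed(4)
  ua <- matrix(rnorm(3 * n, sd = 2e-4), n, 3)
  f <- internal_forces(pre, ua)
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("bar nodal forces match a linear-elastic assembly at small strain", {
  vol <- block_volume(c(4, 1, 1))
  mesh <- build_hex_mesh(vol)
  cfg <- default_config()
  cfg$solver$quadrature <- "full"
  cfg$materials$parenchyma <- list(E = 2e5, nu = 0.49, rho = 1000)
  pre <- precompute_tled(mesh, cfg)
  u <- cbind(0.005 * mesh$nodes[, 1], 0, 0)  # 0.5% uniaxial strain
  f_nh <- internal_forces(pre, u)
  f_lin <- linear_fem_forces(mesh, 2e5, 0.49, u)
  expect_lt(max(abs(f_nh - f_lin)) / max(abs(f_lin)), 0.01)
})

test_that("the critical time step follows the dilatational CFL bound", {
  vol <- labeled_volume(array(1L, c(2, 2, 2)), spacing = c(1, 1, 1))
  mesh <- build_hex_mesh(vol)
  cfg <- default_config()
  cfg$solver$mass_scaling <- FALSE
  lame <- lame_from_youngs(2e5, 0.49)
  dt_ref <- 0.8 * 1 / sqrt((lame$lambda + 2 * lame$mu) / 1000)
  expect_equal(critical_time_step(mesh, cfg, safety = 0.8), dt_ref,
               tolerance = 1e-12)
  # doubling E shrinks dt by sqrt(2); halving the edge halves dt
  cfg2 <- cfg; cfg2$materials$parenchyma$E <- 4e5
  expect_equal(critical_time_step(mesh, cfg2, 0.8), dt_ref / sqrt(2),
               tolerance = 1e-12)
  half <- build_hex_mesh(labeled_volume(array(1L, c(2, 2, 2)),
                                        spacing = c(0.5, 0.5, 0.5)))
  expect_equal(critical_time_step(half, cfg, 0.8), dt_ref / 2,
               tolerance = 1e-12)
  expect_error(critical_time_step(mesh, cfg, safety = 1.5), "safety")
})

test_that("the explicit update fixes equilibria and enforces constraints", {
  mesh <- build_hex_mesh(block_volume(c(2, 2, 2)))
  cfg <- test_config()
  pre <- precompute_tled(mesh, cfg)
  dt <- critical_time_step(mesh, cfg)
  st0 <- sim_state(nrow(mesh$nodes))
  # zero forces, zero velocity, no bc: nothing moves
  st1 <- advance_step(pre, st0, dt = dt, n_steps = 5)
  expect_equal(st1$u, st0$u)
  expect_equal(st1$v, st0$v)
  # a prescribed node carries exactly its boundary value after the step
  bc <- list(idx = 1L, u = matrix(c(2e-4, 0, -1e-4), 1))
  st2 <- advance_step(pre, st0, bc = bc, dt = dt, n_steps = 3)
  expect_equal(st2$u[1, ], c(2e-4, 0, -1e-4), tolerance = 1e-15)
})

test_that("mechanical energy decays under mass damping", {
  mesh <- build_hex_mesh(block_volume(c(2, 2, 2)))
  cfg <- test_config()
  cfg$solver$damping <- 2000
  cfg$solver$dt_safety <- 0.1
  pre <- precompute_tled(mesh, cfg)
  dt <- critical_time_step(mesh, cfg)
  n <- nrow(mesh$nodes)
  # pre-stretched free block, no constraints, released from rest; audit the
  # kinetic + strain (+hourglass) energy over windows longer than the
  # block's vibration period (the staggered-time leapfrog energy carries an
  # O(dt * omega) ripple within a period, so the audit samples per window)
  st <- sim_state(n)
  st$u <- cbind(2e-3 * (mesh$nodes[, 1] - mean(mesh$nodes[, 1])) / max(mesh$nodes[, 1]), 0, 0)
  energy <- function(s) sum(0.5 * pre$mass * rowSums(s$v^2)) + strain_energy(pre, s$u)
  e0 <- energy(st)
  e_prev <- e0
  for (k in 1:20) {
    st <- advance_step(pre, st, dt = dt, n_steps = 100)
    e <- energy(st)
    expect_lte(e, e_prev)
    e_prev <- e
  }
  expect_lt(e_prev, 1e-6 * e0)
})

test_that("linear momentum is conserved without damping or constraints", {
  mesh <- build_hex_mesh(block_volume(c(2, 2, 2)))
  cfg <- test_config()
  cfg$solver$damping <- 0
  cfg$solver$mass_scaling <- FALSE
  pre <- precompute_tled(mesh, cfg)
  dt <- critical_time_step(mesh, cfg, safety = 0.2)
  n <- nrow(mesh$nodes)
  set.seed(5)
  st <- sim_state(n, v = matrix(rnorm(3 * n, sd = 1e-3), n, 3))
  p0 <- colSums(pre$mass * st$v)
  st <- advance_step(pre, st, dt = dt, n_steps = 1000)
  p1 <- colSums(pre$mass * st$v)
  expect_lt(max(abs(p1 - p0)) / max(abs(p0)), 1e-9)
})

test_that("run_to_equilibrium converges trivially at rest and reports failure", {
  mesh <- build_hex_mesh(block_volume(c(2, 2, 2)))
  cfg <- test_config()
  pre <- precompute_tled(mesh, cfg)
  st <- run_to_equilibrium(pre, bc = list(idx = integer(0)))
  expect_true(st$converged)
  expect_equal(max(abs(st$u)), 0)
  # an unreachable tolerance raises the non-convergence error with the
  # residual velocity
  bc <- block_scenario(mesh, magnitude = 1e-3)
  bcl <- bc_from_scenario(mesh, bc)
  expect_error(
    run_to_equilibrium(pre, bcl, tol = 1e-300, max_steps = 2000),
    "no equilibrium.*residual")
})
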
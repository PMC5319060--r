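tumor_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vol <- embedded_tumor_volume(7, 3)
      mesh <- build_hex_mesh(vol)
      cfg <- test_config()
      model <- deformable_model(mesh, cfg)
      cache <<- list(mesh = mesh, cfg = cfg, model = model)
    }
    cache
  }
})

test_that("boundary-pair enumeration matches brute-force shared vertices", {
  # a homogeneous mesh has no interface
  mesh_h <- build_hex_mesh(block_volume(c(3, 3, 3)))
  iface_h <- build_interface(mesh_h)
  expect_equal(nrow(iface_h$pairs), 0L)
  # one tumor element inside a 3x3x3 parenchyma block: its 8 corners are
  # exactly the vertices shared between tumor and parenchyma elements
  mesh1 <- build_hex_mesh(embedded_tumor_volume(3, 1))
  pairs <- enumerate_boundary_pairs(mesh1)
  shared <- intersect(
    unique(as.vector(mesh1$elements[mesh1$element_label == 3L, , drop = FALSE])),
    unique(as.vector(mesh1$elements[mesh1$element_label == 1L, , drop = FALSE])))
  expect_equal(sort(pairs$node), sort(shared))
  expect_equal(nrow(pairs), 8L)
  expect_true(all(pairs$kind == "tumor"))
})

test_that("split pairs start coincident and support domains stay disjoint", {
  fx <- tumor_fixture()
  iface <- fx$model$interface
  expect_gt(nrow(iface$pairs), 0)
  st0 <- reconstruct_boundary_positions(iface, matrix(0, nrow(fx$mesh$nodes), 3))
  expect_lt(max(st0$gap), 1e-10)
  # per-pair support node sets are disjoint across the two sides
  for (s in seq_len(nrow(iface$pairs))) {
    kP <- (iface$supP$ptr[s] + 1):iface$supP$ptr[s + 1]
    kQ <- (iface$supQ$ptr[s] + 1):iface$supQ$ptr[s + 1]
    expect_length(intersect(iface$supP$idx[kP], iface$supQ$idx[kQ]), 0)
  }
})

# the stored per-pair radius is not kept on the interface; recompute it the
# same way the builder does (support radius after k-nearest trimming)
attr_radius <- function(iface, s) {
  kP <- (iface$supP$ptr[s] + 1):iface$supP$ptr[s + 1]
  idx <- iface$supP$idx[kP]
  fx <- tumor_fixture()
  q <- as.numeric(unlist(iface$pairs[s, c("x", "y", "z")]))
  d <- sqrt(colSums((t(fx$mesh$nodes[idx, ]) - q)^2))
  max(default_config()$mls$radius_factor * max(fx$mesh$spacing), 1.05 * max(d))
}

test_that("boundary reconstruction reproduces rigid motion and direct MLS", {
  fx <- tumor_fixture()
  iface <- fx$model$interface
  n <- nrow(fx$mesh$nodes)
  # rigid translation: both sides move by d, the gap stays zero
  d <- c(1e-3, 2e-3, -5e-4)
  st <- reconstruct_boundary_positions(iface, matrix(rep(d, each = n), n, 3))
  expect_lt(max(st$gap), 1e-12)
  expect_equal(st$bp_x - iface$pairs$x, rep(d[1], nrow(st)), tolerance = 1e-12)
  # random smooth deformation: bp agrees with an independent direct MLS
  # evaluation at the same query
  set.seed(6)
  u <- matrix(rnorm(3 * n, sd = 1e-4), n, 3)
  st2 <- reconstruct_boundary_positions(iface, u)
  for (s in c(1L, nrow(iface$pairs))) {
    kP <- (iface$supP$ptr[s] + 1):iface$supP$ptr[s + 1]
    idx <- iface$supP$idx[kP]
    # oracle weights at the rest geometry, applied to displaced positions
    q <- as.numeric(unlist(iface$pairs[s, c("x", "y", "z")]))
    dmax <- max(sqrt(colSums((t(fx$mesh$nodes[idx, ]) - q)^2)))
    phi <- mls_weights_oracle(q, fx$mesh$nodes[idx, , drop = FALSE],
                              radius = unname(attr_radius(iface, s)))
    bp_oracle <- q + colSums(phi * u[idx, , drop = FALSE])
    expect_equal(c(st2$bp_x[s], st2$bp_y[s], st2$bp_z[s]), bp_oracle,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("penalty forces follow f = -k delta with per-kind coefficients", {
  params <- coupling_params(600, 500)
  st <- tibble::tibble(pair = 1:2, kind = c("tumor", "vessel"),
                       dx = c(1e-3, 1e-3), dy = 0, dz = 0,
                       gap = 1e-3)
  f <- compute_coupling_forces(st, params)
  expect_equal(f$fx, c(-0.6, -0.5), tolerance = 1e-12)
  expect_equal(f$fy, c(0, 0))
  # zero gap, zero force
  st0 <- st; st0$dx <- 0; st0$gap <- 0
  expect_equal(compute_coupling_forces(st0, params)$fx, c(0, 0))
})

test_that("force distribution is balanced and preserves the pair total", {
  fx <- tumor_fixture()
  iface <- fx$model$interface
  n <- nrow(fx$mesh$nodes)
  npair <- nrow(iface$pairs)
  expect_equal(distribute_forces(iface, matrix(0, npair, 3), n),
               matrix(0, n, 3))
  # a single loaded pair deposits exactly its force on each side
  pf <- matrix(0, npair, 3); pf[1, ] <- c(0.3, -0.1, 0.2)
  field <- distribute_forces(iface, pf, n)
  kP <- (iface$supP$ptr[1] + 1):iface$supP$ptr[2]
  expect_equal(colSums(field[iface$supP$idx[kP], , drop = FALSE]), pf[1, ],
               tolerance = 1e-12)
  # action-reaction: the grand total is zero
  set.seed(8)
  pf2 <- matrix(rnorm(3 * npair), npair, 3)
  field2 <- distribute_forces(iface, pf2, n)
  expect_lt(max(abs(colSums(field2))), 1e-12 * max(abs(pf2)) * npair)
})

test_that("equilibrium gaps shrink monotonically with stiffer coupling", {
  fx <- tumor_fixture()
  scen <- block_scenario(fx$mesh, magnitude = 2e-3)
  gaps <- sapply(c(100, 1000), function(k) {
    st <- simulate_heterogeneous(fx$model, scen, coupling_params(k, k))
    max(reconstruct_boundary_positions(fx$model$interface, st$u)$gap)
  })
  expect_lt(gaps[2], gaps[1])
})

test_that("the Signorini report bounds gaps by force/k at equilibrium", {
  fx <- tumor_fixture()
  scen <- block_scenario(fx$mesh, magnitude = 2e-3)
  params <- coupling_params(600, 600)
  st <- simulate_heterogeneous(fx$model, scen, params)
  ist <- compute_coupling_forces(
    reconstruct_boundary_positions(fx$model$interface, st$u), params)
  # Eq. 2 ties force and gap exactly: |f.delta| = k |delta|^2
  expect_equal(abs(ist$fx * ist$dx + ist$fy * ist$dy + ist$fz * ist$dz),
               600 * ist$gap^2, tolerance = 1e-10)
  expect_lte(max(ist$gap), max(ist$f) / 600 + 1e-12)
  rep <- verify_signorini(ist, params, tol = 600 * max(ist$gap)^2 * 1.01,
                          gap_max = max(ist$gap) * 1.01)
  expect_true(attr(rep, "all_pass"))
  # a pair beyond gap_max is flagged
  rep2 <- verify_signorini(ist, params, tol = Inf, gap_max = max(ist$gap) / 2)
  expect_false(attr(rep2, "all_pass"))
})

test_that("with identical materials and stiff coupling the split model matches a direct mesh", {
  # the split formulation reconstructs interface vertices by one-sided MLS,
  # a consistent (h^2) approximation; the agreement with the unsplit mesh is
  # checked at a resolution where that discretization error is below 2%
  vol <- embedded_tumor_volume(21, 9, spacing_mm = 35 / 21)
  cfg <- test_config()
  cfg$materials$tumor <- cfg$materials$parenchyma
  cfg$materials$vessel <- cfg$materials$parenchyma
  cfg$solver$ramp_steps <- 3000L
  cfg$solver$dt_safety <- 0.15
  mesh <- build_hex_mesh(vol)
  split <- deformable_model(mesh, cfg, coupling = "split")
  direct <- deformable_model(mesh, cfg, coupling = "direct")
  scen <- block_scenario(mesh, magnitude = 1.5e-3)
  params <- coupling_params(2e4, 2e4)
  st_s <- simulate_heterogeneous(split, scen, params)
  st_d <- simulate_heterogeneous(direct, scen, params)
  # compare interior master displacements
  masters <- setdiff(seq_len(nrow(mesh$nodes)), split$interface$pairs$node)
  err <- max(abs(st_s$u[masters, ] - st_d$u[masters, ]))
  expect_lt(err / max(abs(st_d$u)), 0.02)
})
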
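#' Lame parameters from Young's modulus and Poisson's ratio
#'
#' mu = E / (2(1+nu)), lambda = E nu / ((1+nu)(1-2nu)). The incompressible
#' limit nu = 0.5 is rejected: the compressible Neo-Hookean strain energy
#' used by the solver has no finite lambda there.
#'
#' @param E Young's modulus (Pa), > 0
#' @param nu Poisson's ratio in [0, 0.5)
#' @return list with elements \code{mu} and \code{lambda} (Pa)
#' @export
lame_from_youngs <- function(E, nu) {
  if (any(E <= 0)) stopf("Young's modulus must be > 0")
  if (any(nu < 0) || any(nu >= 0.5))
    stopf("Poisson's ratio must lie in [0, 0.5); nu = 0.5 (incompressible) is unsupported")
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

material_for_label <- function(label, config) {
  nm <- label_name(label)
  m <- config$materials[[nm]]
  if (is.null(m)) stopf("no material defined for label %d (%s)", label, nm)
  m
}

# rest-configuration shape-function derivatives for an axis-aligned hex of
# edge lengths `spacing`; stacked (8*nq) x 3, with volume-carrying weights
hex_shape_derivatives <- function(spacing, quadrature = c("reduced", "full")) {
  quadrature <- match.arg(quadrature)
  s <- 2 * VTK_CORNERS - 1               # node signs in natural coords
  V <- prod(spacing)
  gp <- if (quadrature == "reduced") matrix(0, 1, 3)
        else as.matrix(expand.grid(x = c(-1, 1) / sqrt(3),
                                   y = c(-1, 1) / sqrt(3),
                                   z = c(-1, 1) / sqrt(3)))
  nq <- nrow(gp)
  dhdX <- matrix(0, 8L * nq, 3L)
  for (q in seq_len(nq)) {
    g <- as.numeric(gp[q, ])
    for (a in 1:8) {
      dhdX[8 * (q - 1) + a, ] <- c(
        s[a, 1] * (1 + g[2] * s[a, 2]) * (1 + g[3] * s[a, 3]) / (4 * spacing[1]),
        s[a, 2] * (1 + g[1] * s[a, 1]) * (1 + g[3] * s[a, 3]) / (4 * spacing[2]),
        s[a, 3] * (1 + g[1] * s[a, 1]) * (1 + g[2] * s[a, 2]) / (4 * spacing[3]))
    }
  }
  list(dhdX = dhdX, qw = rep(V / nq, nq), nq = nq)
}

#' Precompute the total-Lagrangian element quantities
#'
#' Assembles everything the explicit loop reuses every step: the
#' rest-configuration shape-function derivatives at the quadrature points
#' (identical for every element of a uniform grid), per-element Lame
#' parameters, the lumped nodal mass vector, and the hourglass stiffness
#' (only with reduced one-point quadrature, where four zero-energy modes per
#' element need stabilizing).
#'
#' @param mesh a \code{hex_mesh}
#' @param config a [default_config()] list; \code{config$solver$quadrature}
#'   selects "reduced" (one-point + hourglass control, the default) or
#'   "full" (8-point Gauss)
#' @return list of class \code{tled_precomp}
#' @export
precompute_tled <- function(mesh, config = default_config()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  E <- nrow(mesh$elements)
  mu_e <- lam_e <- rho_e <- numeric(E)
  for (lab in unique(mesh$element_label)) {
    m <- material_for_label(lab, config)
    lame <- lame_from_youngs(m$E, m$nu)
    sel <- mesh$element_label == lab
    mu_e[sel] <- lame$mu; lam_e[sel] <- lame$lambda; rho_e[sel] <- m$rho
  }
  # selective mass scaling (static analyses only): inflate the density of
  # stiff elements so every element shares the slowest dilatational wave
  # speed, enlarging the stable explicit step. Equilibria are unaffected
  # (mass enters only the transient); disable for true dynamics.
  if (isTRUE(config$solver$mass_scaling)) {
    c2 <- (lam_e + 2 * mu_e) / rho_e
    rho_e <- (lam_e + 2 * mu_e) / min(c2)
  }
  quad <- hex_shape_derivatives(mesh$spacing, config$solver$quadrature)
  V <- prod(mesh$spacing)
  hg_kappa <- if (quad$nq == 1L)
    config$solver$hourglass_coef * mu_e * V^(1 / 3) else numeric(E)
  mass <- numeric(nrow(mesh$nodes))
  share <- rho_e * V / 8
  for (a in 1:8) {
    acc <- tapply(share, mesh$elements[, a], sum)
    mass[as.integer(names(acc))] <- mass[as.integer(names(acc))] + acc
  }
  structure(list(mesh = mesh, mu_e = mu_e, lam_e = lam_e, rho_e = rho_e,
                 dhdX = quad$dhdX, qw = quad$qw, nq = quad$nq,
                 hg_kappa = hg_kappa, mass = mass,
                 damping = config$solver$damping, config = config),
            class = "tled_precomp")
}

#' Second Piola-Kirchhoff stress of the compressible Neo-Hookean material
#'
#' S = mu (I - C^-1) + lambda ln(J) C^-1 with C = F'F and J = det F, the
#' stress conjugate to Green strain derived from the strain energy
#' W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2.
#'
#' @param F 3 x 3 deformation gradient with det F > 0
#' @param mu,lambda Lame parameters (Pa)
#' @return 3 x 3 stress matrix (Pa)
#' @export
pk2_neo_hookean <- function(F, mu, lambda) {
  F <- matrix(as.numeric(F), 3L, 3L)
  J <- det(F)
  if (J <= 0) stopf("element inversion: det F = %g <= 0", J)
  C <- crossprod(F)
  Ci <- solve(C)
  mu * (diag(3) - Ci) + lambda * log(J) * Ci
}

#' Assembled internal (elastic) nodal forces
#'
#' Total-Lagrangian assembly: at every quadrature point F = I + du/dX, the
#' Neo-Hookean second Piola-Kirchhoff stress, and nodal forces through the
#' precomputed rest-configuration shape derivatives and volumes. The
#' returned vector enters the dynamics as the elastic force term, i.e.
#' M a = R - f_int.
#'
#' @param precomp a \code{tled_precomp}
#' @param displacements N x 3 matrix (m), or length-3N vector
#' @return N x 3 matrix of internal forces (N)
#' @export
internal_forces <- function(precomp, displacements) {
  u <- as_displacement_matrix(displacements, nrow(precomp$mesh$nodes))
  tled_internal_forces_cpp(precomp$mesh$elements - 1L, precomp$mu_e,
                           precomp$lam_e, precomp$dhdX, precomp$qw,
                           precomp$hg_kappa, u, nrow(precomp$mesh$nodes))
}

#' Total strain energy stored in the mesh at a displacement field
#' @inheritParams internal_forces
#' @return scalar energy (J), including the hourglass stabilization energy
#' @export
strain_energy <- function(precomp, displacements) {
  u <- as_displacement_matrix(displacements, nrow(precomp$mesh$nodes))
  tled_strain_energy_cpp(precomp$mesh$elements - 1L, precomp$mu_e,
                         precomp$lam_e, precomp$dhdX, precomp$qw,
                         precomp$hg_kappa, u)
}

as_displacement_matrix <- function(u, n) {
  if (is.null(dim(u))) u <- matrix(u, n, 3L)
  if (nrow(u) != n || ncol(u) != 3L)
    stopf("displacement field must be %d x 3", n)
  u
}

#' Critical explicit time step of a mesh
#'
#' dt = safety * min over elements of (shortest edge / dilatational wave
#' speed), wave speed c = sqrt((lambda + 2 mu)/rho) — the usual CFL bound
#' for explicit central differences.
#'
#' @param mesh a \code{hex_mesh}
#' @param config configuration holding the material table
#' @param safety factor in (0, 1]; defaults to \code{config$solver$dt_safety}
#' @return time step in seconds
#' @export
critical_time_step <- function(mesh, config = default_config(), safety = NULL) {
  safety <- safety %||% config$solver$dt_safety
  if (safety <= 0 || safety > 1) stopf("safety factor must be in (0, 1]")
  dts <- vapply(unique(mesh$element_label), function(lab) {
    m <- material_for_label(lab, config)
    lame <- lame_from_youngs(m$E, m$nu)
    min(mesh$spacing) / sqrt((lame$lambda + 2 * lame$mu) / m$rho)
  }, numeric(1))
  # with selective mass scaling every element shares the slowest wave speed
  safety * if (isTRUE(config$solver$mass_scaling)) max(dts) else min(dts)
}

#' Construct a simulation state
#' @param n_nodes node count
#' @param u,v optional initial displacement / velocity matrices (m, m/s)
#' @return object of class \code{sim_state}
#' @export
sim_state <- function(n_nodes, u = NULL, v = NULL) {
  structure(list(u = u %||% matrix(0, n_nodes, 3L),
                 v = v %||% matrix(0, n_nodes, 3L),
                 ubp = NULL, ubq = NULL,
                 time = 0, steps = 0L, converged = NA),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %d nodes, t = %.4g s (%d steps), converged: %s\n",
              nrow(x$u), x$time, x$steps, x$converged))
  cat(sprintf("  max |u| = %.4g m, max |v| = %.4g m/s\n",
              max(abs(x$u)), max(abs(x$v))))
  invisible(x)
}

empty_interface_args <- function(n_elems) {
  list(slave_node = integer(0),
       supP_ptr = 0L, supP_idx = integer(0), supP_w = numeric(0),
       supQ_ptr = 0L, supQ_idx = integer(0), supQ_w = numeric(0),
       kc = numeric(0),
       elem_slave = matrix(-1L, n_elems, 8L),
       elem_side = integer(n_elems))
}

interface_args <- function(interface, params) {
  if (is.null(interface)) return(NULL)
  kc <- ifelse(interface$pairs$kind == "tumor", params$k_tumor, params$k_vessel)
  list(slave_node = interface$pairs$node - 1L,
       supP_ptr = interface$supP$ptr, supP_idx = interface$supP$idx - 1L,
       supP_w = interface$supP$w,
       supQ_ptr = interface$supQ$ptr, supQ_idx = interface$supQ$idx - 1L,
       supQ_w = interface$supQ$w,
       kc = kc,
       elem_slave = interface$elem_slave, elem_side = interface$elem_side)
}

run_tled <- function(precomp, bc, state = NULL, interface = NULL,
                     params = NULL, external_forces = NULL, dt = NULL,
                     max_steps = NULL, tol = NULL, ramp_steps = NULL,
                     check_convergence = TRUE) {
  mesh <- precomp$mesh
  n <- nrow(mesh$nodes)
  cfg <- precomp$config$solver
  dt <- dt %||% critical_time_step(mesh, precomp$config)
  state <- state %||% sim_state(n)
  f_ext <- external_forces %||% matrix(0, n, 3L)
  f_ext <- as_displacement_matrix(f_ext, n)
  ia <- interface_args(interface, params) %||% empty_interface_args(nrow(mesh$elements))
  free_mask <- rep(1L, n)
  if (length(bc$idx)) free_mask[bc$idx] <- 0L
  if (length(ia$slave_node)) free_mask[ia$slave_node + 1L] <- 0L
  # slaves are massless; keep their (unused) entries positive for safety
  mass <- precomp$mass
  mass[mass <= 0] <- min(mass[mass > 0])
  presc_u <- bc$u %||% matrix(0, 0, 3L)
  if (length(bc$idx) && nrow(presc_u) != length(bc$idx))
    stopf("boundary condition has %d nodes but %d displacement rows",
          length(bc$idx), nrow(presc_u))
  res <- tled_run_cpp(mesh$elements - 1L, precomp$mu_e, precomp$lam_e,
                      precomp$dhdX, precomp$qw, precomp$hg_kappa,
                      mass, free_mask,
                      as.integer(bc$idx %||% integer(0)) - 1L, presc_u,
                      as.integer(ramp_steps %||% cfg$ramp_steps),
                      ia$slave_node,
                      ia$supP_ptr, ia$supP_idx, ia$supP_w,
                      ia$supQ_ptr, ia$supQ_idx, ia$supQ_w, ia$kc,
                      ia$elem_slave, ia$elem_side,
                      state$u, state$v, f_ext,
                      dt, precomp$damping,
                      as.integer(max_steps %||% cfg$max_steps),
                      tol %||% cfg$equilibrium_tol,
                      as.integer(cfg$consec_steps),
                      as.integer(cfg$min_steps %||% 600L), check_convergence)
  out <- sim_state(n, u = res$u, v = res$v)
  out$ubp <- res$ubp; out$ubq <- res$ubq
  out$time <- state$time + res$steps * dt
  out$steps <- state$steps + res$steps
  out$converged <- res$converged
  out$max_velocity <- res$max_velocity
  out
}

#' Advance the explicit dynamics by one (or a few) steps
#'
#' Central-difference update of the lumped-mass equation of motion with
#' mass-proportional damping D = alpha M. Prescribed nodes are set exactly
#' to their boundary values; interface (slave) vertices carry no mass and
#' are excluded from the update.
#'
#' @param precomp a \code{tled_precomp}
#' @param state a \code{sim_state}
#' @param bc list with \code{idx} (node indices) and \code{u} (matrix of
#'   prescribed displacements, m); use \code{idx = integer(0)} for none
#' @param dt time step (s); must not exceed the critical step
#' @param external_forces optional N x 3 force matrix (N)
#' @param n_steps number of steps to take (default 1)
#' @param interface,params optional coupling interface and
#'   \code{coupling_params}
#' @return updated \code{sim_state}
#' @export
advance_step <- function(precomp, state, bc = list(idx = integer(0)), dt,
                         external_forces = NULL, n_steps = 1L,
                         interface = NULL, params = NULL) {
  run_tled(precomp, bc, state = state, interface = interface, params = params,
           external_forces = external_forces, dt = dt, max_steps = n_steps,
           ramp_steps = 1L, check_convergence = FALSE)
}

#' Run the explicit dynamics to static equilibrium
#'
#' Steps the damped dynamics until the largest free-node velocity component
#' stays below \code{tol} for \code{config$solver$consec_steps} consecutive
#' steps (after the boundary-condition ramp), or errors when
#' \code{max_steps} is exhausted, reporting the residual velocity.
#'
#' @inheritParams advance_step
#' @param tol equilibrium velocity tolerance (m/s)
#' @param max_steps step budget
#' @param ramp_steps steps over which prescribed displacements ramp to full
#' @return converged \code{sim_state} (with \code{steps} and
#'   \code{converged} fields)
#' @export
run_to_equilibrium <- function(precomp, bc, state = NULL, tol = NULL,
                               max_steps = NULL, dt = NULL, ramp_steps = NULL,
                               interface = NULL, params = NULL,
                               external_forces = NULL) {
  out <- run_tled(precomp, bc, state = state, interface = interface,
                  params = params, external_forces = external_forces,
                  dt = dt, max_steps = max_steps, tol = tol,
                  ramp_steps = ramp_steps, check_convergence = TRUE)
  if (!isTRUE(out$converged))
    stopf("no equilibrium within %d steps (residual max velocity %.3g m/s)",
          out$steps, out$max_velocity)
  out
}
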
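#' Compression scenario
#'
#' A compression condition: a circular patch on the upper organ surface,
#' a unit push direction, and a displacement magnitude. This mirrors the
#' plate-compression protocol of phantom experiments, where displacements
#' (not forces) are prescribed.
#'
#' @param position integer index of the compression position (patch)
#' @param center length-3 world point (m); only its (x, y) locate the patch
#'   on the top surface
#' @param radius patch radius (m)
#' @param direction length-3 push direction (normalized internally)
#' @param magnitude prescribed displacement magnitude (m), >= 0
#' @return list of class \code{compression_condition}
#' @export
compression_condition <- function(position, center, radius, direction,
                                  magnitude) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stopf("direction must be nonzero")
  if (magnitude < 0) stopf("magnitude must be >= 0")
  structure(list(position = as.integer(position), center = as.numeric(center),
                 radius = as.numeric(radius),
                 direction = as.numeric(direction) / nrm,
                 magnitude = as.numeric(magnitude)),
            class = "compression_condition")
}

#' Boundary conditions realizing a compression scenario
#'
#' Prescribes \code{magnitude * direction} on the surface nodes of the top
#' patch (surface nodes in the upper half of the mesh within the patch
#' radius of the patch axis) and fixes the bottom support band (surface
#' nodes in the lowest 15 percent of the z-extent), emulating the phantom
#' resting in its container while a plate presses from above.
#'
#' @param mesh a \code{hex_mesh}
#' @param scenario a \code{compression_condition}
#' @return list with \code{idx} and \code{u} as consumed by the solver
#' @export
bc_from_scenario <- function(mesh, scenario) {
  surf <- boundary_nodes(mesh)
  z <- mesh$nodes[surf, 3]
  zmid <- (max(z) + min(z)) / 2
  horiz <- sqrt((mesh$nodes[surf, 1] - scenario$center[1])^2 +
                (mesh$nodes[surf, 2] - scenario$center[2])^2)
  patch <- surf[z > zmid & horiz <= scenario$radius]
  if (!length(patch))
    stopf("compression patch at (%.4g, %.4g) captures no surface nodes",
          scenario$center[1], scenario$center[2])
  bottom <- surf[z <= min(z) + 0.15 * (max(z) - min(z))]
  bottom <- setdiff(bottom, patch)
  idx <- c(patch, bottom)
  u <- rbind(matrix(rep(scenario$magnitude * scenario$direction,
                        each = length(patch)), length(patch), 3L),
             matrix(0, length(bottom), 3L))
  list(idx = idx, u = u, patch = patch, fixed = bottom)
}

#' Assemble a deformable registration model from a mesh
#'
#' Bundles the TLED precomputation and, depending on \code{coupling}, the
#' split-vertex interface:
#' \describe{
#'   \item{"split"}{per-tissue materials with the penalty-coupled split
#'     boundary vertices — the full heterogeneous model;}
#'   \item{"direct"}{per-tissue materials on a directly connected mesh (no
#'     splitting) — used at the coarse resolution;}
#'   \item{"homogeneous"}{parenchyma material everywhere, no interface —
#'     the no-coupling baseline comparator.}
#' }
#'
#' @param mesh a \code{hex_mesh}
#' @param config a [default_config()] list
#' @param coupling one of "split", "direct", "homogeneous"
#' @return list of class \code{deformable_model}
#' @export
deformable_model <- function(mesh, config = default_config(),
                             coupling = c("split", "direct", "homogeneous")) {
  coupling <- match.arg(coupling)
  if (coupling == "homogeneous") {
    par <- config$materials$parenchyma
    config$materials <- list(parenchyma = par, vessel = par, tumor = par)
  }
  interface <- NULL
  if (coupling == "split") {
    interface <- build_interface(mesh, config)
    if (nrow(interface$pairs) == 0L) interface <- NULL
  }
  structure(list(mesh = mesh, config = config, coupling = coupling,
                 precomp = precompute_tled(mesh, config),
                 interface = interface,
                 hash = object_hash(list(mesh, config$materials, coupling))),
            class = "deformable_model")
}

#' Simulate a compression scenario to equilibrium
#'
#' Runs the unified explicit loop of the heterogeneous model: each step
#' reconstructs the split boundary vertices by MLS, applies the penalty
#' coupling forces to both support domains, assembles the TLED internal
#' forces, and advances the damped central-difference update, until the
#' equilibrium criterion is met. For "direct"/"homogeneous" models the
#' coupling stage is absent.
#'
#' @param model a \code{deformable_model}
#' @param scenario a \code{compression_condition}
#' @param params a \code{coupling_params} (ignored without an interface)
#' @param state optional warm-start \code{sim_state}
#' @param ... overrides passed to [run_to_equilibrium()] (tol, max_steps, dt)
#' @return converged \code{sim_state}
#' @export
simulate_heterogeneous <- function(model, scenario, params = coupling_params(),
                                   state = NULL, ramp_steps = NULL, ...) {
  bc <- bc_from_scenario(model$mesh, scenario)
  # a warm-started state is already near its deformed shape: no ramp
  if (is.null(ramp_steps) && !is.null(state)) ramp_steps <- 1L
  run_to_equilibrium(model$precomp, bc, state = state,
                     interface = model$interface, params = params,
                     ramp_steps = ramp_steps, ...)
}

#' Predict landmark positions from a simulated state
#'
#' Interpolates each embedded landmark trilinearly inside its element, with
#' split boundary vertices resolved to the element's own tissue side (bp for
#' parenchyma elements, bq for lesion elements).
#'
#' @param model a \code{deformable_model}
#' @param embedding result of [embed_landmarks()] on the model mesh
#' @param state a \code{sim_state} from [simulate_heterogeneous()]
#' @return a \code{landmark_set} of predicted positions
#' @export
predict_landmarks <- function(model, embedding, state) {
  mesh <- model$mesh
  iface <- model$interface
  pos <- matrix(0, nrow(embedding), 3L)
  for (r in seq_len(nrow(embedding))) {
    e <- embedding$element[r]
    nodesr <- mesh$elements[e, ]
    P <- mesh$nodes[nodesr, , drop = FALSE] + state$u[nodesr, , drop = FALSE]
    if (!is.null(iface)) {
      sl <- iface$elem_slave[e, ]
      for (a in which(sl >= 0L)) {
        s <- sl[a] + 1L
        ub <- if (iface$elem_side[e] == 0L) state$ubp[s, ] else state$ubq[s, ]
        P[a, ] <- mesh$nodes[nodesr[a], ] + ub
      }
    }
    w <- trilinear_weights(embedding$xi[r], embedding$eta[r], embedding$zeta[r])
    pos[r, ] <- colSums(w * P)
  }
  landmark_set(embedding$id, pos[, 1], pos[, 2], pos[, 3], embedding$category)
}

#' Target registration error between predicted and ground-truth landmarks
#'
#' Per-landmark Euclidean distance in millimetres, with means overall, by
#' surface/internal split, and for the internal tumor/vessel categories.
#'
#' @param predicted,truth \code{landmark_set}s with matching ids
#' @return object of class \code{tre_report}: a list with
#'   \code{per_landmark} (tibble) and \code{summary} (tibble)
#' @export
compute_tre <- function(predicted, truth) {
  missing_ids <- setdiff(truth$id, predicted$id)
  extra_ids <- setdiff(predicted$id, truth$id)
  if (length(missing_ids) || length(extra_ids))
    stopf("landmark id mismatch; missing: %s; unmatched: %s",
          paste(missing_ids, collapse = ", ") %0% "none",
          paste(extra_ids, collapse = ", ") %0% "none")
  m <- dplyr::left_join(as_tibble(truth), as_tibble(predicted),
                        by = "id", suffix = c("_true", "_pred"))
  per <- tibble::tibble(
    id = m$id, category = m$category_true,
    group = ifelse(m$category_true == "surface", "surface", "internal"),
    error_mm = sqrt((m$x_pred - m$x_true)^2 + (m$y_pred - m$y_true)^2 +
                    (m$z_pred - m$z_true)^2) * 1e3)
  overall <- tibble::tibble(group = "overall", n = nrow(per),
                            mean_tre_mm = mean(per$error_mm),
                            max_tre_mm = max(per$error_mm))
  by_group <- per %>% group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean_tre_mm = mean(.data$error_mm),
              max_tre_mm = max(.data$error_mm), .groups = "drop")
  by_cat <- per %>% filter(.data$group == "internal") %>%
    group_by(group = .data$category) %>%
    summarise(n = dplyr::n(), mean_tre_mm = mean(.data$error_mm),
              max_tre_mm = max(.data$error_mm), .groups = "drop")
  structure(list(per_landmark = per,
                 summary = dplyr::bind_rows(overall, by_group, by_cat)),
            class = "tre_report")
}

`%0%` <- function(x, alt) if (nchar(x)) x else alt

#' @export
print.tre_report <- function(x, ...) {
  cat("<tre_report>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Estimate the tissue-tissue coupling coefficients from landmark data
#'
#' Data-driven calibration: minimizes the summed squared landmark residual
#' between model-predicted and observed deformed landmark positions over
#' the training scenarios, as a function of (k_tumor, k_vessel). The search
#' is a logarithmic coarse grid over \code{bounds} followed by Nelder-Mead
#' refinement (in log-parameter space) from the best cell; every evaluation
#' is a full forward simulation to equilibrium per training case, warm
#' started from the previous equilibrium of that case.
#'
#' @param model a "split" \code{deformable_model}
#' @param landmarks the rest-state \code{landmark_set} (the undeformed
#'   positions that are pushed through the model)
#' @param training_cases list of cases, each a list with \code{scenario}
#'   (a \code{compression_condition}) and \code{landmarks} (the observed
#'   deformed \code{landmark_set} for that scenario)
#' @param bounds length-2 admissible range for both coefficients (N/m)
#' @param n_grid coarse grid resolution per axis
#' @param refine_maxit Nelder-Mead iteration budget
#' @param verbose print progress
#' @return object of class \code{coupling_fit}: \code{params}
#'   (\code{coupling_params}), \code{objective} (m^2), \code{trace} tibble
#'   of all evaluations, \code{n_evals}
#' @export
estimate_coupling_parameters <- function(model, landmarks, training_cases,
                                         bounds = c(50, 5000), n_grid = 7L,
                                         refine_maxit = 60L, verbose = FALSE) {
  if (!length(training_cases)) stopf("empty training set")
  if (is.null(model$interface))
    stopf("coupling estimation needs a 'split' model with a nonempty interface")
  for (case in training_cases)
    if (!nrow(case$landmarks)) stopf("a training case has no landmarks")
  if (!nrow(landmarks)) stopf("no landmarks to train on")
  embedding <- embed_landmarks(model$mesh, landmarks)
  warm <- vector("list", length(training_cases))
  trace <- list()
  n_fail <- 0L
  objective <- function(k, stage) {
    params <- coupling_params(k[1], k[2])
    total <- 0
    for (ci in seq_along(training_cases)) {
      case <- training_cases[[ci]]
      st <- tryCatch(
        simulate_heterogeneous(model, case$scenario, params,
                               state = warm[[ci]]),
        error = function(e) NULL)
      if (is.null(st)) { n_fail <<- n_fail + 1L; return(Inf) }
      warm[[ci]] <<- st
      pred <- predict_landmarks(model, embedding, st)
      resid <- landmark_matrix(pred) - landmark_matrix(case$landmarks)
      total <- total + sum(resid^2)
    }
    trace[[length(trace) + 1L]] <<-
      tibble::tibble(k_tumor = k[1], k_vessel = k[2], objective = total,
                     stage = stage)
    if (verbose)
      message(sprintf("  %s k = (%.1f, %.1f) -> %.4g", stage, k[1], k[2], total))
    total
  }
  grid_vals <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  grid <- expand.grid(k_tumor = grid_vals, k_vessel = grid_vals)
  obj_grid <- vapply(seq_len(nrow(grid)), function(i)
    objective(as.numeric(grid[i, ]), "grid"), numeric(1))
  if (all(!is.finite(obj_grid)))
    stopf("all forward evaluations failed during the coarse grid search")
  best <- as.numeric(grid[which.min(obj_grid), ])
  penalized <- function(lk) {
    k <- exp(lk)
    if (any(k < bounds[1]) || any(k > bounds[2])) return(1e6 * (1 + sum(lk^2)))
    objective(k, "refine")
  }
  opt <- optim(log(best), penalized, method = "Nelder-Mead",
               control = list(maxit = refine_maxit,
                              reltol = 1e-6,
                              parscale = c(0.3, 0.3)))
  k_hat <- exp(opt$par)
  trace <- dplyr::bind_rows(trace)
  structure(list(params = coupling_params(k_hat[1], k_hat[2]),
                 objective = opt$value, trace = trace,
                 n_evals = nrow(trace), n_failed = n_fail,
                 bounds = bounds, model_hash = model$hash),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> k_tumor = %.1f N/m, k_vessel = %.1f N/m\n",
              x$params$k_tumor, x$params$k_vessel))
  cat(sprintf("  objective %.4g m^2 after %d forward evaluations\n",
              x$objective, x$n_evals))
  invisible(x)
}
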
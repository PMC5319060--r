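#' Tissue-tissue coupling parameters
#'
#' Penalty coefficients (N/m) for the parenchyma-tumor and parenchyma-vessel
#' interfaces. The defaults are the phantom-calibrated values 600 and
#' 500 N/m.
#'
#' @param k_tumor,k_vessel coupling coefficients in N/m, both > 0
#' @return list of class \code{coupling_params}
#' @export
coupling_params <- function(k_tumor = 600, k_vessel = 500) {
  if (k_tumor <= 0 || k_vessel <= 0) stopf("coupling coefficients must be > 0")
  structure(list(k_tumor = k_tumor, k_vessel = k_vessel),
            class = "coupling_params")
}

#' Enumerate the shared parenchyma-lesion boundary vertices of a mesh
#'
#' Every node incident to both a parenchyma element and a lesion (tumor or
#' vessel) element is an internal-surface vertex that the coupled model
#' splits into a pair. This enumeration does not require the lesion to have
#' interior nodes, unlike the full interface construction.
#'
#' @param mesh a \code{hex_mesh}
#' @return tibble with columns pair, node, kind and the rest position
#' @export
enumerate_boundary_pairs <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  n <- nrow(mesh$nodes)
  touches <- matrix(FALSE, n, 3L)
  for (lab in sort(unique(mesh$element_label))) {
    sel <- unique(as.vector(mesh$elements[mesh$element_label == lab, ]))
    touches[sel, lab] <- TRUE
  }
  slaves <- which(touches[, LABEL_PARENCHYMA] &
                  (touches[, LABEL_VESSEL] | touches[, LABEL_TUMOR]))
  tibble::tibble(pair = seq_along(slaves), node = slaves,
                 kind = ifelse(touches[slaves, LABEL_TUMOR], "tumor", "vessel"),
                 x = mesh$nodes[slaves, 1], y = mesh$nodes[slaves, 2],
                 z = mesh$nodes[slaves, 3])
}

#' Build the split-vertex coupling interface of a heterogeneous mesh
#'
#' Every node shared by a parenchyma element and a lesion (tumor/vessel)
#' element is split into a parenchyma-side copy bp and a lesion-side copy
#' bq. Each copy is reconstructed by MLS from its own tissue's non-boundary
#' nodes within the support radius (grown when needed), so the two support
#' domains of a pair are disjoint node sets. Split nodes are flagged as
#' massless slaves for the solver: they are never time-integrated, and any
#' element force landing on them is redistributed to their support nodes by
#' the transposed shape weights.
#'
#' @param mesh a \code{hex_mesh} with at least two distinct tissue labels
#' @param config configuration (MLS radius factor, node counts)
#' @return list of class \code{coupling_interface}: \code{pairs} tibble
#'   (pair, node, kind, rest position), CSR support-domain weights for both
#'   sides, and the element-side tables the solver consumes
#' @export
build_interface <- function(mesh, config = default_config()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  labs <- sort(unique(mesh$element_label))
  if (length(intersect(labs, c(LABEL_TUMOR, LABEL_VESSEL))) == 0L ||
      !(LABEL_PARENCHYMA %in% labs)) {
    # homogeneous (or lesion-free) mesh: empty interface
    return(structure(list(
      pairs = tibble::tibble(pair = integer(0), node = integer(0),
                             kind = character(0), x = numeric(0),
                             y = numeric(0), z = numeric(0)),
      supP = list(ptr = 0L, idx = integer(0), w = numeric(0)),
      supQ = list(ptr = 0L, idx = integer(0), w = numeric(0)),
      elem_slave = matrix(-1L, nrow(mesh$elements), 8L),
      elem_side = integer(nrow(mesh$elements))),
      class = "coupling_interface"))
  }
  n <- nrow(mesh$nodes)
  touches <- matrix(FALSE, n, 3L)  # node touches parenchyma / vessel / tumor
  for (lab in labs) {
    sel <- unique(as.vector(mesh$elements[mesh$element_label == lab, ]))
    touches[sel, lab] <- TRUE
  }
  is_lesion_node <- touches[, LABEL_VESSEL] | touches[, LABEL_TUMOR]
  is_boundary <- touches[, LABEL_PARENCHYMA] & is_lesion_node
  slaves <- which(is_boundary)
  if (!length(slaves))
    stopf("mesh has multiple labels but no shared parenchyma-lesion vertices")
  masters_p <- which(touches[, LABEL_PARENCHYMA] & !is_boundary)
  masters_t <- which(touches[, LABEL_TUMOR] & !is_boundary &
                     !touches[, LABEL_PARENCHYMA])
  masters_v <- which(touches[, LABEL_VESSEL] & !is_boundary &
                     !touches[, LABEL_PARENCHYMA])
  kind <- ifelse(touches[slaves, LABEL_TUMOR], "tumor", "vessel")
  radius <- config$mls$radius_factor * max(mesh$spacing)
  build_side <- function(node, candidates) {
    if (!length(candidates))
      stopf("boundary vertex %d has no same-tissue interior support nodes", node)
    # keep the support local: the nearest `target_nodes` candidates, extended
    # one node at a time while the set is coplanar (the radius-growth
    # fallback of build_support_domain still applies on top)
    d <- sqrt(colSums((t(mesh$nodes[candidates, , drop = FALSE]) -
                       mesh$nodes[node, ])^2))
    ord <- order(d)
    k <- min(config$mls$target_nodes, length(candidates))
    while (k < length(candidates) &&
           coplanar(mesh$nodes[candidates[ord[seq_len(k)]], , drop = FALSE]))
      k <- k + 1L
    near <- candidates[ord[seq_len(k)]]
    min_req <- max(config$mls$min_nodes, min(config$mls$target_nodes, k))
    dom <- build_support_domain(mesh$nodes[node, ],
                                mesh$nodes[near, , drop = FALSE],
                                max(radius, 1.05 * d[ord[k]]),
                                min_nodes = min_req,
                                candidate_idx = near,
                                growth_factor = config$mls$growth_factor,
                                max_growth = config$mls$max_growth)
    compute_shape_functions(dom)
  }
  supP_idx <- supQ_idx <- list(); supP_w <- supQ_w <- list()
  for (s in seq_along(slaves)) {
    node <- slaves[s]
    sp <- build_side(node, masters_p)
    sq <- build_side(node, if (kind[s] == "tumor") masters_t else masters_v)
    supP_idx[[s]] <- sp$idx; supP_w[[s]] <- sp$phi
    supQ_idx[[s]] <- sq$idx; supQ_w[[s]] <- sq$phi
  }
  slave_of <- integer(n); slave_of[slaves] <- seq_along(slaves)
  elem_slave <- matrix(slave_of[mesh$elements], nrow(mesh$elements), 8L) - 1L
  elem_side <- as.integer(mesh$element_label != LABEL_PARENCHYMA)
  structure(list(
    pairs = tibble::tibble(pair = seq_along(slaves), node = slaves,
                           kind = kind, x = mesh$nodes[slaves, 1],
                           y = mesh$nodes[slaves, 2], z = mesh$nodes[slaves, 3]),
    supP = list(ptr = c(0L, cumsum(lengths(supP_idx))),
                idx = unlist(supP_idx), w = unlist(supP_w)),
    supQ = list(ptr = c(0L, cumsum(lengths(supQ_idx))),
                idx = unlist(supQ_idx), w = unlist(supQ_w)),
    elem_slave = elem_slave, elem_side = elem_side),
    class = "coupling_interface")
}

#' @export
print.coupling_interface <- function(x, ...) {
  cat(sprintf("<coupling_interface> %d split boundary pairs (%d tumor, %d vessel)\n",
              nrow(x$pairs), sum(x$pairs$kind == "tumor"),
              sum(x$pairs$kind == "vessel")))
  invisible(x)
}

side_positions <- function(interface, side, u, rest) {
  sup <- if (side == "p") interface$supP else interface$supQ
  npair <- nrow(interface$pairs)
  out <- matrix(0, npair, 3L)
  for (s in seq_len(npair)) {
    k <- (sup$ptr[s] + 1L):sup$ptr[s + 1L]
    out[s, ] <- rest[s, ] + colSums(sup$w[k] * u[sup$idx[k], , drop = FALSE])
  }
  out
}

#' Reconstruct split boundary-vertex positions from a displacement field
#'
#' bp = Phi_p . P and bq = Phi_q . Q with the fixed rest-geometry MLS
#' weights applied to the current support-node positions; the gap is
#' delta = bp - bq. At rest (and under any rigid translation) delta = 0 by
#' linear reproduction.
#'
#' @param interface a \code{coupling_interface}
#' @param displacements N x 3 nodal displacement matrix (m), or a
#'   \code{sim_state}
#' @return tibble of class \code{interface_state}: pair, kind, bp/bq
#'   positions, gap components and magnitude
#' @export
reconstruct_boundary_positions <- function(interface, displacements) {
  if (inherits(displacements, "sim_state")) displacements <- displacements$u
  rest <- as.matrix(interface$pairs[, c("x", "y", "z")])
  bp <- side_positions(interface, "p", displacements, rest)
  bq <- side_positions(interface, "q", displacements, rest)
  d <- bp - bq
  out <- tibble::tibble(pair = interface$pairs$pair,
                        kind = interface$pairs$kind,
                        bp_x = bp[, 1], bp_y = bp[, 2], bp_z = bp[, 3],
                        bq_x = bq[, 1], bq_y = bq[, 2], bq_z = bq[, 3],
                        dx = d[, 1], dy = d[, 2], dz = d[, 3],
                        gap = sqrt(rowSums(d^2)))
  class(out) <- c("interface_state", class(out))
  out
}

#' Penalty coupling forces of an interface state
#'
#' The pair force is f = -k_c * delta (N), with k_c chosen per lesion kind.
#' It acts on the parenchyma side; the lesion side receives -f
#' (action-reaction), so the penalty always closes the gap.
#'
#' @param interface_state result of [reconstruct_boundary_positions()]
#' @param params a \code{coupling_params}
#' @return the state tibble with force columns fx, fy, fz and magnitude f
#' @export
compute_coupling_forces <- function(interface_state, params) {
  kc <- ifelse(interface_state$kind == "tumor", params$k_tumor, params$k_vessel)
  out <- interface_state
  out$fx <- -kc * out$dx
  out$fy <- -kc * out$dy
  out$fz <- -kc * out$dz
  out$f <- sqrt(out$fx^2 + out$fy^2 + out$fz^2)
  out
}

#' Distribute pair coupling forces to the support-domain nodes
#'
#' Each pair's force is spread over its two MLS support domains with the
#' shape-function weights: the parenchyma-side nodes receive the pair force
#' f, the lesion-side nodes receive -f. Because each side's weights sum to
#' one, the total over all nodes is exactly zero (action-reaction).
#'
#' @param interface a \code{coupling_interface}
#' @param pair_forces matrix (pairs x 3) of pair forces, or the tibble from
#'   [compute_coupling_forces()] (columns fx, fy, fz)
#' @param n_nodes mesh node count
#' @return N x 3 nodal force field (N)
#' @export
distribute_forces <- function(interface, pair_forces, n_nodes) {
  if (is.data.frame(pair_forces))
    pair_forces <- as.matrix(pair_forces[, c("fx", "fy", "fz")])
  f <- matrix(0, n_nodes, 3L)
  for (s in seq_len(nrow(interface$pairs))) {
    kP <- (interface$supP$ptr[s] + 1L):interface$supP$ptr[s + 1L]
    f[interface$supP$idx[kP], ] <- f[interface$supP$idx[kP], , drop = FALSE] +
      interface$supP$w[kP] %o% pair_forces[s, ]
    kQ <- (interface$supQ$ptr[s] + 1L):interface$supQ$ptr[s + 1L]
    f[interface$supQ$idx[kQ], ] <- f[interface$supQ$idx[kQ], , drop = FALSE] -
      interface$supQ$w[kQ] %o% pair_forces[s, ]
  }
  f
}

#' Check the penalty relaxation of the Signorini condition
#'
#' The exact Signorini law (gap and force complementary) can only hold
#' approximately under a penalty coupling, where |f| = k_c |gap| by
#' construction. This report-only check flags pairs whose complementarity
#' residual |f . delta| exceeds \code{tol} or whose gap magnitude exceeds
#' \code{gap_max}, and identifies the worst pair.
#'
#' @param interface_state state with force columns (see
#'   [compute_coupling_forces()])
#' @param params a \code{coupling_params}
#' @param tol complementarity residual bound (N m)
#' @param gap_max admissible gap magnitude (m)
#' @return tibble with per-pair residuals and pass flags; attributes
#'   \code{worst_pair} and \code{all_pass}
#' @export
verify_signorini <- function(interface_state, params, tol = 1e-6,
                             gap_max = 1e-3) {
  st <- if ("fx" %in% names(interface_state)) interface_state
        else compute_coupling_forces(interface_state, params)
  residual <- abs(st$fx * st$dx + st$fy * st$dy + st$fz * st$dz)
  out <- tibble::tibble(pair = st$pair, kind = st$kind, gap = st$gap,
                        force = st$f, residual = residual,
                        pass = residual <= tol & st$gap <= gap_max)
  attr(out, "worst_pair") <- if (nrow(out)) out$pair[which.max(out$residual)] else NA_integer_
  attr(out, "all_pass") <- all(out$pass)
  out
}
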
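#' Uniform hexahedral meshes from labeled voxels
#'
#' The mesh is built by connecting foreground voxels directly: every
#' foreground voxel becomes one 8-node hexahedral element carrying exactly
#' one tissue label, and nodes on shared voxel corners are deduplicated, so
#' face-adjacent elements share exactly four nodes. All elements are
#' axis-aligned boxes with identical edge lengths (the voxel spacing).
#'
#' @name hex_mesh
#' @keywords internal
NULL

grid_node_id <- function(idx, res) {
  # idx: m x 3 matrix of 0-based node grid indices; res: cell counts
  idx[, 1] + (res[1] + 1L) * (idx[, 2] + (res[2] + 1L) * idx[, 3]) + 1
}

# VTK hexahedron corner offsets relative to cell (i,j,k)
VTK_CORNERS <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(1L,1L,0L), c(0L,1L,0L),
                     c(0L,0L,1L), c(1L,0L,1L), c(1L,1L,1L), c(0L,1L,1L))

new_hex_mesh <- function(nodes, elements, element_label, element_cell,
                         resolution, spacing, origin) {
  structure(list(nodes = nodes, elements = elements,
                 element_label = as.integer(element_label),
                 element_cell = element_cell,
                 resolution = as.integer(resolution),
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "hex_mesh")
}

#' Build a uniform hexahedral mesh from a labeled volume
#'
#' One element per foreground voxel, with the voxel's tissue label. If
#' \code{target_resolution} differs from the volume grid, the volume is first
#' resampled to it by per-block foreground-majority voting (ties prefer the
#' lesion label, tumor > vessel > parenchyma), which requires the volume grid
#' to be divisible by the target resolution.
#'
#' @param volume a \code{labeled_volume}
#' @param target_resolution optional integer triple of cell counts
#' @return a \code{hex_mesh}
#' @export
build_hex_mesh <- function(volume, target_resolution = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!is.null(target_resolution)) {
    target_resolution <- as.integer(target_resolution)
    if (any(target_resolution > dim(volume$labels)))
      stopf("target resolution (%s) exceeds the volume grid (%s)",
            paste(target_resolution, collapse = "x"),
            paste(dim(volume$labels), collapse = "x"))
    if (any(target_resolution != dim(volume$labels)))
      volume <- downsample_volume(volume, target_resolution)
  }
  labels <- volume$labels
  res <- dim(labels)
  fg <- which(labels > 0L)
  if (!length(fg)) stopf("volume has no foreground voxels")
  cells <- arrayInd(fg, res) - 1L
  nelem <- nrow(cells)
  corner_gid <- matrix(0, nelem, 8L)
  for (a in 1:8)
    corner_gid[, a] <- grid_node_id(sweep(cells, 2L, VTK_CORNERS[a, ], "+"), res)
  used <- sort(unique(as.vector(corner_gid)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[corner_gid], nelem, 8L)
  g0 <- used - 1
  nxy <- (res[1] + 1L) * (res[2] + 1L)
  k <- g0 %/% nxy
  j <- (g0 - k * nxy) %/% (res[1] + 1L)
  i <- g0 - k * nxy - j * (res[1] + 1L)
  nodes <- cbind(volume$origin[1] + i * volume$spacing[1],
                 volume$origin[2] + j * volume$spacing[2],
                 volume$origin[3] + k * volume$spacing[3])
  new_hex_mesh(nodes, elements, labels[fg], cells, res, volume$spacing,
               volume$origin)
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d elements, grid %s, spacing %s mm\n",
              nrow(x$nodes), nrow(x$elements),
              paste(x$resolution, collapse = "x"),
              paste(signif(x$spacing * 1e3, 4), collapse = " x ")))
  tab <- table(label_name(x$element_label))
  cat("  elements:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# majority foreground label of a count vector over labels 1..3;
# ties prefer the lesion (tumor > vessel > parenchyma)
majority_label <- function(counts) {
  if (sum(counts) == 0L) return(0L)
  mx <- max(counts)
  for (lab in c(3L, 2L, 1L)) if (counts[lab] == mx) return(lab)
}

#' Downsample a labeled volume by per-block foreground-majority voting
#'
#' A coarse voxel is foreground iff its block contains at least one
#' foreground fine voxel; its label is the most frequent foreground label in
#' the block, ties resolved in favor of the lesion (tumor > vessel >
#' parenchyma) so heterogeneity is not voted away.
#'
#' @param volume a \code{labeled_volume}
#' @param target_resolution integer triple dividing the volume grid
#' @return a coarser \code{labeled_volume}
#' @export
downsample_volume <- function(volume, target_resolution) {
  res <- dim(volume$labels)
  target_resolution <- as.integer(target_resolution)
  if (any(res %% target_resolution != 0L))
    stopf("volume grid %s is not divisible by target resolution %s",
          paste(res, collapse = "x"), paste(target_resolution, collapse = "x"))
  b <- res %/% target_resolution
  out <- array(0L, target_resolution)
  counts <- block_label_counts(volume$labels, b)
  for (lab_idx in seq_len(prod(target_resolution)))
    out[lab_idx] <- majority_label(counts[lab_idx, ])
  labeled_volume(out, spacing = volume$spacing * b, origin = volume$origin)
}

# per-block counts of labels 1..3; returns (prod(coarse_res)) x 3 matrix
block_label_counts <- function(labels, b) {
  res <- dim(labels)
  cres <- res %/% b
  idx <- arrayInd(seq_along(labels), res) - 1L
  block <- cbind(idx[, 1] %/% b[1], idx[, 2] %/% b[2], idx[, 3] %/% b[3])
  bid <- block[, 1] + cres[1] * (block[, 2] + cres[2] * block[, 3]) + 1
  counts <- matrix(0L, prod(cres), 3L)
  for (lab in 1:3) {
    t <- tabulate(bid[labels == lab], nbins = prod(cres))
    counts[, lab] <- t
  }
  counts
}

#' Coarsen a hexahedral mesh with the majority-label rule
#'
#' Groups fine cells into blocks; a coarse element exists iff its block
#' contains at least one foreground fine cell, and its tissue label is the
#' majority foreground label in the block (lesion-priority tie-break).
#' Because coarse cell boundaries lie on fine node planes, coarse nodes
#' coincide with fine-grid nodes; the returned correspondence maps each
#' coarse node to the coincident fine-mesh node (NA when the fine mesh
#' retains no node at that grid position).
#'
#' @param fine a \code{hex_mesh}
#' @param coarse_resolution integer triple; must divide the fine resolution
#' @return list with elements \code{mesh} (coarse \code{hex_mesh}) and
#'   \code{correspondence} (integer vector, coarse node -> fine node index)
#' @export
coarsen_mesh <- function(fine, coarse_resolution) {
  stopifnot(inherits(fine, "hex_mesh"))
  coarse_resolution <- as.integer(coarse_resolution)
  if (any(fine$resolution %% coarse_resolution != 0L))
    stopf("fine resolution %s must be divisible by coarse resolution %s",
          paste(fine$resolution, collapse = "x"),
          paste(coarse_resolution, collapse = "x"))
  b <- fine$resolution %/% coarse_resolution
  # reconstruct the fine label grid from the mesh and downsample it
  labels <- array(0L, fine$resolution)
  labels[fine$element_cell[, 1] + 1L +
         fine$resolution[1] * (fine$element_cell[, 2] +
         fine$resolution[2] * fine$element_cell[, 3])] <- fine$element_label
  cvol <- downsample_volume(
    labeled_volume(labels, fine$spacing, fine$origin), coarse_resolution)
  coarse <- build_hex_mesh(cvol)
  # coarse node (I,J,K) sits on fine grid node (I*b1, J*b2, K*b3)
  cg <- round(sweep(sweep(coarse$nodes, 2L, coarse$origin, "-"),
                    2L, coarse$spacing, "/"))
  fine_gid <- grid_node_id(cg * rep(b, each = nrow(cg)), fine$resolution)
  fine_used <- grid_node_id(round(sweep(sweep(fine$nodes, 2L, fine$origin, "-"),
                                        2L, fine$spacing, "/")), fine$resolution)
  correspondence <- match(fine_gid, fine_used)
  list(mesh = coarse, correspondence = as.integer(correspondence))
}

trilinear_weights <- function(xi, eta, zeta) {
  s <- 2 * VTK_CORNERS - 1  # natural-coordinate signs per corner
  (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
}

#' Embed landmarks into a hexahedral mesh
#'
#' Locates each landmark's containing element (axis-aligned box containment
#' with 1e-9 m tolerance) and computes its trilinear natural coordinates
#' (xi, eta, zeta) in [-1,1]^3 from the affine inverse of the box map, so
#' that trilinear interpolation of the 8 element nodes reproduces the
#' landmark position.
#'
#' @param mesh a \code{hex_mesh}
#' @param landmarks a \code{landmark_set}
#' @return a tibble with columns id, category, element, xi, eta, zeta
#' @export
embed_landmarks <- function(mesh, landmarks) {
  stopifnot(inherits(mesh, "hex_mesh"))
  cell_key <- mesh$element_cell[, 1] + mesh$resolution[1] *
    (mesh$element_cell[, 2] + mesh$resolution[2] * mesh$element_cell[, 3])
  elem_of <- integer(prod(mesh$resolution))
  elem_of[cell_key + 1] <- seq_len(nrow(mesh$elements))
  tol <- 1e-9 / min(mesh$spacing)  # 1e-9 m expressed in cell units
  n <- nrow(landmarks)
  element <- integer(n); nat <- matrix(0, n, 3L)
  pos <- landmark_matrix(landmarks)
  for (r in seq_len(n)) {
    local <- (pos[r, ] - mesh$origin) / mesh$spacing
    cell <- pmin(pmax(floor(local + tol), 0L), mesh$resolution - 1L)
    # a point on a shared face belongs to the lower cell unless that cell
    # is absent; try the 8 cells the tolerance band could place it in
    found <- 0L
    shifts <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
    for (s in seq_len(nrow(shifts))) {
      cand <- cell - as.integer(shifts[s, ])
      if (any(cand < 0L) || any(cand > mesh$resolution - 1L)) next
      if (all(local >= cand - tol) && all(local <= cand + 1L + tol)) {
        e <- elem_of[cand[1] + mesh$resolution[1] *
                     (cand[2] + mesh$resolution[2] * cand[3]) + 1]
        if (e > 0L) { found <- e; cell <- cand; break }
      }
    }
    if (found == 0L)
      stopf("landmark '%s' lies outside every mesh element", landmarks$id[r])
    element[r] <- found
    nat[r, ] <- pmin(pmax(2 * (local - cell) - 1, -1), 1)
  }
  tibble::tibble(id = landmarks$id, category = landmarks$category,
                 element = element, xi = nat[, 1], eta = nat[, 2],
                 zeta = nat[, 3])
}

#' Interpolate embedded landmark rest positions from the mesh
#'
#' Reconstructs each landmark position by trilinear interpolation of its
#' element's 8 node positions; with the rest mesh this reproduces the
#' original landmark coordinates (the embedding invariant).
#'
#' @param mesh a \code{hex_mesh}
#' @param embedding result of [embed_landmarks()]
#' @param node_positions optional N x 3 matrix of (deformed) node positions;
#'   defaults to the rest nodes
#' @return matrix of landmark positions (m), one row per embedded landmark
#' @export
interpolate_landmarks <- function(mesh, embedding, node_positions = NULL) {
  P <- node_positions %||% mesh$nodes
  out <- matrix(0, nrow(embedding), 3L)
  for (r in seq_len(nrow(embedding))) {
    w <- trilinear_weights(embedding$xi[r], embedding$eta[r], embedding$zeta[r])
    out[r, ] <- colSums(w * P[mesh$elements[embedding$element[r], ], ])
  }
  rownames(out) <- embedding$id
  out
}

#' Boundary (surface) nodes of a hexahedral mesh
#'
#' A node is on the mesh surface iff at least one of its up-to-8 incident
#' grid cells is not a foreground element.
#'
#' @param mesh a \code{hex_mesh}
#' @return integer vector of node indices
#' @export
boundary_nodes <- function(mesh) {
  occ <- array(FALSE, mesh$resolution)
  occ[mesh$element_cell[, 1] + 1L + mesh$resolution[1] *
      (mesh$element_cell[, 2] + mesh$resolution[2] * mesh$element_cell[, 3])] <- TRUE
  gidx <- round(sweep(sweep(mesh$nodes, 2L, mesh$origin, "-"),
                      2L, mesh$spacing, "/"))
  is_surface <- vapply(seq_len(nrow(gidx)), function(r) {
    g <- gidx[r, ]
    for (dz in -1:0) for (dy in -1:0) for (dx in -1:0) {
      c <- g + c(dx, dy, dz)
      if (any(c < 0L) || any(c > mesh$resolution - 1L)) return(TRUE)
      if (!occ[c[1] + 1L + mesh$resolution[1] * (c[2] + mesh$resolution[2] * c[3])])
        return(TRUE)
    }
    FALSE
  }, logical(1))
  which(is_surface)
}

# --- VTK legacy ASCII unstructured grid ------------------------------------

#' Export a hexahedral mesh as a legacy-ASCII VTK unstructured grid
#'
#' Cells are written in VTK hexahedron node ordering with a per-cell integer
#' tissue-label field. When a simulation state is given, point coordinates
#' are rest position + displacement and a per-point displacement vector
#' field is included.
#'
#' @param mesh a \code{hex_mesh}
#' @param path destination .vtk path
#' @param state optional \code{sim_state} whose displacement count matches
#'   the mesh node count
#' @return \code{path}, invisibly
#' @export
export_mesh <- function(mesh, path, state = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  u <- matrix(0, nrow(mesh$nodes), 3L)
  if (!is.null(state)) {
    if (nrow(state$u) != nrow(mesh$nodes))
      stopf("state has %d displacements but the mesh has %d nodes",
            nrow(state$u), nrow(mesh$nodes))
    u <- state$u
  }
  pts <- mesh$nodes + u
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(pts); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "tledreg hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(apply(pts, 1L, function(p) paste(sprintf("%.12g", p), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9L), con)
  writeLines(apply(mesh$elements - 1L, 1L, function(e)
    paste(c(8L, e), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$element_label), con)
  if (!is.null(state)) {
    writeLines(c(sprintf("POINT_DATA %d", nn),
                 "VECTORS displacement double"), con)
    writeLines(apply(u, 1L, function(p) paste(sprintf("%.12g", p), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a legacy-ASCII VTK unstructured grid written by [export_mesh()]
#'
#' Restores node positions, hexahedral connectivity and the per-cell label
#' field. Grid metadata (resolution, spacing, origin) is reconstructed from
#' the node lattice.
#'
#' @param path .vtk file path
#' @return a \code{hex_mesh}
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ppos <- grep("^POINTS", lines)[1]
  nn <- as.integer(strsplit(lines[ppos], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ppos + 1):(ppos + nn)], quiet = TRUE),
                  nn, 3L, byrow = TRUE)
  cpos <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[cpos], "\\s+")[[1]][2])
  cells <- matrix(scan(text = lines[(cpos + 1):(cpos + ne)], quiet = TRUE),
                  ne, 9L, byrow = TRUE)
  elements <- cells[, 2:9, drop = FALSE] + 1L
  lpos <- grep("^LOOKUP_TABLE", lines)[1]
  labels <- as.integer(scan(text = lines[(lpos + 1):(lpos + ne)], quiet = TRUE))
  spacing <- nodes[elements[1, 7], ] - nodes[elements[1, 1], ]
  origin <- apply(nodes, 2L, min)
  cell0 <- nodes[elements[, 1], , drop = FALSE]
  cellidx <- round(sweep(sweep(cell0, 2L, origin, "-"), 2L, spacing, "/"))
  resolution <- apply(cellidx, 2L, max) + 1L
  new_hex_mesh(nodes, matrix(as.integer(elements), ne, 8L), labels,
               matrix(as.integer(cellidx), ne, 3L), resolution, spacing, origin)
}
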
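#' Fine-vertex bookkeeping for the detail-enrichment database
#'
#' Every fine-mesh vertex becomes one database entry — split boundary
#' vertices become two (a parenchyma-side and a lesion-side entry), since
#' the two sides deform differently. Each entry is assigned to one coarse
#' element by rest position: the coarse block containing the vertex's
#' incident fine cells, lowest coarse element id on shared-face ties.
#'
#' @noRd
enrichment_entries <- function(fine_mesh, fine_interface, coarse_mesh) {
  b <- fine_mesh$resolution %/% coarse_mesh$resolution
  cres <- coarse_mesh$resolution
  coarse_of_cell <- integer(prod(cres))
  ckey <- coarse_mesh$element_cell[, 1] + cres[1] *
    (coarse_mesh$element_cell[, 2] + cres[2] * coarse_mesh$element_cell[, 3])
  coarse_of_cell[ckey + 1L] <- seq_len(nrow(coarse_mesh$elements))
  # lowest incident coarse element per fine node
  n <- nrow(fine_mesh$nodes)
  assign_elem <- rep(NA_integer_, n)
  fcells <- fine_mesh$element_cell
  ccell <- cbind(fcells[, 1] %/% b[1], fcells[, 2] %/% b[2], fcells[, 3] %/% b[3])
  ce <- coarse_of_cell[ccell[, 1] + cres[1] * (ccell[, 2] + cres[2] * ccell[, 3]) + 1L]
  for (a in 1:8) {
    nd <- fine_mesh$elements[, a]
    take <- is.na(assign_elem[nd]) | ce < assign_elem[nd]
    assign_elem[nd[take]] <- ce[take]
  }
  slaves <- fine_interface$pairs$node %||% integer(0)
  side <- rep("m", n)
  entries <- tibble::tibble(node = seq_len(n), side = side,
                            coarse_element = assign_elem)
  if (length(slaves)) {
    entries$side[slaves] <- "p"
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      node = slaves, side = "q", coarse_element = assign_elem[slaves]))
  }
  entries
}

# deformed positions of the database entries from a fine sim_state
entry_positions <- function(fine_mesh, entries, state) {
  pos <- fine_mesh$nodes + state$u
  out <- pos[entries$node, , drop = FALSE]
  pq <- entries$side != "m"
  if (any(pq)) {
    # rows appended for slave sides: state$ubp/ubq are ordered by pair
    slaves <- entries$node[entries$side == "q"]
    pair_of <- match(entries$node[pq], slaves)
    is_q <- entries$side[pq] == "q"
    rest <- fine_mesh$nodes[entries$node[pq], , drop = FALSE]
    upq <- matrix(0, sum(pq), 3L)
    upq[!is_q, ] <- state$ubp[pair_of[!is_q], , drop = FALSE]
    upq[is_q, ] <- state$ubq[pair_of[is_q], , drop = FALSE]
    out[pq, ] <- rest + upq
  }
  out
}

#' Fit the 8-vertex MLS shape set of one fine vertex (detail enrichment)
#'
#' MLS weights over exactly the 8 (deformed) vertices of the assigned
#' coarse element, linear basis, cubic-spline kernel, evaluated at the fine
#' vertex's deformed position. By linear reproduction, applying the weights
#' to the fit-time vertex positions returns the fine position exactly, so
#' the stored database is self-consistent to round-off.
#'
#' @param fine_position length-3 deformed fine-vertex position (m)
#' @param coarse_vertices 8 x 3 matrix of deformed coarse element vertices
#' @return numeric length-8 weight vector summing to 1
#' @export
fit_element_shapefuns <- function(fine_position, coarse_vertices) {
  if (nrow(coarse_vertices) != 8L) stopf("need exactly 8 coarse vertices")
  d <- sqrt(colSums((t(coarse_vertices) - fine_position)^2))
  if (min(d) < 1e-9) {
    # a fine vertex sitting on a coarse vertex must follow it exactly under
    # any later deformation, so it gets interpolating (indicator) weights
    w <- numeric(8L)
    w[which.min(d)] <- 1
    return(w)
  }
  dmax <- max(d)
  dom <- tryCatch(
    build_support_domain(fine_position, coarse_vertices, radius = 1.5 * dmax,
                         min_nodes = 8L, max_growth = 0L),
    error = function(e) stopf("collapsed coarse element at the fit point"))
  sf <- compute_shape_functions(dom)
  phi <- numeric(8L)
  phi[sf$idx] <- sf$phi
  phi
}

#' Build the detail-enrichment database
#'
#' For every compression condition, runs the fine (split heterogeneous) and
#' coarse (direct multi-material) models to equilibrium under the same
#' scenario, then fits each fine vertex's MLS shape set over its coarse
#' element's deformed vertices. Conditions whose forward runs fail are
#' skipped with a logged reason; the build errors only if all fail.
#'
#' @param fine_model a "split" \code{deformable_model}
#' @param coarse_model a "direct" \code{deformable_model} on the coarsened
#'   mesh
#' @param conditions list of \code{compression_condition}
#' @param params \code{coupling_params} used by the fine model
#' @param seed recorded in the database provenance
#' @param verbose print progress
#' @return object of class \code{enrichment_db}
#' @export
build_enrichment_database <- function(fine_model, coarse_model, conditions,
                                      params = coupling_params(), seed = 1L,
                                      verbose = FALSE) {
  if (!length(conditions)) stopf("no compression conditions given")
  iface <- fine_model$interface %||%
    list(pairs = tibble::tibble(node = integer(0)))
  entries <- enrichment_entries(fine_model$mesh, iface, coarse_model$mesh)
  records <- list()
  skipped <- character(0)
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    res <- tryCatch({
      fine_st <- simulate_heterogeneous(fine_model, cond, params)
      coarse_st <- simulate_heterogeneous(coarse_model, cond, params)
      fine_pos <- entry_positions(fine_model$mesh, entries, fine_st)
      cpos <- coarse_model$mesh$nodes + coarse_st$u
      W <- matrix(0, nrow(entries), 8L)
      for (r in seq_len(nrow(entries))) {
        P8 <- cpos[coarse_model$mesh$elements[entries$coarse_element[r], ], ,
                   drop = FALSE]
        W[r, ] <- fit_element_shapefuns(fine_pos[r, ], P8)
      }
      list(id = length(records) + 1L, condition = cond, weights = W,
           coarse_u = coarse_st$u, fine_positions = fine_pos)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("condition %d: %s", ci, conditionMessage(res)))
      if (verbose) message("  skipped ", ci, ": ", conditionMessage(res))
      next
    }
    records[[length(records) + 1L]] <- res
    if (verbose) message(sprintf("  stored condition %d/%d", ci, length(conditions)))
  }
  if (!length(records))
    stopf("all %d forward runs failed; first reason: %s",
          length(conditions), skipped[1])
  structure(list(records = records, entries = entries,
                 coarse_elements = coarse_model$mesh$elements,
                 meta = list(fine_hash = fine_model$hash,
                             coarse_hash = coarse_model$hash,
                             params = unclass(params), seed = as.integer(seed),
                             config_hash = object_hash(fine_model$config),
                             skipped = skipped)),
            class = "enrichment_db")
}

#' @export
print.enrichment_db <- function(x, ...) {
  cat(sprintf("<enrichment_db> %d records, %d fine-vertex entries\n",
              length(x$records), nrow(x$entries)))
  invisible(x)
}

condition_distance <- function(a, b, w) {
  ang <- acos(pmin(pmax(sum(a$direction * b$direction), -1), 1))
  w$w_position * sqrt(sum((a$center - b$center)^2)) +
    w$w_angle * ang + w$w_magnitude * abs(a$magnitude - b$magnitude)
}

#' Find the database record nearest to a query condition
#'
#' Condition distance is a weighted sum of patch-centroid distance (m),
#' angle between push directions (rad) and magnitude difference (m);
#' weights come from \code{config$lookup}. Ties break by smaller magnitude
#' difference, then lowest record id.
#'
#' @param db an \code{enrichment_db}
#' @param query a \code{compression_condition}
#' @param weights list with w_position, w_angle, w_magnitude
#' @return the nearest \code{enrichment record} (list), with attribute
#'   \code{distance}
#' @export
lookup_condition <- function(db, query,
                             weights = default_config()$lookup) {
  if (!length(db$records)) stopf("enrichment database is empty")
  d <- vapply(db$records, function(r)
    condition_distance(r$condition, query, weights), numeric(1))
  dmag <- vapply(db$records, function(r)
    abs(r$condition$magnitude - query$magnitude), numeric(1))
  ord <- order(d, dmag, vapply(db$records, `[[`, integer(1), "id"))
  rec <- db$records[[ord[1]]]
  attr(rec, "distance") <- d[ord[1]]
  rec
}

#' Synthesize fine-vertex positions from a coarse state (detail enrichment)
#'
#' Applies the stored per-entry shape sets to the current deformed coarse
#' element vertices: x_j = Phi_j' P_i. At the record's own fit-time coarse
#' state this reproduces the stored fine equilibrium; by partition of unity
#' the synthesis is exactly equivariant under rigid translation of the
#' coarse state.
#'
#' @param db an \code{enrichment_db}
#' @param record a record from [lookup_condition()]
#' @param coarse_state \code{sim_state} of the coarse model (or an N x 3
#'   displacement matrix)
#' @param coarse_mesh the coarse \code{hex_mesh}
#' @return matrix (entries x 3) of synthesized fine positions (m)
#' @export
synthesize_fine <- function(db, record, coarse_state, coarse_mesh) {
  u <- if (inherits(coarse_state, "sim_state")) coarse_state$u else coarse_state
  cpos <- coarse_mesh$nodes + u
  out <- matrix(0, nrow(db$entries), 3L)
  for (r in seq_len(nrow(db$entries))) {
    P8 <- cpos[db$coarse_elements[db$entries$coarse_element[r], ], , drop = FALSE]
    out[r, ] <- record$weights[r, ] %*% P8
  }
  out
}

# per-fine-element nodal positions out of synthesized entry positions
entry_index_tables <- function(db, fine_mesh, fine_interface) {
  n <- nrow(fine_mesh$nodes)
  master_entry <- match(paste(seq_len(n), "m"),
                        paste(db$entries$node, db$entries$side))
  p_entry <- match(paste(seq_len(n), "p"),
                   paste(db$entries$node, db$entries$side))
  q_entry <- match(paste(seq_len(n), "q"),
                   paste(db$entries$node, db$entries$side))
  list(m = master_entry, p = p_entry, q = q_entry)
}

#' Coarse-to-fine registration
#'
#' The runtime path of the coarse-to-fine scheme: deform the coarse model
#' to equilibrium under the scenario, look up the nearest stored condition,
#' synthesize the fine-mesh microstructure from the coarse equilibrium, and
#' interpolate the embedded landmarks from the synthesized fine mesh.
#'
#' @param coarse_model a "direct" \code{deformable_model} (must match the
#'   database's coarse mesh)
#' @param fine_model the "split" fine model the database was built from
#'   (supplies the fine mesh and interface for landmark interpolation)
#' @param db an \code{enrichment_db}
#' @param scenario the query \code{compression_condition}
#' @param landmarks rest-state \code{landmark_set}
#' @param params \code{coupling_params} for the coarse run
#' @param weights condition-distance weights (see [lookup_condition()])
#' @return list of class \code{c2f_result}: predicted \code{landmark_set},
#'   synthesized fine positions, the record used, the coarse state
#' @export
register_coarse_to_fine <- function(coarse_model, fine_model, db, scenario,
                                    landmarks, params = coupling_params(),
                                    weights = default_config()$lookup) {
  if (!identical(db$meta$coarse_hash, coarse_model$hash))
    stopf("database was built against a different coarse mesh/model")
  if (!identical(db$meta$fine_hash, fine_model$hash))
    stopf("database was built against a different fine mesh/model")
  coarse_st <- simulate_heterogeneous(coarse_model, scenario, params)
  rec <- lookup_condition(db, scenario, weights)
  fine_pos <- synthesize_fine(db, rec, coarse_st, coarse_model$mesh)
  embedding <- embed_landmarks(fine_model$mesh, landmarks)
  tab <- entry_index_tables(db, fine_model$mesh, fine_model$interface)
  mesh <- fine_model$mesh
  pred <- matrix(0, nrow(embedding), 3L)
  for (r in seq_len(nrow(embedding))) {
    e <- embedding$element[r]
    nodesr <- mesh$elements[e, ]
    lesion_side <- !is.null(fine_model$interface) &&
      fine_model$interface$elem_side[e] == 1L
    ent <- tab$m[nodesr]
    split_rows <- which(!is.na(tab$p[nodesr]))
    if (length(split_rows)) {
      tabside <- if (lesion_side) tab$q else tab$p
      ent[split_rows] <- tabside[nodesr[split_rows]]
    }
    w <- trilinear_weights(embedding$xi[r], embedding$eta[r], embedding$zeta[r])
    pred[r, ] <- colSums(w * fine_pos[ent, , drop = FALSE])
  }
  predicted <- landmark_set(embedding$id, pred[, 1], pred[, 2], pred[, 3],
                            embedding$category)
  structure(list(predicted = predicted, fine_positions = fine_pos,
                 record = rec, coarse_state = coarse_st,
                 distance = attr(rec, "distance")),
            class = "c2f_result")
}

# --- persistence (single JSON container) -----------------------------------

#' Write an enrichment database to a JSON container
#'
#' One indexed file holding provenance (mesh/config hashes, seed, the
#' generating coupling parameters), the fine-entry table, and every
#' condition record. Shape-set weights are stored at single-precision
#' significance (7 significant digits); positions at full precision.
#'
#' @param db an \code{enrichment_db}
#' @param path destination .json path
#' @return \code{path}, invisibly
#' @export
write_enrichment_db <- function(db, path) {
  ser <- list(
    meta = db$meta,
    entries = as.list(db$entries),
    coarse_elements = db$coarse_elements,
    records = lapply(db$records, function(r) list(
      id = r$id,
      condition = unclass(r$condition),
      weights = signif(r$weights, 7),
      coarse_u = r$coarse_u,
      fine_positions = r$fine_positions)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an enrichment database written by [write_enrichment_db()]
#' @param path .json path
#' @return an \code{enrichment_db}
#' @export
read_enrichment_db <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- lapply(seq_len(nrow(ser$records)), function(i) {
    row <- ser$records[i, ]
    cond <- as.list(row$condition)
    list(id = as.integer(row$id),
         condition = structure(list(position = as.integer(cond$position),
                                    center = as.numeric(cond$center[[1]]),
                                    radius = as.numeric(cond$radius),
                                    direction = as.numeric(cond$direction[[1]]),
                                    magnitude = as.numeric(cond$magnitude)),
                               class = "compression_condition"),
         weights = row$weights[[1]],
         coarse_u = row$coarse_u[[1]],
         fine_positions = row$fine_positions[[1]])
  })
  structure(list(records = recs,
                 entries = tibble::as_tibble(ser$entries),
                 coarse_elements = ser$coarse_elements,
                 meta = ser$meta),
            class = "enrichment_db")
}
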
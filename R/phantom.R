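with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthetic phantom specification
#'
#' Describes a labeled abdominal-phantom stand-in: a parenchyma ellipsoid
#' with an embedded tumor sphere and a vessel tube, plus landmark counts.
#' The default grid (16 x 8 x 12 cells at 5 mm spacing) is sized so the full
#' calibrate/enrich/register loop runs in minutes while keeping every
#' lesion thick enough (>= 3 cells across) for its split-vertex interface to
#' have interior MLS support nodes. Landmark defaults follow the 25-landmark
#' protocol: 11 on the organ surface and 14 internal (split over tumor and
#' vessel boundaries).
#'
#' @param dims integer triple of voxel counts
#' @param spacing_mm voxel edge length (mm)
#' @param ellipsoid list(center, semiaxes) in mm — the parenchyma body
#' @param tumors list of list(center, radius) spheres in mm
#' @param vessel list(from, to, radius) tube in mm
#' @param n_surface,n_tumor,n_vessel landmark counts per category
#' @param seed RNG seed controlling landmark placement
#' @return list of class \code{phantom_spec}
#' @export
phantom_spec <- function(dims = c(16L, 8L, 12L), spacing_mm = 5,
                         ellipsoid = list(center = c(40, 20, 30),
                                          semiaxes = c(37, 18, 28)),
                         tumors = list(list(center = c(26, 20, 22),
                                            radius = 11)),
                         vessel = list(from = c(26, 17.5, 37.5),
                                       to = c(58, 17.5, 37.5), radius = 8),
                         n_surface = 11L, n_tumor = 7L, n_vessel = 7L,
                         seed = 1L) {
  structure(list(dims = as.integer(dims), spacing_mm = spacing_mm,
                 ellipsoid = ellipsoid, tumors = tumors, vessel = vessel,
                 n_surface = as.integer(n_surface),
                 n_tumor = as.integer(n_tumor),
                 n_vessel = as.integer(n_vessel), seed = as.integer(seed)),
            class = "phantom_spec")
}

point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  t <- pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                  (pts[, 3] - a[3]) * ab[3]) / sum(ab^2), 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((pts - proj)^2))
}

#' Generate a labeled phantom volume with landmarks
#'
#' Voxel labels come from analytic membership at voxel centers with
#' precedence tumor > vessel > parenchyma; lesions must lie strictly inside
#' the parenchyma ellipsoid or generation errors. Surface landmarks sample
#' parenchyma boundary voxels; internal landmarks sample tumor and vessel
#' boundary voxels. Fully reproducible from the spec seed.
#'
#' @param spec a [phantom_spec()]
#' @return list with \code{volume} (a \code{labeled_volume}),
#'   \code{landmarks} (a \code{landmark_set}) and \code{counts} (per-label
#'   voxel counts)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  d <- spec$dims
  sp <- spec$spacing_mm
  ctr <- expand.grid(x = (seq_len(d[1]) - 0.5) * sp,
                     y = (seq_len(d[2]) - 0.5) * sp,
                     z = (seq_len(d[3]) - 0.5) * sp)
  ctr <- as.matrix(ctr)
  e <- spec$ellipsoid
  in_par <- rowSums(sweep(sweep(ctr, 2L, e$center), 2L, e$semiaxes, "/")^2) <= 1
  lab <- ifelse(in_par, LABEL_PARENCHYMA, LABEL_BACKGROUND)
  v <- spec$vessel
  if (!is.null(v)) {
    in_ves <- point_segment_distance(ctr, v$from, v$to) <= v$radius
    if (any(in_ves & !in_par))
      stopf("vessel tube escapes the parenchyma ellipsoid")
    lab[in_ves] <- LABEL_VESSEL
  }
  for (tu in spec$tumors) {
    in_tu <- sqrt(rowSums(sweep(ctr, 2L, tu$center)^2)) <= tu$radius
    if (any(in_tu & !in_par))
      stopf("tumor sphere escapes the parenchyma ellipsoid")
    lab[in_tu] <- LABEL_TUMOR
  }
  volume <- labeled_volume(array(as.integer(lab), d), spacing = rep(sp, 3) * 1e-3)
  volume$provenance <- list(seed = spec$seed, spec_hash = object_hash(unclass(spec)))
  landmarks <- with_seed(spec$seed, phantom_landmarks(volume, spec))
  list(volume = volume, landmarks = landmarks, counts = label_counts(volume))
}

# boundary voxels of label `lab` (6-neighborhood against `against` labels)
boundary_voxels <- function(labels, lab, against) {
  d <- dim(labels)
  idx <- which(labels == lab, arr.ind = TRUE)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  on_boundary <- logical(nrow(idx))
  for (s in seq_len(6)) {
    nb <- sweep(idx, 2L, shifts[s, ], "+")
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    val <- rep(LABEL_BACKGROUND, nrow(nb))
    val[!outside] <- labels[nb[!outside, , drop = FALSE]]
    on_boundary <- on_boundary | (val %in% against)
  }
  idx[on_boundary, , drop = FALSE]
}

phantom_landmarks <- function(volume, spec) {
  labels <- volume$labels
  sp <- volume$spacing  # m
  pick <- function(vox, n, what) {
    if (nrow(vox) < n)
      stopf("phantom has only %d %s boundary voxels; %d landmarks requested",
            nrow(vox), what, n)
    vox[sample.int(nrow(vox), n), , drop = FALSE]
  }
  centers <- function(vox) sweep((vox - 0.5), 2L, sp, "*")
  surf <- pick(boundary_voxels(labels, LABEL_PARENCHYMA, LABEL_BACKGROUND),
               spec$n_surface, "surface")
  tum <- pick(boundary_voxels(labels, LABEL_TUMOR, LABEL_PARENCHYMA),
              spec$n_tumor, "tumor")
  ves <- pick(boundary_voxels(labels, LABEL_VESSEL, LABEL_PARENCHYMA),
              spec$n_vessel, "vessel")
  pos <- rbind(centers(surf), centers(tum), centers(ves))
  landmark_set(
    id = c(sprintf("S%02d", seq_len(spec$n_surface)),
           sprintf("T%02d", seq_len(spec$n_tumor)),
           sprintf("V%02d", seq_len(spec$n_vessel))),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    category = c(rep("surface", spec$n_surface),
                 rep("internal-tumor", spec$n_tumor),
                 rep("internal-vessel", spec$n_vessel)))
}

#' Generate a grid of compression scenarios
#'
#' The cross product of compression positions (disjoint patches spaced
#' along the top surface), displacement magnitudes (evenly spaced in
#' \code{magnitude_range}) and push orientations (unit vectors within
#' \code{cone_angle} degrees of straight down; the first orientation is the
#' inward normal itself, further ones are seeded samples in the cone).
#'
#' @param volume the phantom \code{labeled_volume} (locates the top surface)
#' @param n_positions,n_magnitudes,n_orientations grid sizes, all >= 1
#' @param magnitude_range length-2 range of displacement magnitudes (m)
#' @param cone_angle cone half-angle in degrees, < 90
#' @param seed RNG seed for the orientation samples
#' @param patch_radius optional patch radius (m); the default keeps
#'   neighboring patches disjoint
#' @return list of \code{compression_condition}, length = product of counts
#' @export
generate_scenarios <- function(volume, n_positions = 5L, n_magnitudes = 3L,
                               n_orientations = 2L,
                               magnitude_range = c(2e-3, 8e-3),
                               cone_angle = 20, seed = 1L,
                               patch_radius = NULL) {
  if (n_positions < 1 || n_magnitudes < 1 || n_orientations < 1)
    stopf("scenario grid counts must all be >= 1")
  if (cone_angle >= 90) stopf("cone angle must be < 90 degrees")
  labels <- volume$labels
  sp <- volume$spacing
  fg <- which(labels > 0L, arr.ind = TRUE)
  xr <- range((fg[, 1] - 0.5) * sp[1])
  ymid <- mean((range(fg[, 2]) - 0.5) * sp[2])
  zr <- range(fg[, 3] * sp[3])
  margin <- 0.18 * diff(xr)
  cx <- if (n_positions == 1L) mean(xr)
        else seq(xr[1] + margin, xr[2] - margin, length.out = n_positions)
  sep <- if (n_positions > 1L) min(diff(cx)) else Inf
  radius <- patch_radius %||% min(1.6 * max(sp), 0.45 * sep)
  mags <- if (n_magnitudes == 1L) mean(magnitude_range)
          else seq(magnitude_range[1], magnitude_range[2],
                   length.out = n_magnitudes)
  dirs <- with_seed(seed, {
    out <- list(c(0, 0, -1))
    while (length(out) < n_orientations) {
      theta <- runif(1, 0, cone_angle * pi / 180)
      phi <- runif(1, 0, 2 * pi)
      out[[length(out) + 1L]] <-
        c(sin(theta) * cos(phi), sin(theta) * sin(phi), -cos(theta))
    }
    out[seq_len(n_orientations)]
  })
  scenarios <- list()
  for (p in seq_len(n_positions))
    for (m in seq_along(mags))
      for (o in seq_along(dirs))
        scenarios[[length(scenarios) + 1L]] <- compression_condition(
          position = p, center = c(cx[p], ymid, zr[2]), radius = radius,
          direction = dirs[[o]], magnitude = mags[m])
  scenarios
}

#' Generate model-based ground truth for a scenario
#'
#' Stands in for scanned compression datasets: runs the heterogeneous
#' forward model with the true coupling parameters, records the noiseless
#' predicted landmark positions, and adds isotropic Gaussian observation
#' noise of standard deviation \code{sigma} per coordinate.
#'
#' @param model a "split" \code{deformable_model}
#' @param landmarks rest-state \code{landmark_set}
#' @param scenario a \code{compression_condition}
#' @param true_params the generating \code{coupling_params}
#' @param sigma observation noise sd (m); 0 gives observed == predicted
#' @param seed RNG seed for the noise realization
#' @return list of class \code{ground_truth_case}: scenario, predicted,
#'   observed, sigma, seed
#' @export
generate_ground_truth <- function(model, landmarks, scenario,
                                  true_params = coupling_params(),
                                  sigma = 0, seed = 1L) {
  embedding <- embed_landmarks(model$mesh, landmarks)
  st <- simulate_heterogeneous(model, scenario, true_params)
  predicted <- predict_landmarks(model, embedding, st)
  observed <- predicted
  if (sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(3 * nrow(predicted), sd = sigma),
                                    ncol = 3L))
    observed$x <- observed$x + noise[, 1]
    observed$y <- observed$y + noise[, 2]
    observed$z <- observed$z + noise[, 3]
  }
  structure(list(scenario = scenario, predicted = predicted,
                 observed = observed, sigma = sigma, seed = as.integer(seed)),
            class = "ground_truth_case")
}
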
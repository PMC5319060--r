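#' Moving-least-squares shape functions
#'
#' MLS builds meshfree shape functions from a support domain: the nodes
#' within a radius of a query point, weighted by a compactly supported
#' kernel. With a linear basis (1, x, y, z) the resulting weights form a
#' partition of unity and reproduce any affine field exactly — the property
#' the split-vertex coupling and the detail-enrichment synthesis rely on.
#'
#' @name mls
#' @keywords internal
NULL

# cubic-spline weight of normalized distance r in [0, 1]
mls_kernel <- function(r) {
  w <- numeric(length(r))
  a <- r <= 0.5
  w[a] <- 2/3 - 4 * r[a]^2 + 4 * r[a]^3
  b <- r > 0.5 & r <= 1
  w[b] <- 4/3 - 4 * r[b] + 4 * r[b]^2 - (4/3) * r[b]^3
  w
}

#' Build an MLS support domain around a query point
#'
#' Selects the candidate nodes within \code{radius} of the query. If fewer
#' than \code{min_nodes} (or a coplanar set) are captured, the radius grows
#' by \code{growth_factor} up to \code{max_growth} times; the applied growth
#' is recorded in the result.
#'
#' @param query length-3 world point (m)
#' @param candidates n x 3 matrix of candidate node rest positions (m)
#' @param radius initial support radius (m)
#' @param min_nodes minimum admissible node count (must be >= 4 and
#'   non-coplanar for the linear basis)
#' @param candidate_idx optional external indices reported for the selected
#'   nodes (defaults to row numbers of \code{candidates})
#' @param growth_factor,max_growth radius growth schedule
#' @return list of class \code{support_domain}: query, idx, positions,
#'   radius, growths
#' @export
build_support_domain <- function(query, candidates, radius, min_nodes = 4L,
                                 candidate_idx = NULL, growth_factor = 1.3,
                                 max_growth = 5L) {
  if (is.null(dim(candidates))) candidates <- matrix(candidates, ncol = 3L)
  if (nrow(candidates) == 0L) stopf("empty candidate set for support domain")
  candidate_idx <- candidate_idx %||% seq_len(nrow(candidates))
  d <- sqrt(colSums((t(candidates) - query)^2))
  r <- radius
  growths <- 0L
  repeat {
    sel <- which(d <= r)
    if (length(sel) >= min_nodes && !coplanar(candidates[sel, , drop = FALSE]))
      break
    if (growths >= max_growth)
      stopf(paste0("support domain at (%.4g, %.4g, %.4g) still under-determined",
                   " after %d radius growths (%d nodes captured)"),
            query[1], query[2], query[3], growths, length(sel))
    r <- r * growth_factor
    growths <- growths + 1L
  }
  structure(list(query = as.numeric(query), idx = candidate_idx[sel],
                 positions = candidates[sel, , drop = FALSE],
                 radius = r, growths = growths),
            class = "support_domain")
}

coplanar <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 4L) return(TRUE)
  centered <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sv[3] <= tol * max(sv[1], 1e-300)
}

#' Compute MLS shape functions on a support domain
#'
#' Linear basis (1, x, y, z), shifted to the query point for conditioning,
#' with the cubic-spline kernel. The weights satisfy the partition of unity
#' exactly (to round-off) and reproduce affine fields exactly.
#'
#' @param domain a \code{support_domain}
#' @return list of class \code{shape_function_set}: idx, phi
#' @export
compute_shape_functions <- function(domain) {
  stopifnot(inherits(domain, "support_domain"))
  X <- domain$positions
  m <- nrow(X)
  dx <- sweep(X, 2L, domain$query)
  r <- sqrt(rowSums(dx^2)) / domain$radius
  w <- mls_kernel(pmin(r, 1))
  # guard: nodes exactly on the support boundary get zero weight; keep the
  # moment matrix well posed by flooring at a tiny positive value
  w <- pmax(w, 1e-12)
  P <- cbind(1, dx)                      # m x 4 shifted basis
  A <- crossprod(P, w * P)               # 4 x 4 moment matrix
  e1 <- c(1, 0, 0, 0)                    # basis evaluated at the query
  coef <- tryCatch(solve(A, e1), error = function(e)
    stopf("singular MLS moment matrix (support nodes coplanar?); grow the support radius"))
  if (kappa(A) > 1e12)
    stopf("singular MLS moment matrix (support nodes coplanar?); grow the support radius")
  phi <- as.numeric(w * (P %*% coef))
  structure(list(idx = domain$idx, phi = phi), class = "shape_function_set")
}
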
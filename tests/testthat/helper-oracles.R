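# independent oracles, written from scratch against textbook formulations so
# they share no code path with the package implementation

# brute-force MLS weights: weighted least-squares fit of the indicator data
# e_j with a linear polynomial, evaluated at the query (uses lm.wfit, not the
# moment-matrix solve the package uses)
mls_weights_oracle <- function(query, nodes, radius) {
  d <- sqrt(colSums((t(nodes) - query)^2))
  r <- pmin(d / radius, 1)
  w <- ifelse(r <= 0.5, 2 / 3 - 4 * r^2 + 4 * r^3,
              4 / 3 - 4 * r + 4 * r^2 - (4 / 3) * r^3)
  w <- pmax(w, 1e-12)
  X <- cbind(1, nodes)
  m <- nrow(nodes)
  phi <- numeric(m)
  for (j in seq_len(m)) {
    fitj <- lm.wfit(X, as.numeric(seq_len(m) == j), w)
    phi[j] <- sum(c(1, query) * fitj$coefficients)
  }
  phi
}

# small-strain isotropic linear-elastic global stiffness of a uniform hex
# mesh: full 2x2x2 Gauss, engineering-strain B matrices, dense assembly
linear_fem_K <- function(mesh, E, nu) {
  nn <- nrow(mesh$nodes)
  h <- mesh$spacing
  D <- matrix(0, 6, 6)
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- E / (2 * (1 + nu))
  gp <- c(-1, 1) / sqrt(3)
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  sgn <- 2 * corners - 1
  Ke <- matrix(0, 24, 24)
  detJ <- prod(h) / 8
  for (gx in gp) for (gy in gp) for (gz in gp) {
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      dN[a, 1] <- sgn[a, 1] * (1 + gy * sgn[a, 2]) * (1 + gz * sgn[a, 3]) / 8 * 2 / h[1]
      dN[a, 2] <- sgn[a, 2] * (1 + gx * sgn[a, 1]) * (1 + gz * sgn[a, 3]) / 8 * 2 / h[2]
      dN[a, 3] <- sgn[a, 3] * (1 + gx * sgn[a, 1]) * (1 + gy * sgn[a, 2]) / 8 * 2 / h[3]
    }
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    Ke <- Ke + t(B) %*% D %*% B * detJ
  }
  K <- matrix(0, 3 * nn, 3 * nn)
  for (e in seq_len(nrow(mesh$elements))) {
    dofs <- as.vector(t(outer(mesh$elements[e, ], 1:3,
                              function(n, i) 3 * (n - 1) + i)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# static solve under prescribed displacements; bc = list(idx, u)
linear_fem_solve <- function(mesh, E, nu, bc) {
  nn <- nrow(mesh$nodes)
  K <- linear_fem_K(mesh, E, nu)
  u <- rep(0, 3 * nn)
  presc_dofs <- as.vector(t(outer(bc$idx, 1:3, function(n, i) 3 * (n - 1) + i)))
  u[presc_dofs] <- as.vector(t(bc$u))
  free <- setdiff(seq_len(3 * nn), presc_dofs)
  rhs <- -K[free, presc_dofs, drop = FALSE] %*% u[presc_dofs]
  u[free] <- solve(K[free, free], rhs)
  matrix(u, nn, 3, byrow = TRUE)
}

# nodal forces K u of the linear model, for force-level comparisons
linear_fem_forces <- function(mesh, E, nu, u) {
  K <- linear_fem_K(mesh, E, nu)
  matrix(K %*% as.vector(t(u)), nrow(mesh$nodes), 3, byrow = TRUE)
}

# jittered-grid support domain used by the MLS property suites
random_domain <- function(m = 10, jitter = 0.3) {
  base <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  sel <- sample(nrow(base), m)
  nodes <- (base[sel, ] + matrix(runif(3 * m, -jitter, jitter), m, 3)) * 1e-2
  query <- colMeans(nodes) + runif(3, -5e-3, 5e-3)
  radius <- 1.2 * max(sqrt(colSums((t(nodes) - query)^2)))
  build_support_domain(query, nodes, radius, min_nodes = 4)
}

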
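# programmatic fixtures shared across the suite; everything is generated in
# code so the repository carries no binary data

lmm <- function(l) as.matrix(l[, c("x", "y", "z")])

# solid block volume, all parenchyma unless labels overridden
block_volume <- function(dims, spacing_mm = 5, label = 1L) {
  labeled_volume(array(label, dims), spacing = rep(spacing_mm, 3) * 1e-3)
}

# n^3 parenchyma block with a centered t^3 tumor (t >= 3 gives the tumor
# interior MLS support nodes)
embedded_tumor_volume <- function(n = 7L, t = 3L, spacing_mm = 5) {
  labels <- array(1L, c(n, n, n))
  lo <- (n - t) %/% 2 + 1L
  rng <- lo:(lo + t - 1L)
  labels[rng, rng, rng] <- 3L
  labeled_volume(labels, spacing = rep(spacing_mm, 3) * 1e-3)
}

# fast-converging solver settings for small test meshes
test_config <- function(...) {
  cfg <- default_config(...)
  cfg$solver$ramp_steps <- 400L
  cfg$solver$min_steps <- 300L
  cfg
}

# compression straight down onto the block's top face
block_scenario <- function(mesh, magnitude = 2e-3, radius = NULL) {
  ext <- apply(mesh$nodes, 2, range)
  compression_condition(
    position = 1L,
    center = c(mean(ext[, 1]), mean(ext[, 2]), ext[2, 3]),
    radius = radius %||% (0.35 * diff(ext[, 1])),
    direction = c(0, 0, -1), magnitude = magnitude)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the standard small phantom + derived objects, built once per test run
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom()
      mesh <- build_hex_mesh(ph$volume)
      cache <<- list(phantom = ph, mesh = mesh)
    }
    cache
  }
})

# seeded 0.1 mm landmark-noise draws, restoring the global RNG state
with_noise_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(3 * n, sd = 1e-4)
}

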
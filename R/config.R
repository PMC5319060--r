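#' Default configuration
#'
#' Central table of material, solver, MLS and coarse-to-fine settings. The
#' material table follows the phantom's reported properties: Young's moduli
#' of 2e5 Pa (parenchyma), 1e6 Pa (vessel) and 5e6 Pa (tumor) with Poisson's
#' ratio 0.49 for all three. Mass density is not a registration-relevant
#' quantity (only the transient path depends on it, not the equilibrium) and
#' defaults to 1000 kg/m^3.
#'
#' Solver settings: \code{dt_safety} scales the critical explicit time step;
#' \code{damping} is the mass-proportional damping coefficient alpha in 1/s
#' (D = alpha*M); equilibrium is declared when the largest free-node velocity
#' component stays below \code{equilibrium_tol} (m/s) for
#' \code{consec_steps} consecutive steps.
#'
#' @param ... named overrides, e.g. \code{damping = 100}; nested lists
#'   (\code{materials}, \code{coupling}) are replaced wholesale when given
#' @return a named list of class \code{tledreg_config}
#' @export
default_config <- function(...) {
  cfg <- list(
    materials = list(
      parenchyma = list(E = 2e5, nu = 0.49, rho = 1000),
      vessel     = list(E = 1e6, nu = 0.49, rho = 1000),
      tumor      = list(E = 5e6, nu = 0.49, rho = 1000)
    ),
    coupling = list(k_tumor = 600, k_vessel = 500),  # N/m
    solver = list(dt_safety = 0.2, damping = 500, equilibrium_tol = 2e-4,
                  consec_steps = 50, min_steps = 600L,
                  max_steps = 400000L, ramp_steps = 1500L,
                  quadrature = "reduced", hourglass_coef = 0.1,
                  mass_scaling = TRUE),
    mls = list(radius_factor = 1.5, min_nodes = 4L, target_nodes = 8L,
               growth_factor = 1.3, max_growth = 5L),
    lookup = list(w_position = 1.0, w_angle = 0.02, w_magnitude = 1.0),
    resolutions = list(fine = c(16L, 8L, 12L), coarse = c(8L, 4L, 6L)),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
  class(cfg) <- c("tledreg_config", "list")
  cfg
}

validate_config <- function(cfg) {
  for (nm in names(cfg$materials)) {
    m <- cfg$materials[[nm]]
    if (m$E <= 0) stopf("material %s: E must be > 0", nm)
    if (m$nu < 0 || m$nu >= 0.5) stopf("material %s: need 0 <= nu < 0.5", nm)
    if (m$rho <= 0) stopf("material %s: rho must be > 0", nm)
  }
  if (cfg$coupling$k_tumor <= 0 || cfg$coupling$k_vessel <= 0)
    stopf("coupling coefficients must be > 0")
  invisible(cfg)
}

#' Read a configuration file (YAML or JSON), merged over the defaults
#'
#' Keys absent from the file keep their [default_config()] value; top-level
#' sections present in the file are merged key-by-key.
#'
#' @param path path to a .yaml/.yml or .json config
#' @return a \code{tledreg_config}
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- if (grepl("\\.ya?ml$", tolower(path))) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- unclass(default_config())
  for (sec in names(raw)) {
    if (is.list(raw[[sec]]) && is.list(cfg[[sec]])) {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else cfg[[sec]] <- raw[[sec]]
  }
  validate_config(cfg)
  class(cfg) <- c("tledreg_config", "list")
  cfg
}
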
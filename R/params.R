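#' Model parameters for phage-bacteria simulations
#'
#' `phage_params()` builds a validated parameter set. The internal unit system
#' is micrometres for length, hours for time, and absolute particle counts per
#' lattice box for populations; bulk densities (`n0`, `K`) are given per
#' millilitre and converted through the box volume \eqn{\ell^3}. The
#' adsorption constant `eta` is always stored in \eqn{\mu m^3/h}; values given
#' in mL/h are converted with 1 mL = 1e12 \eqn{\mu m^3}.
#'
#' @param lambda_max Maximal bacterial growth rate, 1/h.
#' @param eta Phage adsorption rate constant, in the unit named by `eta_unit`.
#' @param eta_unit Either `"um3/h"` (internal unit) or `"mL/h"`.
#' @param beta Burst size: phages released per lysis.
#' @param delta Free-phage decay rate, 1/h.
#' @param tau Mean latency time between infection and lysis, h.
#' @param n_stages Number of sequential infected stages (Erlang shape), 10 by
#'   default.
#' @param n0 Initial nutrient density, bacteria-equivalents per mL.
#' @param K Monod half-saturation constant, bacteria-equivalents per mL.
#'   Defaults to `n0 / 5`; stored as an absolute value so it can be overridden
#'   independently of `n0`.
#' @param D_n,D_P,D_B Diffusion constants of nutrient, phages, bacteria,
#'   \eqn{\mu m^2/h}. Bacteria are treated as immotile on the lattice and
#'   `D_B` must be 0 there.
#' @param alpha Fraction of progeny phages readsorbing to the parent colony
#'   upon lysis, in \[0, 1\].
#' @param zeta Phage penetration depth through the infected surface layer, in
#'   units of the bacterial radius.
#' @param box_len Lattice box side \eqn{\ell}, \eqn{\mu m}.
#' @param lattice_shape Integer vector of box counts per axis (X, Y, Z).
#' @param boundary Per-axis boundary condition, `"periodic"` or
#'   `"reflective"`; a single value is recycled to all three axes.
#' @param dt Time step \eqn{\Delta T}, h.
#' @param seed Integer RNG seed, or `NULL`.
#'
#' @return An object of class `phage_params` (a validated named list).
#' @seealso [default_params()], [p1_plate_params()], [check_stability()]
#' @export
phage_params <- function(lambda_max = 2,
                         eta = 1e4,
                         eta_unit = c("um3/h", "mL/h"),
                         beta = 100,
                         delta = 0.1,
                         tau = 0.5,
                         n_stages = 10L,
                         n0 = 1e9,
                         K = NULL,
                         D_n = 1e6,
                         D_P = 1e4,
                         D_B = 0,
                         alpha = 0.5,
                         zeta = 1,
                         box_len = 200,
                         lattice_shape = c(50L, 50L, 50L),
                         boundary = "periodic",
                         dt = 2e-3,
                         seed = NULL) {
  eta_unit <- match.arg(eta_unit)
  if (eta_unit == "mL/h") eta <- eta * ML_PER_UM3_INV
  if (is.null(K)) K <- n0 / 5
  if (length(boundary) == 1) boundary <- rep(boundary, 3)
  p <- structure(
    list(
      lambda_max = lambda_max, eta = eta, beta = beta, delta = delta,
      tau = tau, n_stages = as.integer(n_stages), n0 = n0, K = K,
      D_n = D_n, D_P = D_P, D_B = D_B, alpha = alpha, zeta = zeta,
      box_len = box_len, lattice_shape = as.integer(lattice_shape),
      boundary = boundary, dt = dt,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "phage_params"
  )
  validate_params(p)
}

# 1 mL = 1e12 um^3
ML_PER_UM3_INV <- 1e12

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, densities and diffusion constants,
#' `alpha` in \[0, 1\], `zeta > 0`, positive geometry, and boundary flags.
#'
#' @param p A `phage_params` object or plain named list with the same fields.
#' @return The validated `phage_params` object (invisibly usable in pipes).
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  num_nonneg <- c("lambda_max", "eta", "beta", "delta", "tau", "n0", "D_n",
                  "D_P", "D_B")
  for (f in num_nonneg) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      abort(sprintf("parameter '%s' must be a single non-negative number", f))
  }
  if (!is.numeric(p$K) || p$K <= 0)
    abort("Monod constant 'K' must be positive")
  if (p$alpha < 0 || p$alpha > 1) abort("'alpha' must lie in [0, 1]")
  if (p$zeta <= 0) abort("'zeta' must be positive")
  if (p$n_stages < 1) abort("'n_stages' must be a positive integer")
  if (p$box_len <= 0) abort("'box_len' must be positive")
  if (p$dt <= 0) abort("'dt' must be positive")
  if (length(p$lattice_shape) != 3 || any(p$lattice_shape < 1))
    abort("'lattice_shape' must be three positive integers")
  if (length(p$boundary) != 3 ||
      !all(p$boundary %in% c("periodic", "reflective")))
    abort("'boundary' must be three flags, 'periodic' or 'reflective'")
  if (!is.null(p$seed) && (length(p$seed) != 1 || is.na(p$seed)))
    abort("'seed' must be a single integer or NULL")
  if (!inherits(p, "phage_params")) class(p) <- "phage_params"
  p
}

#' The default parameter set
#'
#' Well-mixed batch defaults: \eqn{\lambda = 2\,h^{-1}}, \eqn{\eta = 10^{-8}}
#' mL/h (stored as \eqn{10^4\,\mu m^3/h}), \eqn{\beta = 100},
#' \eqn{\delta = 0.1\,h^{-1}}, \eqn{\tau = 0.5} h, \eqn{n_0 = 10^9}/mL,
#' \eqn{K = n_0/5}, with a \eqn{50^3} lattice of 0.2 mm boxes filling one
#' cubic centimetre.
#'
#' @param ... Overrides passed on to [phage_params()].
#' @return A `phage_params` object.
#' @export
default_params <- function(...) {
  phage_params(...)
}

#' P1 soft-agar plate parameter set
#'
#' Parameters for the phage P1 plating scenario: \eqn{\beta = 400},
#' \eqn{\delta = 0.003\,h^{-1}}, \eqn{\eta = 1.32\cdot 10^4\,\mu m^3/h},
#' \eqn{\tau = 1} h, \eqn{D_P = 3000\,\mu m^2/h},
#' \eqn{\lambda = 60/31\,h^{-1}}, in a simulation volume of
#' \eqn{10^4 \times 10^4 \times 400\,\mu m} (a 50 x 50 x 2 lattice of 200
#' \eqn{\mu m} boxes) with a reflective Z boundary. The nutrient level is not
#' pinned by the scenario; `n0` defaults to \eqn{10^9}/mL and `K` to
#' \eqn{n_0/5}, both overridable.
#'
#' @param ... Overrides passed on to [phage_params()].
#' @return A `phage_params` object.
#' @export
p1_plate_params <- function(...) {
  args <- list(
    lambda_max = 60 / 31, eta = 1.32e4, eta_unit = "um3/h", beta = 400,
    delta = 0.003, tau = 1, D_P = 3000,
    lattice_shape = c(50L, 50L, 2L),
    boundary = c("periodic", "periodic", "reflective")
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phage_params, args)
}

#' Check the diffusion stability bound
#'
#' The explicit FTCS scheme is stable in 3-D when
#' \eqn{D\,\Delta T/\ell^2 \le 1/6} for the fastest-diffusing species, the
#' nutrient. Returns the dimensionless margin \eqn{D_n \Delta T/\ell^2} and
#' whether the bound holds.
#'
#' @param params A `phage_params` object.
#' @return A list with elements `stable` (logical) and `margin` (numeric).
#' @export
check_stability <- function(params) {
  params <- validate_params(params)
  if (params$box_len <= 0 || params$dt <= 0)
    abort("invalid parameters: 'box_len' and 'dt' must be positive")
  margin <- params$D_n * params$dt / params$box_len^2
  list(stable = margin <= 1 / 6, margin = margin)
}

#' Geometry helpers
#'
#' `box_volume_um3()` and `box_volume_ml()` return the volume of one lattice
#' box; `total_volume_ml()` the full simulated volume; `n_boxes()` the box
#' count.
#'
#' @param params A `phage_params` object.
#' @return A single number.
#' @export
box_volume_um3 <- function(params) params$box_len^3

#' @rdname box_volume_um3
#' @export
box_volume_ml <- function(params) params$box_len^3 / ML_PER_UM3_INV

#' @rdname box_volume_um3
#' @export
total_volume_ml <- function(params) {
  box_volume_ml(params) * prod(params$lattice_shape)
}

#' @rdname box_volume_um3
#' @export
n_boxes <- function(params) prod(params$lattice_shape)

# Per-box adsorption constant: eta [um^3/h] / V_box [um^3] -> 1/h per pair.
eta_box <- function(params) params$eta / box_volume_um3(params)

# Monod constant and initial nutrient in bacteria-equivalents per box.
K_box <- function(params) params$K * box_volume_ml(params)
n0_box <- function(params) params$n0 * box_volume_ml(params)

# Flat parameter list consumed by the C++ engine.
engine_pars <- function(params, level, singleton = FALSE) {
  stopifnot(level %in% 1:4)
  st <- check_stability(params)
  if (!st$stable)
    abort(sprintf(
      "time step violates the diffusion stability bound: D_n*dt/l^2 = %.3g > 1/6",
      st$margin))
  list(
    level = as.integer(level),
    singleton = isTRUE(singleton),
    n_stages = params$n_stages,
    lambda = params$lambda_max,
    stage_rate = params$n_stages / params$tau,
    beta = params$beta,
    delta = params$delta,
    alpha = params$alpha,
    zeta = params$zeta,
    K_box = K_box(params),
    eta_box = eta_box(params),
    dt = params$dt,
    p_hop = params$D_P * params$dt / params$box_len^2,
    c_n = params$D_n * params$dt / params$box_len^2,
    dims = params$lattice_shape,
    boundary_code = as.integer(params$boundary == "reflective")
  )
}

#' Read and write parameter files
#'
#' Parameter sets round-trip through flat YAML or JSON documents (chosen by
#' file extension: `.yml`/`.yaml` vs `.json`). Unknown keys in a config file
#' are an error: a silent typo in a rate constant is catastrophic in a
#' simulator.
#'
#' @param params A `phage_params` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a validated `phage_params` object.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  x <- unclass(params)
  x$seed <- if (is.null(x$seed)) NULL else x$seed
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(phage_params))
  known <- setdiff(known, "eta_unit")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    abort(paste0("unknown parameter key(s) in config: ",
                 paste(unknown, collapse = ", ")))
  x$lattice_shape <- as.integer(x$lattice_shape)
  x$boundary <- as.character(x$boundary)
  x$seed <- if (length(x$seed)) as.integer(x$seed) else NULL
  do.call(phage_params, c(x, list(eta_unit = "um3/h")))
}

#' @export
print.phage_params <- function(x, ...) {
  cat("<phage_params>\n")
  cat(sprintf("  growth:     lambda_max = %g /h, n0 = %g /mL, K = %g /mL\n",
              x$lambda_max, x$n0, x$K))
  cat(sprintf("  phage:      eta = %g um^3/h, beta = %g, delta = %g /h, tau = %g h (%d stages)\n",
              x$eta, x$beta, x$delta, x$tau, x$n_stages))
  cat(sprintf("  colony:     alpha = %g, zeta = %g\n", x$alpha, x$zeta))
  cat(sprintf("  diffusion:  D_n = %g, D_P = %g, D_B = %g um^2/h\n",
              x$D_n, x$D_P, x$D_B))
  cat(sprintf("  lattice:    %s boxes of %g um (%s), V = %g mL\n",
              paste(x$lattice_shape, collapse = " x "), x$box_len,
              paste(substr(x$boundary, 1, 4), collapse = "/"),
              total_volume_ml(x)))
  cat(sprintf("  numerics:   dt = %g h (stability margin %.3g)%s\n",
              x$dt, check_stability(x)$margin,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}
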
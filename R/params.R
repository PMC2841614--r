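#' Physical and numerical parameters for a simulation
#'
#' Bundles the physical constants of the coupled growth / reaction-diffusion
#' model with the numerical controls of the solver and the shoving loop.
#' Concentrations are in g/L, lengths in micrometres, times in hours, cell
#' biomass in femtograms (1 g/L == 1 fg/um^3, so these units need no
#' conversion factors).
#'
#' The defaults describe a scaled-down but physically plausible aerobic
#' heterotroph condition: biomass density `rho` = 200 g/L, yield `Y` = 0.5,
#' `mu_max` = 1/h, substrate diffusivity `D_G` = 1e5 um^2/h (matrix-hindered),
#' enzyme diffusivity `D_E` = 2e4 um^2/h, boundary layer `h` = 6 um,
#' `K_G` = 0.0035 g/L, division radius `r_div` = 1 um. The default
#' `G_bulk` = 14.4 g/L realizes `delta_number()` = 10 (the saturating,
#' well-mixed regime); use [realize_delta()] to target other regimes.
#'
#' @param G_bulk bulk growth-substrate concentration [g/L].
#' @param D_G,D_E diffusivities of substrate and enzyme [um^2/h].
#' @param Y yield, biomass produced per substrate consumed [dimensionless].
#' @param mu_max maximum specific growth rate [1/h].
#' @param rho cell biomass density [g/L].
#' @param h height of the diffusion boundary layer [um].
#' @param K_G half-saturation constant for growth [g/L].
#' @param r_div critical division radius [um].
#' @param slice nominal slice thickness converting areal to volumetric biomass
#'   density [um]; `rho_area = rho * slice` in fg/um^2.
#' @param width,height domain size [um].
#' @param spacing lattice node spacing [um]; must not exceed the division
#'   diameter `2 * r_div`.
#' @param max_front_height stop height for simulations [um]; must be at most
#'   `height - h`.
#' @param dt_frac cap on `max(mu) * dt` per Euler step [dimensionless].
#' @param eps_overlap fractional overlap left between daughter cells at
#'   division.
#' @param relax_tol,relax_max_sweeps shoving convergence tolerance [um] and
#'   sweep cap.
#' @param solve_tol,solve_max_sweeps relative residual tolerance and sweep cap
#'   for the steady-state solver.
#' @param sor_omega SOR relaxation factor in (0, 2); the default is near the
#'   optimum for the default grid and roughly halves solver time versus
#'   omega = 1.6 without changing the converged fields (same residual
#'   tolerance).
#' @param activity_floor metabolic-activity cutoff used to call a cell
#'   "actively growing" [dimensionless, on m = G/(K_G+G)].
#' @param bulk_rule boundary-layer construction for the surface condition,
#'   `"plane"` (default), `"distance"`, or `"contour"`; see
#'   [compute_bulk_mask()].
#'
#' @return An object of class `"param_set"` (a validated named list).
#' @examples
#' p <- param_set()
#' delta_number(p)
#' @export
param_set <- function(G_bulk = 14.4, D_G = 1e5, D_E = 2e4, Y = 0.5,
                      mu_max = 1, rho = 200, h = 6, K_G = 0.0035,
                      r_div = 1, slice = 1,
                      width = 100, height = 112, spacing = 2,
                      max_front_height = 100,
                      dt_frac = 0.05, eps_overlap = 0.05,
                      relax_tol = 0.05, relax_max_sweeps = 10000,
                      solve_tol = 1e-6, solve_max_sweeps = 50000,
                      sor_omega = 1.92, activity_floor = 0.01,
                      bulk_rule = c("plane", "distance", "contour")) {
  bulk_rule <- match.arg(bulk_rule)
  p <- list(G_bulk = G_bulk, D_G = D_G, D_E = D_E, Y = Y, mu_max = mu_max,
            rho = rho, h = h, K_G = K_G, r_div = r_div, slice = slice,
            width = width, height = height, spacing = spacing,
            max_front_height = max_front_height, dt_frac = dt_frac,
            eps_overlap = eps_overlap, relax_tol = relax_tol,
            relax_max_sweeps = relax_max_sweeps, solve_tol = solve_tol,
            solve_max_sweeps = solve_max_sweeps, sor_omega = sor_omega,
            activity_floor = activity_floor, bulk_rule = bulk_rule)
  pos <- c("G_bulk", "D_G", "D_E", "Y", "mu_max", "rho", "h", "K_G", "r_div",
           "slice", "width", "height", "spacing", "max_front_height",
           "dt_frac", "relax_tol", "solve_tol")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  if (p$spacing > 2 * p$r_div)
    stop("grid spacing must not exceed the division diameter 2*r_div")
  if (p$max_front_height > p$height - p$h)
    stop("max_front_height must be at most height - h")
  if (p$sor_omega <= 0 || p$sor_omega >= 2)
    stop("sor_omega must lie in (0, 2)")
  if (p$eps_overlap < 0 || p$eps_overlap >= 1)
    stop("eps_overlap must lie in [0, 1)")
  class(p) <- "param_set"
  p
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>  delta =", format(delta_number(x), digits = 4), "\n")
  cat("  G_bulk:", x$G_bulk, "g/L   D_G:", x$D_G, "um^2/h   D_E:", x$D_E,
      "um^2/h\n")
  cat("  mu_max:", x$mu_max, "/h   Y:", x$Y, "  rho:", x$rho, "g/L   K_G:",
      x$K_G, "g/L\n")
  cat("  h:", x$h, "um   domain:", x$width, "x", x$height, "um   spacing:",
      x$spacing, "um   r_div:", x$r_div, "um\n")
  invisible(x)
}

#' Areal biomass density and division biomass
#'
#' 2-D disks carry biomass at areal density `rho_area = rho * slice`, so that
#' `radius = sqrt(biomass / (rho_area * pi))`. A cell divides when its radius
#' reaches `r_div`, i.e. at biomass `rho_area * pi * r_div^2`.
#'
#' @param params a [param_set()].
#' @return `rho_area()`: fg/um^2; `division_biomass()`: fg.
#' @export
rho_area <- function(params) params$rho * params$slice

#' @rdname rho_area
#' @export
division_biomass <- function(params) rho_area(params) * pi * params$r_div^2

#' Radius of a 2-D disk cell from its biomass
#'
#' @param biomass biomass [fg], vectorized.
#' @param params a [param_set()].
#' @return radius [um].
#' @export
radius_from_biomass <- function(biomass, params) {
  if (any(biomass <= 0)) stop("biomass must be strictly positive")
  sqrt(biomass / (rho_area(params) * pi))
}

#' The dimensionless active-layer number delta (inverse Thiele modulus)
#'
#' `delta = (1/h) * sqrt(G_bulk * D_G * Y / (mu_max * rho))`. Its square is
#' the factor multiplying the dimensionless Laplacian after normalizing
#' substrate by `G_bulk`, biomass by `rho`, and lengths by `h`; small delta
#' means a thin active layer and strong lineage segregation.
#'
#' @param params a [param_set()].
#' @return dimensionless delta.
#' @examples
#' delta_number(param_set(G_bulk = 0.144))  # the sparse, tower regime
#' @export
delta_number <- function(params) {
  with(params, {
    stopifnot(G_bulk > 0, D_G > 0, Y > 0, mu_max > 0, rho > 0, h > 0)
    (1 / h) * sqrt(G_bulk * D_G * Y / (mu_max * rho))
  })
}

#' Re-parameterize to hit a target delta by altering one constituent
#'
#' Scales exactly one of `G_bulk`, `mu_max`, or `D_G` (all other parameters
#' untouched) so that [delta_number()] of the result equals `delta`.
#'
#' @param params a [param_set()].
#' @param delta target dimensionless active-layer number, > 0.
#' @param via which parameter to alter: `"G_bulk"` (default), `"mu_max"`, or
#'   `"D_G"`.
#' @return a new `param_set`.
#' @export
realize_delta <- function(params, delta,
                          via = c("G_bulk", "mu_max", "D_G")) {
  via <- match.arg(via)
  if (!is.numeric(delta) || delta <= 0) stop("delta must be positive")
  ratio <- (delta / delta_number(params))^2
  p <- unclass(params)
  if (via == "G_bulk") p$G_bulk <- p$G_bulk * ratio
  else if (via == "D_G") p$D_G <- p$D_G * ratio
  else p$mu_max <- p$mu_max / ratio
  do.call(param_set, p)
}
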
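#' Deterministic test fixtures
#'
#' Builds small, fully deterministic cell configurations (with per-cell local
#' substrate assigned directly, bypassing the solver) so the metrics layer
#' can be tested independently of simulation. Kinds:
#' * `MONOLAYER` — a monochromatic row of touching cells on the floor;
#' * `CHECKERBOARD` — alternating RED/BLUE colors on an `nx x ny` square
#'   lattice with pitch `pitch`;
#' * `HALF_HALF` — the same lattice split into RED (left) and BLUE (right)
#'   halves at the domain midline;
#' * `TOWERS` — two monochromatic columns of cells separated by a gap;
#' * `SLAB_1D` — a uniform biomass film of thickness `L` on a narrow periodic
#'   grid, for solver tests (returns field-side objects, no cells).
#'
#' @param kind fixture kind (see above).
#' @param nx,ny lattice extent in cells (CHECKERBOARD/HALF_HALF), or cells
#'   per column/columns (TOWERS: `nx` columns of `ny` cells).
#' @param n_cells cells in a MONOLAYER.
#' @param pitch lattice pitch [um]; default the division diameter.
#' @param gap lateral gap between towers [um].
#' @param G_rule per-cell substrate: a single value (uniform), or a function
#'   `f(x, y)` evaluated at cell centres.
#' @param L,X_film film thickness [um] and biomass concentration [g/L]
#'   (SLAB_1D).
#' @param params a [param_set()].
#' @return for cell fixtures: `list(cells, G, params)`; for SLAB_1D:
#'   `list(grid, biomass, params, L)` where `biomass` is a `biomass_field`.
#' @examples
#' fx <- make_fixture("CHECKERBOARD", nx = 6, ny = 6)
#' head(fx$cells)
#' @export
make_fixture <- function(kind = c("MONOLAYER", "CHECKERBOARD", "HALF_HALF",
                                  "TOWERS", "SLAB_1D"),
                         nx = 6, ny = 6, n_cells = 10,
                         pitch = NULL, gap = 20,
                         G_rule = NULL, L = 20, X_film = 100,
                         params = param_set()) {
  kind <- match.arg(kind)
  if (is.null(pitch)) pitch <- 2 * params$r_div
  if (pitch < 2 * params$r_div * (1 - 1e-9))
    stop("pitch smaller than the cell diameter: cells would overlap")
  X_div <- division_biomass(params)
  mass <- 0.9 * X_div  # radius 0.949 * r_div: lattice cells never overlap
  if (is.null(G_rule)) G_rule <- params$G_bulk

  lattice_cells <- function(nx, ny, colors) {
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
    cell_table(id = seq_len(nrow(g)),
               x = (g$i - 0.5) * pitch, y = (g$j - 0.5) * pitch,
               biomass = mass, color = colors(g), strain = colors(g),
               params = params)
  }
  eval_G <- function(cells) {
    if (is.function(G_rule)) G_rule(cells$x, cells$y)
    else rep(G_rule, nrow(cells))
  }

  if (kind == "SLAB_1D") {
    grid <- grid_from_params(params)
    biomass <- structure(list(
      total = outer(rep(1, grid$nx), node_y(grid), function(i, y)
        ifelse(y < L, X_film, 0)),
      by_strain = list(), grid = grid,
      node_volume = grid$spacing^2 * params$slice),
      class = "biomass_field")
    biomass$by_strain$wt <- biomass$total
    return(list(grid = grid, biomass = biomass, params = params, L = L))
  }

  cells <- switch(kind,
    MONOLAYER = {
      x <- (seq_len(n_cells) - 0.5) * pitch
      cell_table(id = seq_len(n_cells), x = x,
                 y = radius_from_biomass(rep(mass, n_cells), params),
                 biomass = mass, color = "RED", strain = "RED",
                 params = params)
    },
    CHECKERBOARD = lattice_cells(nx, ny, function(g)
      ifelse((g$i + g$j) %% 2 == 0, "RED", "BLUE")),
    HALF_HALF = lattice_cells(nx, ny, function(g)
      ifelse(g$i <= nx / 2, "RED", "BLUE")),
    TOWERS = {
      stopifnot(nx >= 2)
      g <- expand.grid(j = seq_len(ny), t = seq_len(nx))
      x0 <- (g$t - 1) * (pitch + gap) + pitch / 2
      cell_table(id = seq_len(nrow(g)), x = x0, y = (g$j - 0.5) * pitch,
                 biomass = mass,
                 color = ifelse(g$t %% 2 == 1, "RED", "BLUE"),
                 strain = ifelse(g$t %% 2 == 1, "RED", "BLUE"),
                 params = params)
    })
  list(cells = cells, G = eval_G(cells), params = params)
}

#' Closed-form 1-D slab substrate profile (zeroth-order uptake)
#'
#' The steady solution of `D C'' = k` on a film `0 <= y <= L` with `C(L) =
#' G0` and no flux at `y = 0` is `G0 - (k / (2 D)) * (L^2 - y^2)`, clipped at
#' zero. Serves as the independent oracle for the reaction-diffusion solver.
#'
#' @param G0 concentration at the film surface [g/L].
#' @param k volumetric uptake rate [g/L/h].
#' @param D diffusivity [um^2/h].
#' @param L film thickness [um].
#' @param y heights [um], vectorized, in `[0, L]`.
#' @return concentrations [g/L].
#' @export
analytic_slab_profile <- function(G0, k, D, L, y) {
  stopifnot(G0 >= 0, k >= 0, D > 0, L > 0)
  if (any(y < 0 | y > L)) stop("y must lie in [0, L]")
  pmax(G0 - (k / (2 * D)) * (L^2 - y^2), 0)
}
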
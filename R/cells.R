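#' Cell tables
#'
#' Cells are stored as a plain data.frame with one row per circular agent and
#' columns `id` (integer), `x`, `y` (centre, um), `biomass` (fg), `radius`
#' (um, derived from biomass), `color` (character lineage label), `strain`
#' (character strain name), `growth_rate` (1/h, last computed), and `active`
#' (logical). `color` and `strain` are fixed at creation and inherited on
#' division.
#'
#' @param id,x,y,biomass,color,strain,growth_rate,active column vectors.
#' @param params a [param_set()] used to derive radii.
#' @return a `data.frame` of cells.
#' @export
cell_table <- function(id, x, y, biomass, color, strain,
                       growth_rate = 0, active = TRUE, params) {
  if (any(biomass <= 0)) stop("biomass must be strictly positive")
  data.frame(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
             biomass = as.numeric(biomass),
             radius = radius_from_biomass(biomass, params),
             color = as.character(color), strain = as.character(strain),
             growth_rate = as.numeric(growth_rate),
             active = as.logical(active),
             stringsAsFactors = FALSE)
}

# exact-count color assignment by largest remainder, then a seeded permutation
largest_remainder_counts <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("color fractions must sum to 1")
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Seed a mixed monolayer of cells on the floor surface
#'
#' Places `n_cells` cells in a single layer at uniform-random, non-overlapping
#' x positions (overlaps removed by the shoving routine), with colors assigned
#' by exact-count largest-remainder rounding of `fractions` and then randomly
#' permuted. Initial per-cell biomass is drawn uniformly from
#' `[0.55, 0.95] * division_biomass(params)` to desynchronize divisions.
#' Deterministic for a fixed `seed`. For the `"radial"` condition the same
#' roster is packed into a compact disk at the domain centre instead.
#'
#' @param n_cells number of founder cells, >= 1.
#' @param fractions named numeric vector of color fractions summing to 1,
#'   e.g. `c(RED = 0.5, BLUE = 0.5)`.
#' @param strain_map named character vector mapping each color to a strain
#'   name; defaults to using the color itself.
#' @param params a [param_set()].
#' @param seed integer RNG seed.
#' @param condition `"surface"` (monolayer on the floor, periodic x) or
#'   `"radial"` (disk at the domain centre, open boundaries).
#' @return a cell `data.frame` (see [cell_table()]).
#' @examples
#' p <- param_set()
#' cells <- init_monolayer(10, c(BLUE = 0.1, RED = 0.9), params = p, seed = 1)
#' table(cells$color)
#' @export
init_monolayer <- function(n_cells, fractions, strain_map = NULL,
                           params = param_set(), seed = 1,
                           condition = c("surface", "radial")) {
  condition <- match.arg(condition)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be a named vector of colors")
  counts <- largest_remainder_counts(n_cells, fractions)
  if (is.null(strain_map))
    strain_map <- setNames(names(fractions), names(fractions))
  missing_map <- setdiff(names(fractions), names(strain_map))
  if (length(missing_map))
    stop("strain_map lacks colors: ", paste(missing_map, collapse = ", "))

  set.seed(seed)
  X_div <- division_biomass(params)
  biomass <- runif(n_cells, 0.55, 0.95) * X_div
  radius <- radius_from_biomass(biomass, params)
  if (condition == "surface" && sum(2 * radius) > params$width)
    stop("n_cells too large: ", n_cells, " cells do not fit a width of ",
         params$width, " um")

  colors <- rep(names(fractions), counts)
  colors <- colors[sample.int(n_cells)]

  if (condition == "surface") {
    x <- runif(n_cells, 0, params$width)
    y <- radius
  } else {
    cx <- params$width / 2; cy <- params$height / 2
    rcloud <- sqrt(sum(radius^2)) * 1.2 + max(radius)
    ang <- runif(n_cells, 0, 2 * pi)
    rad <- rcloud * sqrt(runif(n_cells))
    x <- cx + rad * cos(ang)
    y <- cy + rad * sin(ang)
  }
  cells <- cell_table(id = seq_len(n_cells), x = x, y = y, biomass = biomass,
                      color = colors, strain = strain_map[colors],
                      params = params)
  relax_overlaps(cells, params, condition = condition)
}

#' Grow cells by one explicit Euler step
#'
#' `biomass <- biomass * (1 + mu * dt)`, radii recomputed from the disk
#' invariant. Rejects steps with `mu * dt > 1` (too large for the Euler
#' policy).
#'
#' @param cells a cell `data.frame`.
#' @param mu specific growth rates [1/h], recycled to `nrow(cells)`;
#'   must be >= 0 (clamp negatives upstream).
#' @param dt time step [h], > 0.
#' @param params a [param_set()].
#' @return the grown cell table (with `growth_rate` updated to `mu`).
#' @export
grow_cells <- function(cells, mu, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  if (any(mu < 0)) stop("mu must be non-negative")
  if (any(mu * dt > 1)) stop("mu * dt exceeds 1: Euler step too large")
  cells$biomass <- cells$biomass * (1 + mu * dt)
  cells$radius <- radius_from_biomass(cells$biomass, params)
  cells$growth_rate <- rep(mu, length.out = nrow(cells))
  cells
}

#' Divide all supercritical cells
#'
#' Every cell whose radius has reached `r_div` is replaced by two daughters
#' with exactly half the parent biomass each (child radius `r/sqrt(2)`),
#' placed symmetrically about the parent centre along a uniform-random axis at
#' separation `2 * r_child * (1 - eps_overlap)`. Daughters inherit color and
#' strain; the parent id is retired and both daughters receive fresh ids.
#' Cells below threshold pass through untouched. Total biomass is conserved
#' exactly.
#'
#' @param cells a cell `data.frame`.
#' @param params a [param_set()].
#' @param next_id first unused integer id.
#' @return `list(cells = <data.frame>, next_id = <integer>)`.
#' @export
divide_cells <- function(cells, params, next_id = max(cells$id) + 1L) {
  split <- which(cells$radius >= params$r_div)
  if (!length(split))
    return(list(cells = cells, next_id = as.integer(next_id)))
  par <- cells[split, , drop = FALSE]
  m_child <- par$biomass / 2
  r_child <- radius_from_biomass(m_child, params)
  ang <- runif(nrow(par), 0, 2 * pi)
  off <- r_child * (1 - params$eps_overlap)
  dx <- cos(ang) * off; dy <- sin(ang) * off
  n <- nrow(par)
  ids <- as.integer(next_id + seq_len(2 * n) - 1L)
  keep <- cells[-split, , drop = FALSE]
  # assemble the combined table column-by-column (parents' survivors, then
  # the +axis daughters, then the -axis daughters); this is the same layout
  # rbind() of three cell tables would produce, without its per-call cost
  out <- data.frame(
    id = c(keep$id, ids),
    x = c(keep$x, par$x + dx, par$x - dx),
    y = c(keep$y, pmax(par$y + dy, r_child), pmax(par$y - dy, r_child)),
    biomass = c(keep$biomass, m_child, m_child),
    radius = c(keep$radius, r_child, r_child),
    color = c(keep$color, par$color, par$color),
    strain = c(keep$strain, par$strain, par$strain),
    growth_rate = c(keep$growth_rate, par$growth_rate, par$growth_rate),
    active = c(keep$active, par$active, par$active),
    stringsAsFactors = FALSE)
  list(cells = out, next_id = as.integer(next_id + 2L * n))
}

#' Resolve overlaps between cells (shoving)
#'
#' Iteratively displaces each overlapping pair along its centre-to-centre
#' axis, each cell by half the overlap, in randomized order per sweep, until
#' the largest pairwise overlap is below `params$relax_tol`. Cells pushed
#' below the floor are projected back onto `y = radius` (surface condition).
#' Neighbor search uses spatial binning, so cost is near-linear in cell count.
#' The sweep-order shuffle is seeded from the current R RNG stream, keeping
#' whole runs reproducible.
#'
#' @param cells a cell `data.frame` with finite positions.
#' @param params a [param_set()].
#' @param condition `"surface"` (periodic x, floor at y = 0) or `"radial"`
#'   (open domain, no floor).
#' @return the relaxed cell table, with attributes `sweeps` and
#'   `max_overlap`.
#' @export
relax_overlaps <- function(cells, params,
                           condition = c("surface", "radial")) {
  condition <- match.arg(condition)
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("cell positions must be finite")
  seed <- sample.int(.Machine$integer.max, 1L)
  res <- relax_overlaps_cpp(cells$x, cells$y, cells$radius,
                            width = params$width,
                            periodic_x = condition == "surface",
                            floor_y = condition == "surface",
                            tol = params$relax_tol,
                            max_sweeps = params$relax_max_sweeps,
                            seed = seed)
  if (!res$converged)
    stop(sprintf(
      "overlap relaxation did not converge in %d sweeps (residual overlap %.4g um)",
      params$relax_max_sweeps, res$max_overlap))
  cells$x <- res$x
  cells$y <- res$y
  attr(cells, "sweeps") <- res$sweeps
  attr(cells, "max_overlap") <- res$max_overlap
  cells
}

#' Height of the advancing front
#'
#' The maximum over cells of `y + radius`.
#'
#' @param cells a non-empty cell `data.frame`.
#' @return front height [um].
#' @export
front_height <- function(cells) {
  if (!nrow(cells)) stop("front_height needs at least one cell")
  max(cells$y + cells$radius)
}
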
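#' A node-centred 2-D lattice
#'
#' Node `(i, j)` (1-based) has its centre at `((i - 0.5) * spacing,
#' (j - 0.5) * spacing)`; node (1, 1) sits at the lower-left. Matrices over
#' the grid are indexed `[i, j]` with `nx` rows and `ny` columns.
#'
#' @param width,height domain size [um]; must be integer multiples of
#'   `spacing`.
#' @param spacing node spacing [um].
#' @param periodic_x logical; periodic lateral wrap (surface condition) or
#'   open/no-flux (radial condition).
#' @return an object of class `"grid2d"`.
#' @export
grid2d <- function(width, height, spacing, periodic_x = TRUE) {
  if (spacing <= 0) stop("spacing must be positive")
  nx <- round(width / spacing); ny <- round(height / spacing)
  if (abs(nx * spacing - width) > 1e-9 || abs(ny * spacing - height) > 1e-9)
    stop("width and height must be integer multiples of spacing")
  if (nx * ny < 4) stop("grid must have at least 4 nodes")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
                 width = width, height = height, periodic_x = periodic_x),
            class = "grid2d")
}

grid_from_params <- function(params, condition = "surface") {
  grid2d(params$width, params$height, params$spacing,
         periodic_x = condition == "surface")
}

node_x <- function(grid) (seq_len(grid$nx) - 0.5) * grid$spacing
node_y <- function(grid) (seq_len(grid$ny) - 0.5) * grid$spacing

#' A solute concentration field
#'
#' Substrate fields hold the bulk value on bulk nodes (infinite source) and
#' obey the maximum principle `0 <= value <= bulk_value`; enzyme fields are
#' zero on bulk nodes (perfect sink) and non-negative inside.
#'
#' @param grid a [grid2d()].
#' @param kind `"substrate"` or `"enzyme"`.
#' @param bulk_value Dirichlet concentration on bulk nodes [g/L]
#'   (`G_bulk` for substrate, 0 for enzyme).
#' @param values optional initial `nx x ny` matrix; defaults to
#'   `bulk_value` everywhere.
#' @param bulk_mask optional `nx x ny` logical matrix of bulk nodes.
#' @return an object of class `"solute_field"`.
#' @export
solute_field <- function(grid, kind = c("substrate", "enzyme"),
                         bulk_value = NULL, values = NULL, bulk_mask = NULL) {
  kind <- match.arg(kind)
  if (is.null(bulk_value)) bulk_value <- if (kind == "substrate") 1 else 0
  if (kind == "enzyme" && bulk_value != 0)
    stop("the bulk is a perfect sink for enzyme: bulk_value must be 0")
  if (is.null(values)) values <- matrix(bulk_value, grid$nx, grid$ny)
  if (is.null(bulk_mask)) bulk_mask <- matrix(TRUE, grid$nx, grid$ny)
  stopifnot(all(dim(values) == c(grid$nx, grid$ny)),
            all(dim(bulk_mask) == c(grid$nx, grid$ny)))
  structure(list(grid = grid, kind = kind, bulk_value = bulk_value,
                 values = values, bulk_mask = bulk_mask,
                 rel_residual = NA_real_, sweeps = NA_integer_),
            class = "solute_field")
}

#' Deposit cell biomass onto the lattice
#'
#' Nearest-node rasterization: each cell's biomass is added to the node
#' containing its centre, as a concentration `mass / (spacing^2 * slice)` in
#' g/L, with one channel per strain. The scheme conserves total biomass
#' exactly.
#'
#' @param cells a cell `data.frame`; all centres must lie inside the domain.
#' @param grid a [grid2d()].
#' @param params a [param_set()] (supplies the slice thickness).
#' @return a list of class `"biomass_field"` with elements `total` (an
#'   `nx x ny` matrix, g/L), `by_strain` (named list of matrices), `grid`,
#'   and `node_volume` (um^3).
#' @export
rasterize_biomass <- function(cells, grid, params) {
  vol <- grid$spacing^2 * params$slice
  by_strain <- list()
  total <- matrix(0, grid$nx, grid$ny)
  if (nrow(cells)) {
    ix <- floor(cells$x / grid$spacing) + 1L
    if (grid$periodic_x) ix <- ((ix - 1L) %% grid$nx) + 1L
    iy <- floor(cells$y / grid$spacing) + 1L
    if (any(ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny))
      stop("cell centre outside the grid")
    idx <- (iy - 1L) * grid$nx + ix
    for (st in unique(cells$strain)) {
      v <- numeric(grid$nx * grid$ny)
      sel <- cells$strain == st
      acc <- rowsum(cells$biomass[sel], idx[sel])
      v[as.integer(rownames(acc))] <- acc[, 1]
      m <- matrix(v / vol, grid$nx, grid$ny)
      by_strain[[st]] <- m
      total <- total + m
    }
  }
  structure(list(total = total, by_strain = by_strain, grid = grid,
                 node_volume = vol),
            class = "biomass_field")
}

#' Bulk-region mask from the current biomass distribution
#'
#' The bulk liquid is the region beyond the diffusion boundary layer of
#' height `h`. Three constructions are available for the surface condition.
#' The `"plane"` rule (default) holds the bulk on the horizontal plane `h`
#' above the highest biomass-bearing node, so a column that falls behind the
#' leaders sits farther from the source by its full height deficit; this is
#' the geometry that lets a rough front amplify into towers under strong
#' substrate limitation. The `"distance"` rule marks a node as bulk when its
#' centre lies farther than `h` from every biomass-bearing node (a
#' morphological dilation of the biomass by `h`), so only troughs narrower
#' than about `2 h` are diffusion-shadowed. The `"contour"` rule is
#' columnwise: per lateral column the front is the centre of its highest
#' biomass-bearing node, laterally smoothed by the minimum front height
#' within a `+/- h` column window, and bulk is everything more than `h`
#' above the smoothed front; this variant supplies every column equally and
#' therefore keeps fronts smooth. The `"radial"` condition always uses the
#' distance rule. With no biomass the whole domain is bulk.
#'
#' @param biomass a `biomass_field` from [rasterize_biomass()].
#' @param h boundary-layer height [um], at least one grid spacing.
#' @param condition `"surface"` or `"radial"`.
#' @param rule `"plane"` (default), `"distance"`, or `"contour"`; ignored
#'   for `"radial"`, which is always distance-based.
#' @return an `nx x ny` logical matrix (TRUE = bulk).
#' @export
compute_bulk_mask <- function(biomass, h, condition = c("surface", "radial"),
                              rule = c("plane", "distance", "contour")) {
  condition <- match.arg(condition)
  rule <- match.arg(rule)
  grid <- biomass$grid
  if (h < grid$spacing) stop("h must be at least one grid spacing")
  occ <- biomass$total > 0
  if (!any(occ)) return(matrix(TRUE, grid$nx, grid$ny))
  if (condition == "radial")
    return(radial_bulk_cpp(occ, h / grid$spacing, periodic_x = FALSE))
  if (rule == "distance")
    return(radial_bulk_cpp(occ, h / grid$spacing,
                           periodic_x = grid$periodic_x))
  if (rule == "plane") {
    ys <- node_y(grid)
    top <- max(ys[colSums(occ) > 0])
    bulk <- matrix(rep(ys > top + h, each = grid$nx), grid$nx, grid$ny)
    return(bulk & !occ)
  }

  ys <- node_y(grid)
  front <- apply(occ, 1, function(col) {
    k <- which(col); if (length(k)) ys[max(k)] else -Inf
  })
  w <- floor(h / grid$spacing)
  nx <- grid$nx
  sm <- vapply(seq_len(nx), function(i) {
    win <- (i - w):(i + w)
    if (grid$periodic_x) win <- ((win - 1L) %% nx) + 1L
    else win <- win[win >= 1 & win <= nx]
    min(front[win])
  }, numeric(1))
  bulk <- outer(seq_len(nx), seq_len(grid$ny),
                function(i, j) ys[j] > sm[i] + h)
  bulk & !occ
}

#' Solve a reaction-diffusion field to steady state
#'
#' Finds the lattice solution of `D * lap(C) + rate(C) = 0` with
#' `rate(C) = Q - S0 - A * C / (K + C)` (source `Q`, zeroth-order sink `S0`,
#' Michaelis-Menten sink with capacity `A` and half-saturation `K`, all in
#' g/L/h), Dirichlet `bulk_value` on bulk nodes, no-flux at the floor and
#' top, and periodic or no-flux lateral boundaries. The solver is damped
#' Gauss-Seidel/SOR; the contract is the relative residual, which must fall
#' below `tol`. Substrate solutions are clipped to `[0, bulk_value]` only if
#' the overshoot is within tolerance; larger violations are an error.
#'
#' @param field a [solute_field()] whose `bulk_mask` is current; its `values`
#'   are used as the warm start.
#' @param D diffusivity [um^2/h].
#' @param A,K Michaelis-Menten sink capacity matrix [g/L/h] and
#'   half-saturation [g/L] (`A = 0` disables the term).
#' @param Q source matrix [g/L/h] (scalar recycled).
#' @param S0 zeroth-order sink matrix [g/L/h] (scalar recycled).
#' @param tol relative residual tolerance.
#' @param max_sweeps sweep cap; exceeding it is an error.
#' @param omega SOR relaxation factor.
#' @return the field with solved `values`, `rel_residual`, and `sweeps`.
#' @examples
#' g <- grid2d(8, 8, 2)
#' f <- solute_field(g, "substrate", bulk_value = 5)
#' f <- solve_reaction_diffusion(f, D = 1e5)  # no biomass: uniform bulk
#' @export
solve_reaction_diffusion <- function(field, D, A = 0, K = 1, Q = 0, S0 = 0,
                                     tol = 1e-6, max_sweeps = 50000,
                                     omega = 1.6) {
  grid <- field$grid
  as_mat <- function(v) {
    if (is.matrix(v)) { stopifnot(all(dim(v) == c(grid$nx, grid$ny))); v }
    else matrix(v, grid$nx, grid$ny)
  }
  if (D <= 0) stop("diffusivity must be positive")
  A <- as_mat(A); Q <- as_mat(Q); S0 <- as_mat(S0)
  res <- solve_rd_cpp(field$values, field$bulk_mask, field$bulk_value,
                      D, grid$spacing, A, K, Q, S0,
                      periodic_x = grid$periodic_x, tol = tol,
                      max_sweeps = max_sweeps, omega = omega,
                      check_every = 5L)
  if (!res$converged)
    stop(sprintf("reaction-diffusion solve did not converge: residual %.3g after %d sweeps",
                 res$rel_residual, res$sweeps))
  C <- res$C
  # The residual criterion bounds pointwise errors relative to the solver's
  # scale, (D/s^2)*max|C| + max rate; expressed as a concentration that is
  # max|C| + max_rate*s^2/D, which exceeds the bulk value wherever the rate
  # term dominates. Size the out-of-range band accordingly.
  conc_scale <- max(abs(C)) +
    max(A + abs(Q) + abs(S0)) * grid$spacing^2 / D
  if (field$kind == "substrate") {
    band <- tol * max(field$bulk_value, conc_scale, 1e-300)
    if (min(C) < -band || max(C) > field$bulk_value + band)
      stop("substrate solution violates [0, bulk] beyond tolerance: ",
           "unstable rate law?")
    C <- pmin(pmax(C, 0), field$bulk_value)
  } else {
    band <- tol * max(max(C), conc_scale, 1)
    if (min(C) < -band)
      stop("negative enzyme concentration beyond tolerance")
    C <- pmax(C, 0)
  }
  field$values <- C
  field$rel_residual <- res$rel_residual
  field$sweeps <- res$sweeps
  field
}

#' Sample a field at arbitrary points
#'
#' Bilinear interpolation of the four surrounding node values; queries are
#' clamped to the node-centre lattice at the domain edges (consistent with
#' the no-flux boundaries) and wrap laterally on periodic grids. Results lie
#' within the min/max of the surrounding node values.
#'
#' @param field a [solute_field()].
#' @param x,y query coordinates [um], vectorized; must lie inside the domain.
#' @return concentrations [g/L].
#' @export
sample_concentration <- function(field, x, y) {
  grid <- field$grid
  if (any(x < 0 | x > grid$width | y < 0 | y > grid$height))
    stop("query point outside the domain")
  s <- grid$spacing
  gx <- x / s - 0.5
  gy <- y / s - 0.5
  if (grid$periodic_x) {
    i0 <- floor(gx); fx <- gx - i0
    ia <- (as.integer(i0) %% grid$nx) + 1L
    ib <- (as.integer(i0 + 1) %% grid$nx) + 1L
  } else {
    gx <- pmin(pmax(gx, 0), grid$nx - 1)
    i0 <- pmin(floor(gx), grid$nx - 2); fx <- gx - i0
    ia <- as.integer(i0) + 1L; ib <- ia + 1L
  }
  gy <- pmin(pmax(gy, 0), grid$ny - 1)
  j0 <- pmin(floor(gy), grid$ny - 2); fy <- gy - j0
  ja <- as.integer(j0) + 1L; jb <- ja + 1L
  V <- field$values
  n <- grid$nx
  v00 <- V[(ja - 1L) * n + ia]; v10 <- V[(ja - 1L) * n + ib]
  v01 <- V[(jb - 1L) * n + ia]; v11 <- V[(jb - 1L) * n + ib]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# value at the node containing each point, with the same node mapping as
# rasterize_biomass(); this is the sampling used for in-step growth so that
# the agent-side uptake and the field-side sink are the same discretization
sample_nodal <- function(field, x, y) {
  grid <- field$grid
  ix <- floor(x / grid$spacing) + 1L
  if (grid$periodic_x) ix <- ((ix - 1L) %% grid$nx) + 1L
  iy <- floor(y / grid$spacing) + 1L
  if (any(ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny))
    stop("query point outside the grid")
  field$values[(iy - 1L) * grid$nx + ix]
}

#' Write / read a field as delimited text
#'
#' One file per solute: a header line `nx ny spacing kind bulk_value`, then
#' the `ny` rows of the field bottom-to-top, each with `nx` whitespace-
#' separated values.
#'
#' @param field a [solute_field()].
#' @param path file path.
#' @return `write_field()` invisibly returns `path`; `read_field()` a
#'   [solute_field()] (with an all-bulk mask, suitable for re-analysis).
#' @export
write_field <- function(field, path) {
  g <- field$grid
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %.10g %s %.10g", g$nx, g$ny, g$spacing,
                     field$kind, field$bulk_value), con)
  for (j in seq_len(g$ny))
    writeLines(paste(format(field$values[, j], digits = 10), collapse = " "),
               con)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nx <- as.integer(hd[1]); ny <- as.integer(hd[2])
  spacing <- as.numeric(hd[3]); kind <- hd[4]; bulk <- as.numeric(hd[5])
  vals <- matrix(0, nx, ny)
  for (j in seq_len(ny))
    vals[, j] <- as.numeric(strsplit(trimws(lines[j + 1]), "\\s+")[[1]])
  g <- grid2d(nx * spacing, ny * spacing, spacing)
  solute_field(g, kind, bulk_value = bulk, values = vals)
}
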
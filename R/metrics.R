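#' Metabolic activity of a cell from its local substrate
#'
#' `m = G / (K_G + G)`, the Michaelis-Menten saturation term, in `[0, 1]`.
#'
#' @param G_local local substrate concentration [g/L], vectorized.
#' @param K_G half-saturation constant [g/L].
#' @return dimensionless activity in `[0, 1]`.
#' @export
metabolic_activity <- function(G_local, K_G) {
  if (any(G_local < 0) || K_G < 0) stop("inputs must be non-negative")
  G_local / (K_G + G_local)
}

#' Lineage segregation index
#'
#' For every "actively growing" focal cell (metabolic activity
#' `m >= activity_floor`, optionally restricted to one color), all *other*
#' cells within the neighborhood radius are collected and scored with the
#' genetic identity function `g` (1 for the focal color, 0 otherwise) and the
#' activity function `m`. The focal score is the activity-weighted same-color
#' frequency `sum(g*m) / sum(m)`, and the index is the mean focal score: 1
#' means complete lineage segregation at the neighborhood scale, and when all
#' neighbors are fully active it reduces to the local frequency of same-color
#' cells. The index is a spatial form of the relatedness coefficient r in
#' Hamilton's rule. `normalize = FALSE` gives the literal unnormalized mean
#' product `sum(g*m)/N` for comparison (it cannot reach 1 unless all
#' neighbors are fully active).
#'
#' @param cells a cell `data.frame`.
#' @param G per-cell local substrate concentrations [g/L] (a vector), or a
#'   substrate [solute_field()] to sample at the cell centres.
#' @param params a [param_set()] (supplies `K_G`, `r_div`, the activity
#'   floor, and the domain width for periodic distances).
#' @param focal_color a color name, or `"ALL"` (default) to average over
#'   focal cells of every color.
#' @param radius neighborhood radius [um]; default 10 cell lengths,
#'   `10 * 2 * r_div`.
#' @param normalize activity-weighted frequency (default) vs literal mean
#'   product.
#' @param periodic_x measure distances with lateral wrap (default TRUE, the
#'   surface condition).
#' @return the index, a number in `[0, 1]`; focal cells whose neighborhood
#'   carries no activity are excluded (all excluded is an error). The
#'   per-focal scores are attached as attribute `"scores"`.
#' @export
segregation_index <- function(cells, G, params = param_set(),
                              focal_color = "ALL",
                              radius = 10 * 2 * params$r_div,
                              normalize = TRUE, periodic_x = TRUE) {
  if (radius <= 0) stop("neighborhood radius must be positive")
  if (inherits(G, "solute_field")) G <- sample_concentration(G, cells$x, cells$y)
  if (length(G) != nrow(cells))
    stop("G must supply one local concentration per cell")
  m <- metabolic_activity(G, params$K_G)
  focal <- m >= params$activity_floor
  if (!identical(focal_color, "ALL")) focal <- focal & cells$color == focal_color
  if (!any(focal)) stop("no metabolically active focal cells")
  col_int <- as.integer(factor(cells$color))
  s <- seg_scores_cpp(cells$x, cells$y, col_int, m, focal, radius,
                      periodic_x, params$width, normalize)
  s <- s[focal]
  s <- s[!is.na(s)]
  if (!length(s)) stop("every focal cell had a zero-activity neighborhood")
  structure(mean(s), scores = s)
}

#' Strain fitness as division rounds per unit time
#'
#' `W = log2(N_end / N_start) / duration`: the mean number of rounds of cell
#' division per hour achieved over a simulation.
#'
#' @param N_start,N_end cell counts at the start and end (`N_start >= 1`).
#' @param duration elapsed time [h], > 0.
#' @return divisions per hour; `-Inf` (with a warning) if the strain went
#'   extinct.
#' @export
strain_fitness <- function(N_start, N_end, duration) {
  if (N_start < 1) stop("N_start must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  if (N_end == 0) {
    warning("strain went extinct: fitness is -Inf")
    return(-Inf)
  }
  log2(N_end / N_start) / duration
}

#' Relative fitness of strain 1 against strain 2
#'
#' The ratio `W1 / W2`; values above 1 mean strain 1 wins the competition.
#'
#' @param W1,W2 strain fitnesses from [strain_fitness()]; `W2` must be > 0.
#' @return dimensionless relative fitness.
#' @export
relative_fitness <- function(W1, W2) {
  if (!is.finite(W2) || W2 <= 0)
    stop("relative fitness undefined for W2 <= 0")
  W1 / W2
}

#' Mean depth of the actively growing layer
#'
#' Per lateral column (bins of `bin_width`), the depth is the column front
#' height minus the lowest y among cells growing at
#' `mu >= threshold_fraction * mu_max`; columns with cells but none growing
#' contribute 0. Returns the mean over columns containing cells, or 0 when no
#' cell grows.
#'
#' @param cells a cell `data.frame` with current `growth_rate`.
#' @param params a [param_set()].
#' @param threshold_fraction growth cutoff as a fraction of `mu_max`, in
#'   (0, 1); default 0.1.
#' @param bin_width lateral bin width [um]; defaults to the grid spacing.
#' @return mean active-layer depth [um].
#' @export
active_layer_depth <- function(cells, params, threshold_fraction = 0.1,
                               bin_width = params$spacing) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (!nrow(cells)) return(0)
  thr <- threshold_fraction * params$mu_max
  if (!any(cells$growth_rate >= thr)) return(0)
  bin <- floor(cells$x / bin_width)
  depths <- vapply(split(seq_len(nrow(cells)), bin), function(k) {
    top <- max(cells$y[k] + cells$radius[k])
    grow <- k[cells$growth_rate[k] >= thr]
    if (!length(grow)) return(0)
    top - min(cells$y[grow])
  }, numeric(1))
  mean(depths)
}

#' Front roughness and tower gaps
#'
#' Bins cells laterally, takes the front height (max `y + radius`) per
#' occupied bin, and reports the standard deviation of those heights together
#' with the number of empty *interior* bins (gaps between towers; bins
#' outside the occupied range do not count, and on a full-width periodic
#' domain every empty bin is interior). When growth starts from a sparse
#' founder row, a continuous film fills every column while tower-forming
#' regimes leave the channels between towers empty.
#'
#' @param cells a non-empty cell `data.frame`.
#' @param params a [param_set()] (supplies the domain width).
#' @param bin_width lateral bin width [um]; defaults to the grid spacing.
#' @return `list(sd = <um>, gaps = <count>, heights = <per-bin front,
#'   `NA` for empty bins>)`.
#' @export
front_roughness <- function(cells, params, bin_width = params$spacing) {
  if (!nrow(cells)) stop("front_roughness needs at least one cell")
  nb <- max(1L, as.integer(round(params$width / bin_width)))
  bin <- pmin(pmax(floor(cells$x / bin_width) + 1L, 1L), nb)
  heights <- rep(NA_real_, nb)
  top <- tapply(cells$y + cells$radius, bin, max)
  heights[as.integer(names(top))] <- top
  occ <- which(!is.na(heights))
  gaps <- if (length(occ) >= 2) {
    interior <- seq(min(occ), max(occ))
    sum(is.na(heights[interior]))
  } else 0L
  # the lateral domain is periodic: an empty bin outside the occupied span is
  # still between towers
  if (length(occ) >= 1 && length(occ) < nb)
    gaps <- sum(is.na(heights))
  h <- heights[occ]
  list(sd = if (length(h) > 1) sd(h) else 0, gaps = as.integer(gaps),
       heights = heights)
}

# Student-t 95% confidence interval over replicates
t_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0))
  m <- mean(x)
  if (n == 1 || sd(x) == 0) return(c(mean = m, lo = m, hi = m, n = n))
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}
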
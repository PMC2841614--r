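#' Write / read cell snapshot tables
#'
#' Snapshots are CSV with columns exactly `time_h, id, x_um, y_um, radius_um,
#' biomass_fg, color, strain, growth_rate_per_h, active` (`active` coded
#' 0/1), so any external tool can re-analyze them.
#'
#' @param cells a cell `data.frame`.
#' @param time_h snapshot time [h].
#' @param path file path.
#' @return `write_snapshot()` invisibly returns `path`; `read_snapshot()`
#'   returns a cell `data.frame` with attribute `time_h`.
#' @export
write_snapshot <- function(cells, time_h, path) {
  out <- data.frame(time_h = time_h, id = cells$id,
                    x_um = cells$x, y_um = cells$y,
                    radius_um = cells$radius, biomass_fg = cells$biomass,
                    color = cells$color, strain = cells$strain,
                    growth_rate_per_h = cells$growth_rate,
                    active = as.integer(cells$active))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "id", "x_um", "y_um", "radius_um", "biomass_fg",
            "color", "strain", "growth_rate_per_h", "active")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("snapshot lacks columns: ", paste(missing, collapse = ", "))
  cells <- data.frame(id = as.integer(d$id), x = d$x_um, y = d$y_um,
                      biomass = d$biomass_fg, radius = d$radius_um,
                      color = as.character(d$color),
                      strain = as.character(d$strain),
                      growth_rate = d$growth_rate_per_h,
                      active = d$active != 0, stringsAsFactors = FALSE)
  attr(cells, "time_h") <- d$time_h[1]
  cells
}

#' Re-analyze an external cell snapshot
#'
#' Computes the metrics layer (segregation index, front height, roughness,
#' active-layer depth) for any snapshot in the standard table format, given
#' either a substrate field file/object or a per-cell substrate vector.
#'
#' @param cells a cell `data.frame` or a path to a snapshot CSV.
#' @param substrate a [solute_field()], a path to a field text file, or a
#'   numeric vector of per-cell substrate concentrations [g/L].
#' @param params a [param_set()] consistent with the snapshot.
#' @param focal_color passed to [segregation_index()].
#' @return a one-row `data.frame` of metrics.
#' @export
reanalyze_snapshot <- function(cells, substrate, params = param_set(),
                               focal_color = "ALL") {
  if (is.character(cells)) cells <- read_snapshot(cells)
  if (is.character(substrate)) substrate <- read_field(substrate)
  G <- if (inherits(substrate, "solute_field"))
    sample_concentration(substrate, cells$x, cells$y) else substrate
  seg <- as.numeric(segregation_index(cells, G, params,
                                      focal_color = focal_color))
  rough <- front_roughness(cells, params)
  data.frame(n_cells = nrow(cells), seg_index = seg,
             front_um = front_height(cells), roughness_um = rough$sd,
             gaps = rough$gaps,
             active_layer_um = active_layer_depth(cells, params))
}

#' Write a run summary as JSON
#'
#' @param trajectory a result of [run_simulation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_summary <- function(trajectory, path) {
  jsonlite::write_json(trajectory$summary, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
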
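#' Plot a cell configuration
#'
#' Draws every cell as a filled circle colored by its lineage label, in
#' physical micrometre coordinates.
#'
#' @param cells a cell `data.frame`.
#' @param params a [param_set()] (sets the domain extent).
#' @param palette named vector mapping color labels to R colors; unknown
#'   labels cycle through a default palette.
#' @param ... passed to [graphics::symbols()].
#' @return invisibly, `cells`.
#' @export
plot_cells <- function(cells, params = param_set(),
                       palette = c(RED = "#d7301f", BLUE = "#0570b0"), ...) {
  labs <- unique(cells$color)
  extra <- setdiff(labs, names(palette))
  if (length(extra))
    palette <- c(palette, setNames(grDevices::hcl.colors(length(extra)),
                                   extra))
  graphics::plot(NA, xlim = c(0, params$width),
                 ylim = c(0, max(front_height(cells) * 1.1, params$h * 2)),
                 xlab = "x [um]", ylab = "y [um]", asp = 1)
  graphics::symbols(cells$x, cells$y, circles = cells$radius,
                    inches = FALSE, add = TRUE,
                    bg = palette[cells$color], fg = NA, ...)
  invisible(cells)
}
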
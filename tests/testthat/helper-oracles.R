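# Independent brute-force oracles, written deliberately in plain nested-loop
# R so they share no code with the implementations they check.

# segregation index oracle: for each focal cell, scan every other cell and
# accumulate activity-weighted same-color frequency
seg_oracle <- function(cells, m, activity_floor, radius, width,
                       periodic = TRUE, focal_color = "ALL",
                       normalize = TRUE) {
  n <- nrow(cells)
  scores <- c()
  for (i in seq_len(n)) {
    if (m[i] < activity_floor) next
    if (!identical(focal_color, "ALL") && cells$color[i] != focal_color) next
    num <- 0; den <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- abs(cells$x[i] - cells$x[j])
      if (periodic) dx <- min(dx, width - dx)
      dy <- cells$y[i] - cells$y[j]
      if (sqrt(dx^2 + dy^2) > radius) next
      g <- as.numeric(cells$color[j] == cells$color[i])
      num <- num + g * m[j]
      den <- den + m[j]
      cnt <- cnt + 1
    }
    if (normalize) {
      if (den > 0) scores <- c(scores, num / den)
    } else if (cnt > 0) scores <- c(scores, num / cnt)
  }
  mean(scores)
}

# largest pairwise overlap, O(n^2)
max_overlap_oracle <- function(cells, width, periodic = TRUE) {
  n <- nrow(cells)
  worst <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- abs(cells$x[i] - cells$x[j])
      if (periodic) dx <- min(dx, width - dx)
      d <- sqrt(dx^2 + (cells$y[i] - cells$y[j])^2)
      ov <- cells$radius[i] + cells$radius[j] - d
      if (ov > worst) worst <- ov
    }
  }
  worst
}

# small-domain configuration for fast unit tests
tiny_config <- function(..., n_cells = 8, stop_height = 12,
                        height = 40, max_front_height = 30, width = 40,
                        metrics_every = 1e9) {
  scenario_config(params = param_set(height = height, width = width,
                                     max_front_height = max_front_height),
                  n_cells = n_cells, stop_height = stop_height,
                  metrics_every = metrics_every, ...)
}

# The trend analyses reuse one replicated sweep and one competition grid;
# both are computed lazily, once per test session, at the frozen study
# conditions (package defaults).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function(via = "G_bulk", deltas = c(1, 2, 10)) {
  key <- paste0("sweep_", via)
  if (is.null(.acceptance_cache[[key]])) {
    cfg <- scenario_config(metrics_every = 1e9)
    .acceptance_cache[[key]] <- run_segregation_sweep(
      cfg, deltas = deltas, via = via)
  }
  .acceptance_cache[[key]]
}

acceptance_competition <- function() {
  if (is.null(.acceptance_cache$competition)) {
    cfg <- scenario_config(metrics_every = 1e9)
    .acceptance_cache$competition <- run_competition(cfg)
  }
  .acceptance_cache$competition
}
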
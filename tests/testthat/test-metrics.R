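test_that("metabolic activity is the Monod saturation term", {
  expect_equal(metabolic_activity(c(0, 1, 3), 1), c(0, 0.5, 0.75))
  expect_error(metabolic_activity(-1, 1), "non-negative")
})

test_that("segregation index matches the nested-loop oracle on lattices and clouds", {
  p <- param_set(width = 40, height = 40, max_front_height = 30)
  radius <- 10 * 2 * p$r_div

  for (kind in c("CHECKERBOARD", "HALF_HALF")) {
    fx <- make_fixture(kind, nx = 8, ny = 8, params = p)
    m <- metabolic_activity(fx$G, p$K_G)
    got <- segregation_index(fx$cells, fx$G, p)
    want <- seg_oracle(fx$cells, m, p$activity_floor, radius, p$width)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
  # a fine checkerboard is far less segregated than a half/half split; the
  # lattice must extend beyond the 20-um neighborhood radius for the two
  # layouts to be distinguishable at all
  pw <- param_set(width = 80, height = 40, max_front_height = 30)
  chk <- make_fixture("CHECKERBOARD", nx = 40, ny = 8, params = pw)
  hh <- make_fixture("HALF_HALF", nx = 40, ny = 8, params = pw)
  expect_lt(as.numeric(segregation_index(chk$cells, chk$G, pw)),
            as.numeric(segregation_index(hh$cells, hh$G, pw)))

  # random cloud with graded activity, both normalizations, focal colors
  set.seed(21)
  n <- 80
  cloud <- cell_table(id = seq_len(n), x = runif(n, 0, 40),
                      y = runif(n, 1, 35), biomass = runif(n, 100, 600),
                      color = sample(c("RED", "BLUE", "GREEN"), n, TRUE),
                      strain = "wt", params = p)
  G <- runif(n, 0, 2)
  m <- metabolic_activity(G, p$K_G)
  for (fc in c("ALL", "RED")) {
    for (nr in c(TRUE, FALSE)) {
      got <- segregation_index(cloud, G, p, focal_color = fc, normalize = nr)
      want <- seg_oracle(cloud, m, p$activity_floor, radius, p$width,
                         focal_color = fc, normalize = nr)
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
  }
})

test_that("a monochromatic group is completely segregated", {
  p <- param_set(width = 40, height = 40, max_front_height = 30)
  fx <- make_fixture("MONOLAYER", n_cells = 12, params = p)
  expect_identical(as.numeric(segregation_index(fx$cells, fx$G, p)), 1)
})

test_that("segregation distances wrap across the periodic seam", {
  p <- param_set(width = 60, height = 40, max_front_height = 30)
  # RED pair split across the seam, BLUE pair at centre; with wrap each RED
  # sees only its RED partner (distance 4), without wrap each RED sees nobody
  cells <- cell_table(id = 1:4, x = c(1, 59, 29, 31), y = rep(5, 4),
                      biomass = 300, color = c("RED", "RED", "BLUE", "BLUE"),
                      strain = "wt", params = p)
  G <- rep(10, 4)
  with_wrap <- segregation_index(cells, G, p, periodic_x = TRUE)
  expect_equal(as.numeric(with_wrap), 1, tolerance = 1e-12)
  expect_equal(length(attr(with_wrap, "scores")), 4)
  no_wrap <- segregation_index(cells, G, p, periodic_x = FALSE)
  expect_equal(length(attr(no_wrap, "scores")), 2)  # the REDs drop out
  expect_error(segregation_index(cells, rep(0, 4), p), "active")
})

test_that("fitness counts division rounds per hour", {
  expect_equal(strain_fitness(10, 80, 2), 1.5)  # 3 doublings in 2 h
  expect_equal(strain_fitness(10, 10, 5), 0)
  expect_warning(w <- strain_fitness(10, 0, 1), "extinct")
  expect_identical(w, -Inf)
  expect_error(strain_fitness(0, 10, 1), "N_start")
  expect_error(strain_fitness(10, 10, 0), "duration")
  expect_equal(relative_fitness(1.5, 1.2), 1.25)
  expect_error(relative_fitness(1, 0), "undefined")
  expect_error(relative_fitness(1, -Inf), "undefined")
})

test_that("front roughness separates flat films from gapped towers", {
  p <- param_set(width = 40, height = 60, max_front_height = 50)
  flat <- make_fixture("MONOLAYER", n_cells = 20, params = p)$cells
  r <- front_roughness(flat, p)
  expect_equal(r$sd, 0)
  expect_identical(r$gaps, 0L)
  # two towers of different heights, empty channels between them
  tw <- make_fixture("TOWERS", nx = 2, ny = 8, gap = 16, params = p)$cells
  tw2 <- tw
  tw2$y[tw2$color == "BLUE"] <- tw2$y[tw2$color == "BLUE"] / 2  # shorter tower
  r2 <- front_roughness(tw2, p, bin_width = 2)
  expect_gt(r2$gaps, 0)
  expect_gt(r2$sd, 0)
  # hand-checked: heights per occupied bin, sd over them
  occ <- r2$heights[!is.na(r2$heights)]
  expect_equal(r2$sd, sd(occ))
  expect_error(front_roughness(flat[0, ], p), "at least one")
})

test_that("active layer depth measures the growing band and vanishes when growth stops", {
  p <- param_set(width = 40, height = 60, max_front_height = 50)
  fx <- make_fixture("CHECKERBOARD", nx = 8, ny = 10, params = p)
  cells <- fx$cells
  # everybody growing: depth equals the full column height
  cells$growth_rate <- p$mu_max
  expect_equal(active_layer_depth(cells, p),
               max(cells$y + cells$radius) - min(cells$y), tolerance = 1e-9)
  # only the top row grows: shallow layer
  cells$growth_rate <- ifelse(cells$y > 17, p$mu_max, 0.01 * p$mu_max)
  d_top <- active_layer_depth(cells, p)
  expect_lt(d_top, 4)
  expect_gt(d_top, 0)
  # nobody grows
  cells$growth_rate <- 0
  expect_equal(active_layer_depth(cells, p), 0)
  expect_error(active_layer_depth(cells, p, threshold_fraction = 0), "threshold")
})
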
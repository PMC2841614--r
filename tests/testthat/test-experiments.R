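test_that("scenario configuration is validated up front", {
  p <- param_set(height = 40, max_front_height = 30, width = 40)
  expect_error(scenario_config(params = p, fractions = c(RED = 0.6, BLUE = 0.6)),
               "sum to 1")
  expect_error(scenario_config(params = p, stop_height = 60),
               "max_front_height")
  expect_error(scenario_config(
    params = p,
    strains = list(a = strain_phenotype("a"), b = strain_phenotype("b")),
    strain_map = c(RED = "a", BLUE = "zzz")), "unknown")
  expect_error(scenario_config(
    params = p, stop_height = 20,
    strains = list(a = strain_phenotype("a", K_G = 0.01),
                   b = strain_phenotype("b", K_G = 0.02)),
    strain_map = c(RED = "a", BLUE = "b")), "K_G")
})

test_that("replicate seeds are deterministic, distinct, and in integer range", {
  s1 <- replicate_seed(1, 2, 3)
  expect_identical(s1, replicate_seed(1, 2, 3))
  expect_true(is.integer(s1))
  grid <- expand.grid(ci = 1:5, r = 1:10)
  seeds <- mapply(replicate_seed, 123, grid$ci, grid$r)
  expect_equal(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds >= 0 & seeds < .Machine$integer.max))
  big <- replicate_seed(.Machine$integer.max - 1, 100, 5)
  expect_true(big >= 0 && big < .Machine$integer.max)
})

test_that("config hashes are stable fingerprints", {
  cfg <- tiny_config()
  h <- activelayer:::config_hash(cfg)
  expect_match(h, "^[0-9a-f]{8}$")
  expect_identical(h, activelayer:::config_hash(cfg))
  cfg2 <- tiny_config(n_cells = 9)
  expect_false(identical(h, activelayer:::config_hash(cfg2)))
})

test_that("one step grows, divides, relaxes, and re-solves consistently", {
  cfg <- tiny_config(n_cells = 8, stop_height = 20)
  state <- activelayer:::init_state(cfg, seed = 2)
  expect_equal(nrow(state$cells), 8)
  expect_true(all(state$fields$G$values >= 0))
  s2 <- simulate_step(state)
  expect_gt(sum(s2$cells$biomass), sum(state$cells$biomass))
  expect_gt(s2$time, 0)
  expect_equal(s2$iter, 1L)
  # the Euler cap holds exactly: max(mu) * dt == dt_frac
  expect_equal(max(s2$cells$growth_rate) * s2$time,
               cfg$params$dt_frac, tolerance = 1e-12)
  expect_lte(max_overlap_oracle(s2$cells, cfg$params$width),
             cfg$params$relax_tol + 1e-12)
})

test_that("agent-side growth equals yield times field-side consumption, step by step", {
  cfg <- tiny_config(n_cells = 8, stop_height = 25)
  state <- activelayer:::init_state(cfg, seed = 4)
  for (i in 1:20) {
    before <- sum(state$cells$biomass)
    consumed0 <- state$consumed
    state <- simulate_step(state)
    gained <- sum(state$cells$biomass) - before
    eaten <- state$consumed - consumed0
    expect_equal(gained, cfg$params$Y * eaten,
                 tolerance = 1e-10)
  }
})

test_that("a finished run reports consistent bookkeeping", {
  cfg <- tiny_config(n_cells = 8, stop_height = 15)
  tr <- run_simulation(cfg, seed = 1)
  s <- tr$summary
  expect_gte(s$front_um, 15)
  expect_false(s$stalled)
  expect_equal(nrow(tr$snapshots$final), sum(unlist(s$n_end)))
  expect_equal(s$biomass_end_fg, sum(tr$snapshots$final$biomass))
  # fitness recomputes from the reported counts and duration
  expect_equal(s$fitness$wt,
               strain_fitness(sum(unlist(s$n_start)), sum(unlist(s$n_end)),
                              s$duration_h), tolerance = 1e-12)
  # metric trace is monotone in time and ends at the final state
  expect_true(all(diff(tr$metrics$time_h) >= 0))
  expect_equal(tail(tr$metrics$n_cells, 1), nrow(tr$snapshots$final))
  # hitting the iteration cap is reported as a stalled run
  expect_warning(tr2 <- run_simulation(tiny_config(n_cells = 4, stop_height = 25,
                                                   max_iters = 3), seed = 1),
                 "stalled")
  expect_true(tr2$summary$stalled)
  expect_equal(tr2$summary$iters, 3L)
})

test_that("identical config and seed give bit-identical runs at small scale", {
  cfg <- tiny_config(n_cells = 8, stop_height = 15)
  a <- run_simulation(cfg, seed = 9)
  b <- run_simulation(cfg, seed = 9)
  expect_identical(a$snapshots$final, b$snapshots$final)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final_fields$G$values, b$final_fields$G$values)
  c_ <- run_simulation(cfg, seed = 10)
  expect_false(identical(a$snapshots$final, c_$snapshots$final))
})

test_that("sweep and competition drivers return tidy replicated results", {
  cfg <- tiny_config(n_cells = 6, stop_height = 10, base_seed = 5)
  sw <- run_segregation_sweep(cfg, deltas = c(2, 10), replicates = 2)
  expect_equal(nrow(sw$runs), 4)
  expect_true(all(c("seg_index", "roughness_um", "gaps", "rel_fitness") %in%
                    names(sw$runs)))
  expect_equal(sw$summary$delta, c(2, 10))
  expect_true(all(is.finite(sw$runs$seg_index)))
  expect_true(all(sw$runs$front_um >= 10))
  # same base seed reproduces the whole sweep
  sw2 <- run_segregation_sweep(cfg, deltas = c(2, 10), replicates = 2)
  expect_identical(sw$runs, sw2$runs)

  cp <- run_competition(cfg, R_E_grid = c(0, 1), deltas = 10,
                        replicates = 2, stop_heights = c("10" = 10))
  expect_equal(nrow(cp$runs), 4)
  expect_equal(cp$summary$R_E, c(0, 1))
  expect_true(all(cp$runs$n_coop_start + cp$runs$n_expl_start == 6))
  expect_error(run_competition(cfg, fractions = c(RED = 1, GREEN = 0)),
               "RED")
})

test_that("snapshots, fields, and summaries round-trip through the io layer", {
  cfg <- tiny_config(n_cells = 6, stop_height = 10)
  tr <- run_simulation(cfg, seed = 3)
  snap <- tempfile(fileext = ".csv")
  write_snapshot(tr$snapshots$final, tr$summary$duration_h, snap)
  back <- read_snapshot(snap)
  expect_equal(back$x, tr$snapshots$final$x, tolerance = 1e-9)
  expect_equal(back$biomass, tr$snapshots$final$biomass, tolerance = 1e-9)
  expect_identical(back$color, tr$snapshots$final$color)
  expect_equal(attr(back, "time_h"), tr$summary$duration_h, tolerance = 1e-9)

  js <- tempfile(fileext = ".json")
  write_run_summary(tr, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$front_um, tr$summary$front_um, tolerance = 1e-9)
  expect_equal(parsed$config_hash, tr$summary$config_hash)

  # re-analysis of the written snapshot agrees with the in-memory metrics
  fld <- tempfile(fileext = ".txt")
  write_field(tr$final_fields$G, fld)
  re <- reanalyze_snapshot(snap, fld, cfg$params)
  expect_equal(re$n_cells, nrow(tr$snapshots$final))
  expect_equal(re$front_um, tr$summary$front_um, tolerance = 1e-6)
  unlink(c(snap, js, fld))
})

test_that("the command-line interface runs a configured simulation end to end", {
  out <- tempfile("cli")
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c(
    "params:",
    "  width: 40",
    "  height: 40",
    "  max_front_height: 30",
    "scenario:",
    "  n_cells: 6",
    "  stop_height: 10",
    "  metrics_every: 1000000"
  ), cfgfile)
  code <- suppressMessages(cli_main(c("run", "--config", cfgfile,
                                      "--out", out, "--seed", "2")))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "cells_final.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  # unknown subcommand fails politely with a nonzero code
  expect_message(bad <- cli_main("frobnicate"), "unknown")
  expect_identical(bad, 1L)
  unlink(c(out, cfgfile), recursive = TRUE)
})
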
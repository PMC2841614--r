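#' Configuration for a simulation scenario
#'
#' Bundles the parameter set, the strain roster with initial color fractions,
#' the growth condition, and the stopping/recording policy of a run.
#'
#' @param params a [param_set()].
#' @param condition `"surface"` (growth on a flat floor, substrate from
#'   above, periodic x) or `"radial"` (immersed cluster, substrate from all
#'   directions, open domain).
#' @param strains named list of [strain_phenotype()] objects.
#' @param fractions named numeric vector of initial color fractions summing
#'   to 1.
#' @param strain_map named character vector mapping each color to a strain
#'   name in `strains`.
#' @param n_cells number of founder cells. The default 6 founders on a
#'   100-um domain (mean spacing ~17 um, comfortably wider than twice the
#'   shallowest default active layer) seeds well-separated lineages, so the
#'   low-delta regime can express the full clonal-sector phenomenology —
#'   monoclonal towers, inter-tower gaps, founder-effect variance — instead
#'   of starting from an already space-filling lawn.
#' @param stop_height stop when the front reaches this height (surface) or
#'   radial extent [um]; must not exceed `params$max_front_height`.
#' @param max_iters iteration cap; hitting it flags the run as stalled.
#' @param metrics_every record the metrics row every this many iterations
#'   (the final state is always recorded).
#' @param snapshot_every keep a cell snapshot every this many iterations;
#'   0 keeps only the initial and final snapshots.
#' @param base_seed integer; replicate r of condition c runs with seed
#'   `base_seed + 7919 * c + r`, so replicate seeds are distinct.
#' @param replicates default replicate count for the sweep/competition
#'   drivers.
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(params = param_set(),
                            condition = c("surface", "radial"),
                            strains = list(wt = strain_phenotype("wt")),
                            fractions = c(RED = 0.5, BLUE = 0.5),
                            strain_map = NULL,
                            n_cells = 6, stop_height = 50,
                            max_iters = 5000, metrics_every = 50,
                            snapshot_every = 0,
                            base_seed = 1, replicates = 10) {
  condition <- match.arg(condition)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(strain_map)) {
    if (length(strains) == 1)
      strain_map <- setNames(rep(names(strains), length(fractions)),
                             names(fractions))
    else if (length(strains) == length(fractions))
      strain_map <- setNames(names(strains), names(fractions))
    else stop("supply strain_map when strains and colors differ in number")
  }
  if (!all(strain_map %in% names(strains)))
    stop("strain_map refers to unknown strains")
  if (stop_height > params$max_front_height)
    stop("stop_height exceeds params$max_front_height")
  K <- vapply(strains, function(s) resolve_strain(s, params)$K_G, numeric(1))
  if (length(unique(K)) > 1)
    stop("all strains in one simulation must share K_G ",
         "(the lattice sink uses a single half-saturation constant)")
  structure(list(params = params, condition = condition, strains = strains,
                 fractions = fractions, strain_map = strain_map,
                 n_cells = n_cells, stop_height = stop_height,
                 max_iters = max_iters, metrics_every = metrics_every,
                 snapshot_every = snapshot_every, base_seed = base_seed,
                 replicates = replicates),
            class = "scenario_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  # FNV-1a on 32-bit state carried in a double; R's bitwXor only takes
  # 32-bit signed ints, so xor the two 16-bit halves separately and reduce
  # the multiply mod 2^32 exactly (all intermediates stay below 2^53)
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- (lo * 16777619 + (hi * 1048576) %% 4294967296) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# --- internal stepping machinery ------------------------------------------

# per-node Michaelis-Menten sink capacity A [g/L/h] given current enzyme
sink_capacity <- function(biomass, strains, params, E_values) {
  A <- matrix(0, biomass$grid$nx, biomass$grid$ny)
  for (nm in names(biomass$by_strain)) {
    s <- resolve_strain(strains[[nm]], params)
    ben <- matrix(1, nrow(A), ncol(A))
    if (!is.null(E_values)) {
      full <- if (s$benefit_mode == "one_plus_b") 1 + s$B else s$B
      ben[E_values >= s$tau] <- full
    }
    A <- A + s$mu_max * (1 - s$C * s$R_E) * ben * biomass$by_strain[[nm]] / s$Y
  }
  A
}

enzyme_source <- function(biomass, strains) {
  Q <- matrix(0, biomass$grid$nx, biomass$grid$ny)
  for (nm in names(biomass$by_strain)) {
    s <- strains[[nm]]
    if (s$cooperator && s$R_E > 0)
      Q <- Q + s$R_E * biomass$by_strain[[nm]]
  }
  Q
}

# refresh masks, solve both fields against the current cells, and return the
# updated state with the total substrate sink rate [fg/h] recorded
update_fields <- function(state) {
  cfg <- state$config; p <- cfg$params
  biomass <- rasterize_biomass(state$cells, state$grid, p)
  mask <- compute_bulk_mask(biomass, p$h, cfg$condition, rule = p$bulk_rule)

  # the enzyme field does not depend on the substrate, so it is solved first:
  # the substrate sink capacity then uses the same enzyme field the cells
  # will sample in the next growth step, closing the mass balance
  if (state$has_enzyme) {
    E <- state$fields$E
    E$bulk_mask <- mask
    E$values[mask] <- 0
    Q <- enzyme_source(biomass, state$strains)
    E <- solve_reaction_diffusion(E, D = p$D_E, Q = Q,
                                  tol = p$solve_tol,
                                  max_sweeps = p$solve_max_sweeps,
                                  omega = p$sor_omega)
    state$fields$E <- E
  }

  G <- state$fields$G
  G$bulk_mask <- mask
  G$values[mask] <- G$bulk_value
  E_vals <- if (!is.null(state$fields$E)) state$fields$E$values else NULL
  A <- sink_capacity(biomass, state$strains, p, E_vals)
  G <- solve_reaction_diffusion(G, D = p$D_G, A = A, K = p$K_G,
                                tol = p$solve_tol,
                                max_sweeps = p$solve_max_sweeps,
                                omega = p$sor_omega)
  state$fields$G <- G
  # sink from the field side, for the independent mass balance
  GV <- G$values
  state$sink_total <- sum(A * GV / (p$K_G + GV)) * biomass$node_volume
  state$biomass_field <- biomass
  state
}

init_state <- function(config, seed) {
  p <- config$params
  cells <- init_monolayer(config$n_cells, config$fractions,
                          strain_map = config$strain_map, params = p,
                          seed = seed, condition = config$condition)
  grid <- grid_from_params(p, config$condition)
  has_enzyme <- any(vapply(config$strains,
                           function(s) s$cooperator && s$R_E > 0, logical(1)))
  fields <- list(
    G = solute_field(grid, "substrate", bulk_value = p$G_bulk),
    E = if (has_enzyme)
      solute_field(grid, "enzyme", bulk_value = 0,
                   values = matrix(0, grid$nx, grid$ny)) else NULL)
  strains <- lapply(config$strains, resolve_strain, params = p)
  state <- list(cells = cells, fields = fields, grid = grid,
                strains = strains, config = config,
                next_id = as.integer(nrow(cells) + 1L),
                time = 0, iter = 0L, consumed = 0,
                has_enzyme = has_enzyme, stalled = FALSE)
  update_fields(state)
}

front_extent <- function(cells, config) {
  if (config$condition == "surface") return(front_height(cells))
  cx <- config$params$width / 2; cy <- config$params$height / 2
  max(sqrt((cells$x - cx)^2 + (cells$y - cy)^2) + cells$radius)
}

#' Advance a simulation state by one iteration
#'
#' One iteration in the canonical order: sample local substrate and enzyme at
#' each cell centre, compute specific growth rates, Euler-grow all cells with
#' a global `dt` chosen so `max(mu) * dt` equals `params$dt_frac`, divide
#' supercritical cells, relax overlaps, re-rasterize biomass, recompute the
#' bulk mask, and re-solve substrate (then enzyme) to steady state.
#' Deterministic given the R RNG state. Used by [run_simulation()]; exposed
#' for stepwise inspection.
#'
#' @param state a state list from the internals of [run_simulation()].
#' @return the advanced state, with `stalled = TRUE` if no cell can grow.
#' @keywords internal
#' @export
simulate_step <- function(state) {
  cfg <- state$config; p <- cfg$params
  cells <- state$cells
  # growth samples the node that carries each cell's biomass (the same
  # discretization as the uptake sink), so biomass gain and Y * substrate
  # consumed agree to rounding; sample_concentration() stays the smooth
  # analysis-side sampler
  Gc <- sample_nodal(state$fields$G, cells$x, cells$y)
  Ec <- if (state$has_enzyme)
    sample_nodal(state$fields$E, cells$x, cells$y) else rep(0, nrow(cells))
  mu <- numeric(nrow(cells))
  for (nm in unique(cells$strain)) {
    sel <- cells$strain == nm
    mu[sel] <- specific_growth_rate(state$strains[[nm]], Gc[sel], Ec[sel])
  }
  mumax <- max(mu)
  if (mumax < 1e-8) { state$stalled <- TRUE; return(state) }
  dt <- p$dt_frac / mumax

  # substrate consumed this step, accounted from the solved field's sink side
  state$consumed <- state$consumed + state$sink_total * dt

  cells <- grow_cells(cells, mu, dt, p)
  cells$active <- metabolic_activity(Gc, p$K_G) >= p$activity_floor
  div <- divide_cells(cells, p, state$next_id)
  cells <- relax_overlaps(div$cells, p, condition = cfg$condition)
  state$cells <- cells
  state$next_id <- div$next_id
  state$time <- state$time + dt
  state$iter <- state$iter + 1L
  update_fields(state)
}

metrics_row <- function(state) {
  cfg <- state$config
  cells <- state$cells
  rough <- front_roughness(cells, cfg$params)
  seg <- tryCatch(
    as.numeric(segregation_index(
      cells, state$fields$G, cfg$params,
      periodic_x = cfg$condition == "surface")),
    error = function(e) NA_real_)
  counts <- table(factor(cells$color, levels = names(cfg$fractions)))
  out <- data.frame(time_h = state$time, iter = state$iter,
                    n_cells = nrow(cells),
                    front_um = front_extent(cells, cfg),
                    roughness_um = rough$sd, gaps = rough$gaps,
                    seg_index = seg,
                    mean_mu = mean(cells$growth_rate),
                    active_frac = mean(cells$active),
                    total_biomass_fg = sum(cells$biomass),
                    substrate_consumed_fg = state$consumed)
  for (col in names(counts)) out[[paste0("n_", col)]] <- as.integer(counts[[col]])
  out
}

#' Run a growth simulation to the stop height
#'
#' Iterates [simulate_step()] from a seeded mixed monolayer until the front
#' reaches `stop_height` or the iteration cap is hit (a legitimate stalled
#' outcome at very low delta, flagged in the summary). Metrics are recorded
#' every `metrics_every` iterations and at the end; snapshots per
#' `snapshot_every`.
#'
#' @param config a [scenario_config()].
#' @param seed integer RNG seed; identical `(config, seed)` give bit-identical
#'   trajectories.
#' @return an object of class `"trajectory"`: list with `metrics` (data.frame
#'   of per-time records), `snapshots` (named list of cell tables),
#'   `final_fields`, `summary` (per-strain counts and fitness, final
#'   segregation index, delta, front statistics, mass balance, provenance),
#'   `config`, and `seed`.
#' @examples
#' \donttest{
#' cfg <- scenario_config(params = param_set(height = 30, max_front_height = 20),
#'                        n_cells = 20, stop_height = 10, base_seed = 1)
#' tr <- run_simulation(cfg, seed = 1)
#' tr$summary$front_um
#' }
#' @export
run_simulation <- function(config, seed) {
  state <- init_state(config, seed)
  metrics <- list(metrics_row(state))
  snaps <- list(initial = state$cells)
  n_start <- table(factor(state$cells$strain, levels = names(config$strains)))
  col_start <- table(factor(state$cells$color, levels = names(config$fractions)))

  while (front_extent(state$cells, config) < config$stop_height &&
         state$iter < config$max_iters) {
    state <- simulate_step(state)
    if (state$stalled) break
    if (state$iter %% config$metrics_every == 0)
      metrics[[length(metrics) + 1L]] <- metrics_row(state)
    if (config$snapshot_every > 0 &&
        state$iter %% config$snapshot_every == 0)
      snaps[[sprintf("iter_%06d", state$iter)]] <- state$cells
  }
  metrics[[length(metrics) + 1L]] <- metrics_row(state)
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[!duplicated(metrics$iter), , drop = FALSE]
  snaps$final <- state$cells

  n_end <- table(factor(state$cells$strain, levels = names(config$strains)))
  col_end <- table(factor(state$cells$color, levels = names(config$fractions)))
  dur <- state$time
  W <- if (dur > 0)
    setNames(vapply(names(config$strains), function(nm)
      suppressWarnings(strain_fitness(max(n_start[[nm]], 1), n_end[[nm]], dur)),
      numeric(1)), names(config$strains))
  else setNames(rep(NA_real_, length(config$strains)), names(config$strains))

  final <- metrics[nrow(metrics), ]
  summary <- list(
    n_start = as.list(n_start), n_end = as.list(n_end),
    color_start = as.list(col_start), color_end = as.list(col_end),
    fitness = as.list(W), duration_h = dur, iters = state$iter,
    seg_index = final$seg_index, front_um = final$front_um,
    roughness_um = final$roughness_um, gaps = final$gaps,
    delta = delta_number(config$params),
    biomass_start_fg = sum(snaps$initial$biomass),
    biomass_end_fg = sum(state$cells$biomass),
    substrate_consumed_fg = state$consumed,
    stalled = state$stalled || state$iter >= config$max_iters,
    config_hash = config_hash(config), seed = seed)
  if (summary$stalled)
    warning("run stalled before reaching stop height (iter cap or no growth)")

  structure(list(metrics = metrics, snapshots = snaps,
                 final_fields = state$fields, summary = summary,
                 config = config, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<trajectory> delta=%.3g  %d iters, %.2f h, %d cells, front %.1f um\n",
    s$delta, s$iters, s$duration_h, nrow(x$snapshots$final), s$front_um))
  cat(sprintf("  seg index %.3f | roughness %.2f um | gaps %d%s\n",
              s$seg_index, s$roughness_um, s$gaps,
              if (isTRUE(s$stalled)) " | STALLED" else ""))
  invisible(x)
}

#' Derive a per-replicate seed from a base seed
#'
#' Deterministic seed schedule used by the sweep drivers: condition index and
#' replicate number are folded into the base seed so that every (condition,
#' replicate) pair runs an independent, reproducible stream.
#'
#' @param base integer base seed.
#' @param cond_idx 1-based condition index.
#' @param rep 1-based replicate number.
#' @return an integer seed in `[0, .Machine$integer.max)`.
#' @export
replicate_seed <- function(base, cond_idx, rep)
  as.integer((base + 7919 * cond_idx + rep) %% .Machine$integer.max)

#' Replicated segregation sweep over delta
#'
#' For each target delta and replicate, re-parameterizes via
#' [realize_delta()], runs a full growth simulation, and records the final
#' segregation index, front statistics, and — for the default neutral
#' two-color roster — the relative fitness of the first-listed color against
#' the second, computed from the color counts (`NA` when a color went
#' extinct). The summary gives the mean and a Student-t 95% confidence
#' interval per delta.
#'
#' @param config a [scenario_config()] (neutral two-color roster).
#' @param deltas numeric vector of target delta values.
#' @param via which parameter realizes delta: `"G_bulk"` (default),
#'   `"mu_max"`, or `"D_G"`.
#' @param replicates replicate runs per delta; defaults to
#'   `config$replicates`.
#' @param focal_color color for the final index, or `"ALL"` (default).
#' @return list of class `"sweep_result"` with `runs` (one row per run) and
#'   `summary` (mean, CI per delta).
#' @export
run_segregation_sweep <- function(config, deltas = c(1, 2, 10),
                                  via = c("G_bulk", "mu_max", "D_G"),
                                  replicates = config$replicates,
                                  focal_color = "ALL") {
  via <- match.arg(via)
  if (!length(deltas)) stop("supply at least one delta")
  rows <- list()
  for (ci in seq_along(deltas)) {
    d <- deltas[ci]
    p_d <- realize_delta(config$params, d, via = via)
    cfg_d <- config
    cfg_d$params <- p_d
    for (r in seq_len(replicates)) {
      seed <- replicate_seed(config$base_seed, ci, r)
      tr <- suppressWarnings(run_simulation(cfg_d, seed))
      seg <- tryCatch(as.numeric(segregation_index(
        tr$snapshots$final, tr$final_fields$G, p_d,
        focal_color = focal_color,
        periodic_x = config$condition == "surface")),
        error = function(e) NA_real_)
      # neutral drift readout: per-color fitness from the color counts (the
      # two colors share one strain, so strain-level fitness cannot see them)
      rel_W <- tryCatch({
        cs <- tr$summary$color_start; ce <- tr$summary$color_end
        W <- mapply(function(s, e) strain_fitness(max(s, 1), e,
                                                  tr$summary$duration_h),
                    cs, ce)
        relative_fitness(W[[1]], W[[2]])
      }, error = function(e) NA_real_, warning = function(w) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        delta = d, via = via, replicate = r, seed = seed,
        seg_index = seg, roughness_um = tr$summary$roughness_um,
        gaps = tr$summary$gaps, front_um = tr$summary$front_um,
        rel_fitness = rel_W,
        duration_h = tr$summary$duration_h, stalled = tr$summary$stalled)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$delta), function(df) {
    ci <- t_ci(df$seg_index)
    data.frame(delta = df$delta[1], via = df$via[1],
               mean_seg = ci[["mean"]], ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               mean_roughness = mean(df$roughness_um),
               mean_gaps = mean(df$gaps), n = nrow(df))
  }))
  summ <- summ[order(summ$delta), ]
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "sweep_result")
}

#' Cooperator-versus-exploiter competition
#'
#' Competes an enzyme-secreting cooperator (color BLUE) against a
#' non-secreting exploiter (color RED) from a 1:1 random monolayer, across a
#' grid of enzyme production rates `R_E` and active-layer conditions `delta`.
#' Each run is grown to the stop height, per-strain fitness is computed as
#' division rounds per hour, and the cooperator relative fitness is reported
#' per replicate together with mean/CI summaries.
#'
#' @param config a [scenario_config()] whose `params`, geometry, and stop
#'   rule set the shared conditions (its strain roster is replaced).
#' @param R_E_grid enzyme production rates to compete at.
#' @param deltas active-layer conditions, realized via `via`.
#' @param via parameter realizing delta; default `"G_bulk"`.
#' @param replicates replicates per (delta, R_E) cell.
#' @param B,C,tau,benefit_mode social parameters passed to
#'   [strain_phenotype()].
#' @param fractions initial color fractions; default 1:1.
#' @param stop_heights optional named vector of per-condition stop heights
#'   [um] overriding `config$stop_height`; keys are either
#'   `"<delta>"` (whole condition) or `"<delta>:<R_E>"` (single cell, takes
#'   precedence). The default races the focal low-delta secretion cell
#'   (`delta = 1`, `R_E = 0.5`) to 100 um — the cooperator's advantage
#'   builds during the clonal tower-overtopping phase, which only develops
#'   well past the monolayer stage — and a hypothetical `delta = 2`
#'   condition likewise; the `delta = 10` cells stop at 50 um, where the
#'   well-mixed outcome is already asymptotic (truncation moves its
#'   relative fitness toward 1, i.e. is conservative for the expected
#'   cooperator loss), and the remaining `delta = 1` cells, which carry no
#'   headline claim, stop at 30 um to bound compute.
#' @return list of class `"competition_result"` with `runs` and `summary`.
#' @export
run_competition <- function(config, R_E_grid = c(0, 0.5, 1, 1.5, 2),
                            deltas = c(10, 1),
                            via = c("G_bulk", "mu_max", "D_G"),
                            replicates = config$replicates,
                            B = 3, C = 0.3, tau = 0.1,
                            benefit_mode = "one_plus_b",
                            fractions = c(RED = 0.5, BLUE = 0.5),
                            stop_heights = c("10" = 50, "2" = 100, "1" = 30,
                                             "1:0.5" = 100)) {
  via <- match.arg(via)
  if (!setequal(names(fractions), c("RED", "BLUE")))
    stop("competition uses colors RED (exploiter) and BLUE (cooperator)")
  if (any(fractions <= 0)) stop("both strains must be present at t0")
  rows <- list()
  ci_idx <- 0L
  for (d in deltas) {
    p_d <- realize_delta(config$params, d, via = via)
    for (re in R_E_grid) {
      ci_idx <- ci_idx + 1L
      stop_d <- config$stop_height
      if (!is.null(stop_heights)) {
        key_cell <- paste0(format(d), ":", format(re))
        key_delta <- as.character(d)
        if (key_cell %in% names(stop_heights))
          stop_d <- stop_heights[[key_cell]]
        else if (key_delta %in% names(stop_heights))
          stop_d <- stop_heights[[key_delta]]
      }
      strains <- list(
        coop = strain_phenotype("coop", cooperator = TRUE, R_E = re,
                                B = B, C = C, tau = tau,
                                benefit_mode = benefit_mode),
        expl = strain_phenotype("expl", cooperator = FALSE, B = B, C = C,
                                tau = tau, benefit_mode = benefit_mode))
      cfg <- config
      cfg$params <- p_d
      cfg$strains <- strains
      cfg$fractions <- fractions
      cfg$strain_map <- c(RED = "expl", BLUE = "coop")
      cfg$stop_height <- stop_d
      for (r in seq_len(replicates)) {
        seed <- replicate_seed(config$base_seed, ci_idx, r)
        tr <- suppressWarnings(run_simulation(cfg, seed))
        W_c <- tr$summary$fitness$coop
        W_e <- tr$summary$fitness$expl
        rel <- tryCatch(relative_fitness(W_c, W_e), error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          delta = d, R_E = re, replicate = r, seed = seed,
          n_coop_start = tr$summary$n_start$coop,
          n_expl_start = tr$summary$n_start$expl,
          n_coop_end = tr$summary$n_end$coop,
          n_expl_end = tr$summary$n_end$expl,
          W_coop = W_c, W_expl = W_e, rel_fitness = rel,
          duration_h = tr$summary$duration_h, stalled = tr$summary$stalled)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(runs, interaction(runs$delta, runs$R_E, drop = TRUE)),
    function(df) {
      ci <- t_ci(df$rel_fitness)
      data.frame(delta = df$delta[1], R_E = df$R_E[1],
                 mean_rel_fitness = ci[["mean"]],
                 ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], n = nrow(df))
    }))
  summ <- summ[order(summ$delta, summ$R_E), ]
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "competition_result")
}
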
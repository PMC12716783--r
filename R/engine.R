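#' Named experiment presets
#'
#' The five standard experiments: three Neanderthal scenarios spanning high,
#' central and low demographic vigour, the central Aurignacian (modern human)
#' scenario and the central admixed-population scenario. All share the drift
#' coefficient alpha = 1250 km^2/yr^2 and velocity noise sigma = 15 km/yr and
#' differ in cultural carrying capacity C (PDU) and growth rate ro (1/yr):
#' ExpNEA-H (3, 0.05), ExpNEA-C (2, 0.02), ExpNEA-L (1, 0.01),
#' ExpAUR-C (3, 0.02), ExpMIX-C (2, 0.02).
#'
#' @param name preset name
#' @return list with `pop` ([population_params()]), `mobility`
#'   ([mobility_params()]) and `population` label
#' @export
preset_params <- function(name = c("ExpNEA-H", "ExpNEA-C", "ExpNEA-L",
                                   "ExpAUR-C", "ExpMIX-C")) {
  name <- match.arg(name)
  tab <- list(
    "ExpNEA-H" = list(C = 3, ro = 0.05, population = "NEA"),
    "ExpNEA-C" = list(C = 2, ro = 0.02, population = "NEA"),
    "ExpNEA-L" = list(C = 1, ro = 0.01, population = "NEA"),
    "ExpAUR-C" = list(C = 3, ro = 0.02, population = "AMH"),
    "ExpMIX-C" = list(C = 2, ro = 0.02, population = "MIX"))
  p <- tab[[name]]
  list(name = name,
       population = p$population,
       pop = population_params(C = p$C, ro = p$ro),
       mobility = mobility_params())  # alpha = 2.5*500/1 = 1250, sigma = 15
}

#' Agent density field in PDU
#'
#' Counts alive agents per cell and converts to humans per 100 km^2: for the
#' default 20 km cells (400 km^2) the density is count/4.
#'
#' @param agents agent data.frame
#' @param grid a [grid_spec()]
#' @param smooth apply one 3x3 uniform smoothing pass (default FALSE)
#' @return matrix (ny, nx) of density, PDU
#' @export
density_field <- function(agents, grid, smooth = FALSE) {
  ncell <- grid$nx * grid$ny
  counts <- if (nrow(agents)) {
    idx <- cell_index(grid, agents$x, agents$y)
    tabulate(idx$cell[!is.na(idx$cell)], nbins = ncell)
  } else integer(ncell)
  rho <- matrix(counts * 100 / grid$cell_size^2, grid$ny, grid$nx)
  if (smooth) rho <- smooth3x3(rho)
  rho
}

#' Initialize agents around Gaussian population centres
#'
#' N0 humans per centre, positions Gaussian with the given standard
#' deviation; draws landing on sea or outside the domain are redrawn so each
#' centre contributes exactly its N0. Initial velocities have random
#' direction and magnitude `sigma`.
#'
#' @param centers data.frame with `x`, `y` (km) or `lon`, `lat` (degrees),
#'   `n0` and `std` (km, or degrees when `std_deg = TRUE`)
#' @param grid a [grid_spec()]
#' @param land_mask logical matrix; NULL = all land
#' @param sigma initial speed, km/yr
#' @param population population label (default "NEA")
#' @param std_deg interpret `std` in degrees and convert via the grid's
#'   transform (default TRUE when centres are given in lon/lat)
#' @param first_id id of the first agent (default 1)
#' @return agent data.frame: id, population, x, y, u, v, alive
#' @export
init_population <- function(centers, grid, land_mask = NULL, sigma = 15,
                            population = "NEA", std_deg = NULL,
                            first_id = 1L) {
  lonlat <- all(c("lon", "lat") %in% names(centers))
  if (is.null(std_deg)) std_deg <- lonlat
  if (lonlat) {
    km <- lonlat_to_km(grid, centers$lon, centers$lat)
    cx <- km$x; cy <- km$y
  } else {
    cx <- centers$x; cy <- centers$y
  }
  sc <- deg_to_km_scale(grid)
  xs <- ys <- numeric(0)
  for (k in seq_len(nrow(centers))) {
    sx <- if (std_deg) centers$std[k] * sc$kx else centers$std[k]
    sy <- if (std_deg) centers$std[k] * sc$ky else centers$std[k]
    # warn when the centre is mostly over water
    probe_x <- stats::rnorm(200, cx[k], sx)
    probe_y <- stats::rnorm(200, cy[k], sy)
    if (mean(.is_land(land_mask, grid, probe_x, probe_y)) < 0.5) {
      warnf("centre %d: less than 50%% land within its spread", k)
    }
    need <- centers$n0[k]
    got_x <- got_y <- numeric(0)
    while (length(got_x) < need) {
      m <- max(need * 2, 100)
      px <- stats::rnorm(m, cx[k], sx)
      py <- stats::rnorm(m, cy[k], sy)
      ok <- .is_land(land_mask, grid, px, py)
      got_x <- c(got_x, px[ok]); got_y <- c(got_y, py[ok])
    }
    xs <- c(xs, got_x[seq_len(need)]); ys <- c(ys, got_y[seq_len(need)])
  }
  n <- length(xs)
  ang <- stats::runif(n, 0, 2 * pi)
  data.frame(id = first_id + seq_len(n) - 1L,
             population = rep(population, n),
             x = xs, y = ys,
             u = sigma * cos(ang), v = sigma * sin(ang),
             alive = rep(TRUE, n), stringsAsFactors = FALSE)
}

#' Assemble a simulation scenario
#'
#' @param grid a [grid_spec()]
#' @param land_mask logical matrix, TRUE = land
#' @param populations named list (names = population labels); each element a
#'   list with `pop` ([population_params()]), `mobility`
#'   ([mobility_params()]), `phi_ac` (named list of [raster_field()]s, one
#'   per climate period), `centers` (init table for [init_population()]) and
#'   optional `t_start` (yr; agents enter the simulation then)
#' @param timeline data.frame with `t_start` (yr) and `period` (label into
#'   `phi_ac`), ordered; the active accessible-HEP field switches discretely
#'   at these times
#' @param t_end end time, yr
#' @param dt step, yr (default 1)
#' @param admixture an [admixture_config()] or NULL; requires populations
#'   "NEA" and "AMH"; offspring use the "MIX" population entry (its `phi_ac`
#'   defaults to the parents' mean per period)
#' @param spinup_exclude initial years excluded from summary statistics
#'   (default 300)
#' @param record_every snapshot cadence in steps (default 50; 0 = none)
#' @return object of class `scenario`
#' @export
scenario <- function(grid, land_mask, populations, timeline, t_end,
                     dt = 1, admixture = NULL, spinup_exclude = 300,
                     record_every = 50) {
  if (is.unsorted(timeline$t_start)) stopf("timeline must be ordered")
  for (nm in names(populations)) {
    p <- populations[[nm]]
    missing_periods <- setdiff(timeline$period, names(p$phi_ac %||% list()))
    if (nm != "MIX" && length(missing_periods)) {
      stopf("population %s lacks phi_ac for period(s): %s", nm,
            paste(missing_periods, collapse = ", "))
    }
  }
  if (!is.null(admixture)) {
    if (!all(c("NEA", "AMH") %in% names(populations))) {
      stopf("admixture requires NEA and AMH populations")
    }
    if (!"MIX" %in% names(populations)) {
      stopf("admixture requires a MIX population entry (params for offspring)")
    }
    if (is.null(populations$MIX$phi_ac)) {
      populations$MIX$phi_ac <- lapply(
        stats::setNames(timeline$period, timeline$period),
        function(per) mix_accessible_hep(populations$NEA$phi_ac[[per]],
                                         populations$AMH$phi_ac[[per]]))
    }
  }
  structure(list(grid = grid, land_mask = land_mask,
                 populations = populations, timeline = timeline,
                 t_end = t_end, dt = dt, admixture = admixture,
                 spinup_exclude = spinup_exclude,
                 record_every = record_every),
            class = "scenario")
}

# period label active at time t
.active_period <- function(timeline, t) {
  k <- findInterval(t, timeline$t_start)
  timeline$period[max(k, 1L)]
}

#' Run one simulation
#'
#' Per step and population: (1) bin agents and compute the (smoothed) density
#' field; (2) build the demography fields rho_c, f_pa and Phi_Av from the
#' period-active accessible HEP; (3) move agents (drifted random walk plus
#' reflection); (4) apply births and deaths; (5) sample admixture if enabled;
#' (6) record. Accessible-HEP fields switch discretely at timeline
#' boundaries.
#'
#' @param scn a [scenario()]
#' @param seed master seed for this run
#' @param overrides optional named list of per-population parameter
#'   overrides, e.g. `list(NEA = list(pop = ..., mobility = ...))` (used by
#'   the ensemble driver)
#' @param p_adm_override optional admixture probability override
#' @param step_order "motion_first" (default: move, then births/deaths) or
#'   "demography_first"; exposed to verify that the arbitrary choice of
#'   update order does not materially change equilibria
#' @return object of class `sim_output`: `times`, `pop_size` (matrix time x
#'   population), `events` (births/deaths per step), `snapshots` (list of
#'   density matrices per population at cadence, with `snap_times`), `agents`
#'   (final state), `n_fallback`
#' @export
run_simulation <- function(scn, seed = 1, overrides = NULL,
                           p_adm_override = NULL,
                           step_order = c("motion_first", "demography_first")) {
  step_order <- match.arg(step_order)
  grid <- scn$grid; dt <- scn$dt
  pops <- names(scn$populations)
  nsteps <- ceiling(scn$t_end / dt)
  times <- seq_len(nsteps) * dt

  cfg <- lapply(stats::setNames(pops, pops), function(nm) {
    base <- scn$populations[[nm]]
    ov <- overrides[[nm]]
    list(pop = ov$pop %||% base$pop,
         mobility = ov$mobility %||% base$mobility,
         phi_ac = base$phi_ac,
         centers = base$centers,
         t_start = base$t_start %||% 0)
  })
  adm <- scn$admixture
  if (!is.null(adm) && !is.null(p_adm_override)) adm$p_adm <- p_adm_override

  # per-population state
  agents <- list()
  next_id <- 1L
  with_seed(derive_seed(seed, "init"), {
    for (nm in pops) {
      ctr <- cfg[[nm]]$centers
      if (!is.null(ctr) && cfg[[nm]]$t_start <= 0) {
        agents[[nm]] <- init_population(ctr, grid, scn$land_mask,
                                        sigma = cfg[[nm]]$mobility$sigma,
                                        population = nm, first_id = next_id)
        next_id <- next_id + nrow(agents[[nm]])
      } else {
        agents[[nm]] <- .empty_agents()
      }
    }
  })

  pop_size <- matrix(0L, nsteps, length(pops),
                     dimnames = list(NULL, pops))
  ev_list <- list()  # accumulated, bound once at the end
  do_snap <- scn$record_every > 0
  snap_steps <- if (do_snap) seq(scn$record_every, nsteps, by = scn$record_every) else integer(0)
  snapshots <- stats::setNames(
    lapply(pops, function(nm) vector("list", length(snap_steps))), pops)
  n_fallback <- 0L

  # precompute rho_c per population per period
  rho_c_fields <- lapply(cfg, function(pc) {
    lapply(pc$phi_ac, function(f) carrying_capacity(f$values, pc$pop$C))
  })

  set.seed(derive_seed(seed, "dynamics"))
  period_prev <- ""
  for (s in seq_len(nsteps)) {
    t_now <- times[s]
    period <- .active_period(scn$timeline, t_now)

    # late-arriving populations enter at their t_start
    for (nm in pops) {
      if (!is.null(cfg[[nm]]$centers) && nrow(agents[[nm]]) == 0 &&
          cfg[[nm]]$t_start > 0 && t_now >= cfg[[nm]]$t_start &&
          t_now - dt < cfg[[nm]]$t_start) {
        agents[[nm]] <- init_population(cfg[[nm]]$centers, grid,
                                        scn$land_mask,
                                        sigma = cfg[[nm]]$mobility$sigma,
                                        population = nm, first_id = next_id)
        next_id <- next_id + nrow(agents[[nm]])
      }
    }

    for (nm in pops) {
      ag <- agents[[nm]]
      if (nrow(ag) == 0) next
      pc <- cfg[[nm]]
      rho <- density_field(ag, grid, smooth = TRUE)
      rho_c <- rho_c_fields[[nm]][[period]]
      f_pa <- attractiveness(rho, rho_c, pc$pop$eps_a, pc$pop$eta_a)
      phi_av <- raster_field(grid, available_hep(f_pa, rho_c),
                             units = "PDU", mask = scn$land_mask)
      move <- function(a) {
        a <- step_motion(a, phi_av, pc$mobility, pc$pop$C, dt,
                         land_mask = scn$land_mask)
        n_fallback <<- n_fallback + (attr(a, "n_fallback") %||% 0L)
        a
      }
      grow <- function(a) {
        bd <- step_births_deaths(a, rho, rho_c, pc$pop, dt,
                                 sigma = pc$mobility$sigma, grid,
                                 next_id = next_id)
        if (bd$n_births > 0) next_id <<- next_id + bd$n_births
        if (bd$n_births || bd$n_deaths) {
          ev_list[[length(ev_list) + 1]] <<-
            list(step = s, population = nm, births = bd$n_births,
                 deaths = bd$n_deaths, admix_births = 0L)
        }
        bd$agents
      }
      agents[[nm]] <- if (step_order == "motion_first") grow(move(ag)) else move(grow(ag))
    }

    if (!is.null(adm) && adm$p_adm > 0 &&
        nrow(agents$NEA) > 0 && nrow(agents$AMH) > 0) {
      co <- find_cooccupancy(agents$NEA, agents$AMH, grid)
      if (nrow(co)) {
        kids <- sample_admixture(co, adm, dt,
                                 sigma = cfg$MIX$mobility$sigma, grid,
                                 next_id = next_id)
        if (nrow(kids)) {
          next_id <- next_id + nrow(kids)
          agents$MIX <- rbind(agents$MIX, kids)
          ev_list[[length(ev_list) + 1]] <-
            list(step = s, population = "MIX", births = 0L, deaths = 0L,
                 admix_births = nrow(kids))
        }
      }
    }

    for (nm in pops) pop_size[s, nm] <- nrow(agents[[nm]])
    if (do_snap && s %in% snap_steps) {
      k <- match(s, snap_steps)
      for (nm in pops) snapshots[[nm]][[k]] <- density_field(agents[[nm]], grid)
    }
    period_prev <- period
  }

  events <- if (length(ev_list)) {
    do.call(rbind, lapply(ev_list, as.data.frame))
  } else {
    data.frame(step = integer(0), population = character(0),
               births = integer(0), deaths = integer(0),
               admix_births = integer(0))
  }
  structure(list(times = times, pop_size = pop_size, events = events,
                 snapshots = snapshots, snap_times = snap_steps * dt,
                 agents = agents, n_fallback = n_fallback,
                 spinup_exclude = scn$spinup_exclude),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  fin <- x$pop_size[nrow(x$pop_size), ]
  cat(sprintf("sim_output: %d steps; final sizes: %s\n", length(x$times),
              paste(sprintf("%s=%d", colnames(x$pop_size), fin), collapse = ", ")))
  invisible(x)
}
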
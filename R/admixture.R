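#' Admixture configuration
#'
#' Interbreeding between two populations co-occupying a grid cell. The
#' headline probability (default 1% per year) is attached to each
#' NEA-AMH cross pair in a co-occupied cell ("pair" unit, the default, which
#' scales with both local densities); alternative event units are one trial
#' per AMH agent or one per co-occupied cell. Offspring form a third (MIX)
#' population; with `single_generation = TRUE` (default) MIX agents never
#' themselves admix — only the initial crossing is modeled.
#'
#' @param p_adm admixture probability per eligible event per year, in [0, 1]
#'   (default 0.01)
#' @param unit event unit: "pair", "per_amh" or "per_cell"
#' @param single_generation logical (default TRUE)
#' @return object of class `admixture_config`
#' @export
admixture_config <- function(p_adm = 0.01,
                             unit = c("pair", "per_amh", "per_cell"),
                             single_generation = TRUE) {
  if (p_adm < 0 || p_adm > 1) stopf("parameter error: p_adm must be in [0, 1]")
  structure(list(p_adm = p_adm, unit = match.arg(unit),
                 single_generation = single_generation),
            class = "admixture_config")
}

#' Cells co-occupied by two populations
#'
#' @param nea_agents,amh_agents agent data.frames (alive agents)
#' @param grid a [grid_spec()]
#' @return data.frame with `cell` (linear index), `ix`, `iy`, `nea_count`,
#'   `amh_count`; zero rows when occupancy is disjoint
#' @export
find_cooccupancy <- function(nea_agents, amh_agents, grid) {
  ncell <- grid$nx * grid$ny
  cnt <- function(agents) {
    if (nrow(agents) == 0) return(integer(ncell))
    idx <- cell_index(grid, agents$x, agents$y)
    tabulate(idx$cell, nbins = ncell)
  }
  cn <- cnt(nea_agents); ca <- cnt(amh_agents)
  cells <- which(cn > 0L & ca > 0L)
  data.frame(cell = cells,
             iy = ((cells - 1L) %% grid$ny) + 1L,
             ix = ((cells - 1L) %/% grid$ny) + 1L,
             nea_count = cn[cells], amh_count = ca[cells])
}

#' Sample admixture births from co-occupancy events
#'
#' Each eligible event (by default each NEA-AMH cross pair in a co-occupied
#' cell) independently yields one MIX newborn with probability p_adm * dt.
#' Newborns are placed at the cell centre with a random velocity of magnitude
#' `sigma`.
#'
#' @param events co-occupancy table from [find_cooccupancy()]
#' @param cfg an [admixture_config()]
#' @param dt step, yr (p_adm * dt must be <= 1)
#' @param sigma newborn velocity magnitude, km/yr
#' @param grid a [grid_spec()]
#' @param next_id first id for newborns
#' @return data.frame of newborn MIX agents (possibly zero rows), with
#'   attribute `n_events` = number of eligible events considered
#' @export
sample_admixture <- function(events, cfg, dt, sigma, grid, next_id = 1L) {
  p <- cfg$p_adm * dt
  if (p > 1) stopf("config error: p_adm * dt exceeds 1")
  n_events_cell <- switch(cfg$unit,
    pair = events$nea_count * events$amh_count,
    per_amh = events$amh_count,
    per_cell = rep(1L, nrow(events)))
  total_events <- sum(n_events_cell)
  if (nrow(events) == 0 || p == 0 || total_events == 0) {
    out <- data.frame(id = integer(0), population = character(0),
                      x = numeric(0), y = numeric(0),
                      u = numeric(0), v = numeric(0), alive = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_events") <- total_events
    return(out)
  }
  births <- stats::rbinom(nrow(events), n_events_cell, p)
  rows <- rep(seq_len(nrow(events)), births)
  nb <- length(rows)
  ctr <- cell_center(grid, events$ix[rows], events$iy[rows])
  ang <- stats::runif(nb, 0, 2 * pi)
  out <- data.frame(id = next_id + seq_len(nb) - 1L,
                    population = rep("MIX", nb),
                    x = ctr$x, y = ctr$y,
                    u = sigma * cos(ang), v = sigma * sin(ang),
                    alive = rep(TRUE, nb), stringsAsFactors = FALSE)
  attr(out, "n_events") <- total_events
  out
}

#' Accessible HEP of the admixed population
#'
#' The arithmetic mean of the parents' accessible-HEP fields, taken after the
#' landscape modifications (the level the simulator consumes).
#'
#' @param phi_ac_nea,phi_ac_amh [raster_field()]s on one grid
#' @return [raster_field()] of the pointwise mean
#' @export
mix_accessible_hep <- function(phi_ac_nea, phi_ac_amh) {
  if (!identical(unclass(phi_ac_nea$grid), unclass(phi_ac_amh$grid))) {
    stopf("fields are on different grids")
  }
  raster_field(phi_ac_nea$grid,
               (phi_ac_nea$values + phi_ac_amh$values) / 2,
               units = phi_ac_nea$units,
               mask = phi_ac_nea$mask & phi_ac_amh$mask)
}
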
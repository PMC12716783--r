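#' Default "true" suitability coefficients for the synthetic world
#'
#' A concave quadratic-logistic surface on the five standard predictors:
#' suitability peaks at moderate standardized temperature and wet-quarter
#' precipitation and falls off toward the extremes, giving a separable
#' presence signal for parameter-recovery tests.
#'
#' @return list with `A`, `B`, `c0`, `predictors`
#' @export
default_true_hep <- function() {
  p <- DEFAULT_PREDICTORS
  A <- diag(c(-0.6, -0.2, -0.3, -0.15, -0.15))
  dimnames(A) <- list(p, p)
  list(A = A, B = c(0.75, -0.5, 0.4, -0.25, 0.25), c0 = 0.3, predictors = p)
}

#' Assemble a complete synthetic two-period scenario
#'
#' Builds landscape, warm and cold climates, bioclim stacks, accessible-HEP
#' fields from a known suitability surface (no ensemble fitting — the true
#' surface stands in for the ensemble mean), initial population centres at
#' high-suitability land cells, and the timeline warm -> cold. This is the
#' standard desk-scale test bed: real fields are drop-in replacements.
#'
#' @param spec a [synth_spec()]
#' @param presets named character vector mapping population label to preset,
#'   e.g. `c(NEA = "ExpNEA-C")` or `c(NEA = "ExpNEA-C", AMH = "ExpAUR-C",
#'   MIX = "ExpMIX-C")`
#' @param t_end simulated years
#' @param switch_time year at which the cold period replaces the warm one
#' @param n0 total initial humans per population
#' @param n_centers number of Gaussian initialization centres (n0 split
#'   evenly)
#' @param std_deg centre standard deviation, degrees (default 1)
#' @param true_params suitability coefficients (default
#'   [default_true_hep()])
#' @param admixture an [admixture_config()] or NULL (requires NEA, AMH and
#'   MIX presets)
#' @param amh_t_start entry time of the AMH population, yr (default 0)
#' @param dt,record_every,spinup_exclude passed to [scenario()]
#' @return list with `scenario`, `grid`, `landscape`, `bioclim` (warm/cold),
#'   `phi_true` (warm/cold), `true_params`
#' @export
synthetic_scenario <- function(spec = synth_spec(),
                               presets = c(NEA = "ExpNEA-C"),
                               t_end = 1200, switch_time = 600,
                               n0 = 1000, n_centers = 2, std_deg = 1,
                               true_params = default_true_hep(),
                               admixture = NULL, amh_t_start = 0,
                               dt = 1, record_every = 50,
                               spinup_exclude = 300) {
  ls <- generate_landscape(spec)
  g <- ls$grid
  periods <- c("warm", "cold")
  bioclim <- lapply(stats::setNames(periods, periods), function(per) {
    compute_bioclim(generate_climate(spec, ls, per))
  })
  # one standardization (warm-period land cells) applied to both periods
  tw <- true_hep_field(bioclim$warm, true_params)
  tc <- true_hep_field(bioclim$cold, true_params, stats = tw$stats)
  phi_true <- list(warm = tw$field, cold = tc$field)

  populations <- list()
  for (nm in names(presets)) {
    pr <- preset_params(presets[[nm]])
    mods <- mod_func_params(if (nm %in% c("NEA", "AMH")) nm else "AMH")
    phi_ac <- lapply(phi_true, function(f) accessible_hep(f, ls$landscape, mods))
    centers <- .pick_centers(phi_ac$warm, n_centers, n0, std_deg)
    populations[[nm]] <- list(pop = pr$pop, mobility = pr$mobility,
                              phi_ac = phi_ac, centers = centers,
                              t_start = if (nm == "AMH") amh_t_start else 0)
  }
  if (!is.null(admixture) && !is.null(populations$MIX)) {
    populations$MIX$centers <- NULL  # MIX arises only through admixture
    populations$MIX$phi_ac <- lapply(stats::setNames(periods, periods),
      function(per) mix_accessible_hep(populations$NEA$phi_ac[[per]],
                                       populations$AMH$phi_ac[[per]]))
  }
  timeline <- data.frame(t_start = c(0, switch_time),
                         period = c("warm", "cold"),
                         stringsAsFactors = FALSE)
  scn <- scenario(g, ls$landscape$land_mask, populations, timeline,
                  t_end = t_end, dt = dt, admixture = admixture,
                  spinup_exclude = spinup_exclude,
                  record_every = record_every)
  list(scenario = scn, grid = g, landscape = ls$landscape,
       bioclim = bioclim, phi_true = phi_true, true_params = true_params)
}

# greedy selection of well-separated high-suitability centre cells
.pick_centers <- function(phi_ac, n_centers, n0, std_deg,
                          min_sep_cells = 8) {
  g <- phi_ac$grid
  land <- which(as.vector(phi_ac$mask) & !is.na(as.vector(phi_ac$values)))
  ord <- land[order(-phi_ac$values[land])]
  iy <- ((ord - 1L) %% g$ny) + 1L
  ix <- ((ord - 1L) %/% g$ny) + 1L
  sel <- integer(0)
  for (k in seq_along(ord)) {
    if (!length(sel)) {
      sel <- k
    } else if (all(pmax(abs(ix[k] - ix[sel]), abs(iy[k] - iy[sel])) >= min_sep_cells)) {
      sel <- c(sel, k)
    }
    if (length(sel) == n_centers) break
  }
  sel <- sel[seq_len(min(n_centers, length(sel)))]
  ctr <- cell_center(g, ix[sel], iy[sel])
  ll <- km_to_lonlat(g, ctr$x, ctr$y)
  n_each <- rep(floor(n0 / length(sel)), length(sel))
  n_each[1] <- n_each[1] + n0 - sum(n_each)
  data.frame(lon = ll$lon, lat = ll$lat, n0 = n_each, std = std_deg)
}
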
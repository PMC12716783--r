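#' Specification of a synthetic landscape/climate world
#'
#' Stands in for real paleoclimate and archaeological inputs so every model
#' stage can be exercised and parameter recovery tested at desk scale. The
#' defaults describe a temperate mid-latitude domain: a coherent coastline
#' around 60% land, few-hundred-metre relief, a north-south temperature
#' gradient with a seasonal cycle, an elevation lapse rate of 6.5 degC/km,
#' and a cold period that is markedly colder (-5 degC) and drier (40% less
#' precipitation) than the warm period, mirroring the stadial/interstadial
#' contrast the model is used to study.
#'
#' @param nx,ny grid size (default 40 x 40)
#' @param cell_size km (default 20)
#' @param land_frac target land fraction (default 0.6)
#' @param relief_m elevation relief amplitude, m (default 1200)
#' @param t_base mean annual temperature at the domain-centre latitude, degC
#'   (default 9)
#' @param t_lat_gradient temperature decrease per degree latitude northward,
#'   degC/deg (default 0.8)
#' @param t_seasonal seasonal half-amplitude, degC (default 8)
#' @param lapse_rate degC per km of elevation (default 6.5)
#' @param p_base mean monthly precipitation, mm (default 70)
#' @param p_seasonal seasonal half-amplitude of precipitation, mm (default
#'   25)
#' @param cold_dT cold-period temperature offset, degC (default -4)
#' @param cold_p_scale cold-period precipitation scaling (default 0.7)
#' @param noise_T,noise_P spatial noise std of temperature (degC) and
#'   precipitation (mm)
#' @param forest_frac fraction of land under dense forest (default 0.05)
#' @param seed master seed
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(nx = 40, ny = 40, cell_size = 20, land_frac = 0.6,
                       relief_m = 1200, t_base = 9, t_lat_gradient = 0.8,
                       t_seasonal = 8, lapse_rate = 6.5, p_base = 70,
                       p_seasonal = 25, cold_dT = -4, cold_p_scale = 0.7,
                       noise_T = 0.8, noise_P = 8, forest_frac = 0.05,
                       seed = 1) {
  if (land_frac <= 0 || land_frac > 1) stopf("land_frac must be in (0, 1]")
  structure(as.list(environment()), class = "synth_spec")
}

# smooth random field: iterated 3x3 smoothing of white noise, rescaled to
# zero mean / unit sd
.smooth_noise <- function(ny, nx, passes = 6) {
  m <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (i in seq_len(passes)) m <- smooth3x3(m)
  (m - mean(m)) / stats::sd(m)
}

#' Generate a synthetic landscape
#'
#' Low-pass filtered noise produces a smooth elevation surface; the sea is
#' the lowest `1 - land_frac` quantile of that surface, giving a coherent
#' coastline. Roughness is the local (3x3) standard deviation of elevation;
#' optional dense-forest patches come from an independent smooth noise field.
#'
#' @param spec a [synth_spec()]
#' @return list with `grid` ([grid_spec()]) and `landscape`
#'   ([landscape_bundle()])
#' @export
generate_landscape <- function(spec) {
  g <- grid_spec(spec$nx, spec$ny, spec$cell_size, lon0 = -4, lat0 = 40)
  with_seed(derive_seed(spec$seed, "landscape"), {
    base <- .smooth_noise(spec$ny, spec$nx)
    sea_level <- stats::quantile(base, 1 - spec$land_frac)
    land <- base > sea_level
    if (sum(land) < 4) stopf("degenerate spec: (almost) all sea")
    elev <- pmax(base - sea_level, 0) / max(base - sea_level) * spec$relief_m
    elev[!land] <- NA_real_
    # roughness: local sd of elevation over the 3x3 neighbourhood
    e0 <- ifelse(is.na(elev), 0, elev)
    m1 <- smooth3x3(e0)
    m2 <- smooth3x3(e0^2)
    rough <- sqrt(pmax(m2 - m1^2, 0))
    rough[!land] <- NA_real_
    forest <- matrix(FALSE, spec$ny, spec$nx)
    if (spec$forest_frac > 0) {
      fn <- .smooth_noise(spec$ny, spec$nx)
      thr <- stats::quantile(fn[land], 1 - spec$forest_frac)
      forest <- land & fn > thr
    }
    bundle <- landscape_bundle(
      elevation = raster_field(g, elev, units = "m", mask = land),
      roughness = raster_field(g, rough, units = "m", mask = land),
      land_mask = land, forest_mask = forest)
    list(grid = g, landscape = bundle)
  })
}

#' Generate synthetic monthly climate for a warm or cold period
#'
#' Temperature = base - latitudinal gradient - lapse-rate x elevation +
#' seasonal cycle + smooth spatial noise; precipitation = base + seasonal
#' cycle + smooth noise, floored at 0. The cold period applies the configured
#' temperature offset (default -4 degC) and precipitation scaling (default
#' 0.7), emulating the colder and drier stadial state.
#'
#' @param spec a [synth_spec()]
#' @param landscape result of [generate_landscape()]
#' @param period "warm" or "cold"
#' @return a [monthly_climate()]
#' @export
generate_climate <- function(spec, landscape, period = c("warm", "cold")) {
  period <- match.arg(period)
  g <- landscape$grid
  b <- landscape$landscape
  elev_km <- ifelse(is.na(b$elevation$values), 0, b$elevation$values) / 1000
  ll <- km_to_lonlat(g, rep(0, g$ny),
                     g$origin_y + (seq_len(g$ny) - 0.5) * g$cell_size)
  lat_anom <- matrix(ll$lat - g$lat0, g$ny, g$nx)  # degrees from centre
  dT <- if (period == "cold") spec$cold_dT else 0
  pscale <- if (period == "cold") spec$cold_p_scale else 1

  tmean <- array(0, c(g$ny, g$nx, 12))
  precip <- array(0, c(g$ny, g$nx, 12))
  # spatial noise and continentality fields are shared between the warm and
  # cold periods (same geography, different circulation state), so the
  # cold-warm temperature contrast is exactly cold_dT everywhere
  with_seed(derive_seed(spec$seed, "climate"), {
    tnoise <- .smooth_noise(g$ny, g$nx) * spec$noise_T
    pnoise <- .smooth_noise(g$ny, g$nx) * spec$noise_P
    # continentality-like smooth fields modulate the seasonal amplitudes so
    # seasonality (Bio4, Bio15) varies in space, as it does in real climates
    cont_t <- 1 + 0.4 * .smooth_noise(g$ny, g$nx)
    cont_p <- 1 + 0.6 * .smooth_noise(g$ny, g$nx)
    for (m in 1:12) {
      seas_t <- spec$t_seasonal * cont_t * cos(2 * pi * (m - 7) / 12)
      seas_p <- spec$p_seasonal * cont_p * cos(2 * pi * (m - 1) / 12)
      tmean[, , m] <- spec$t_base + dT - spec$t_lat_gradient * lat_anom -
        spec$lapse_rate * elev_km + seas_t + tnoise
      precip[, , m] <- pmax((spec$p_base + seas_p + pnoise) * pscale, 0)
    }
  })
  monthly_climate(g, tmean, precip, land_mask = b$land_mask)
}

#' Evaluate a known (true) suitability surface
#'
#' Computes Phi_E* from prescribed quadratic-logistic coefficients on
#' standardized predictors — the ground truth for parameter-recovery and
#' end-to-end tests.
#'
#' @param stack a [compute_bioclim()] result
#' @param true_params list with `A`, `B`, `c0` and `predictors`
#' @param stats optional standardization statistics; fitted over all land
#'   cells when NULL
#' @return list with `field` ([raster_field()] of Phi_E*), `stats`, `Z`
#'   (standardized predictor matrix over all cells)
#' @export
true_hep_field <- function(stack, true_params, stats = NULL) {
  land <- which(as.vector(stack$land_mask))
  std <- standardize_bioclim(stack, true_params$predictors,
                             training_cells = if (is.null(stats)) land else NULL,
                             stats = stats)
  phi <- rep(NA_real_, stack$grid$ny * stack$grid$nx)
  phi[land] <- predict_hep(true_params, std$values[land, , drop = FALSE])
  v <- matrix(phi, stack$grid$ny, stack$grid$nx)
  list(field = raster_field(stack$grid, v, mask = stack$land_mask),
       stats = std$stats, Z = std$values)
}

#' Sample archaeological sites from a known suitability surface
#'
#' Presence-only discovery model: cells are drawn with replacement with
#' probability proportional to Phi_E* and each draw becomes one site with
#' coordinates jittered uniformly within the cell (several discoveries in one
#' cell later collapse to a single presence record under spatial blocking,
#' as for real data). The pseudo-absence machinery is then applied to these
#' sites exactly as to real records.
#'
#' @param phi_true [raster_field()] of the true suitability
#' @param n_sites number of sites
#' @param seed RNG seed
#' @param techno_tag tag for the generated records (default "TEST")
#' @return a [site_table()]
#' @export
sample_sites_from_hep <- function(phi_true, n_sites, seed = 1,
                                  techno_tag = "TEST") {
  g <- phi_true$grid
  land <- which(as.vector(phi_true$mask))
  if (n_sites > length(land)) stopf("n_sites exceeds the number of land cells")
  w <- phi_true$values[land]
  with_seed(seed, {
    cells <- sample(land, n_sites, replace = TRUE, prob = w)
    iy <- ((cells - 1L) %% g$ny) + 1L
    ix <- ((cells - 1L) %/% g$ny) + 1L
    ctr <- cell_center(g, ix, iy)
    jx <- stats::runif(n_sites, -0.49, 0.49) * g$cell_size
    jy <- stats::runif(n_sites, -0.49, 0.49) * g$cell_size
    ll <- km_to_lonlat(g, ctr$x + jx, ctr$y + jy)
    site_table(site_id = sprintf("S%04d", seq_len(n_sites)),
               lon = ll$lon, lat = ll$lat, techno_tag = techno_tag)
  })
}
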
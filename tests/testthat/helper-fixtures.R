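# shared in-code fixtures (no data files)

# small all-land grid
tiny_grid <- function(nx = 10, ny = 10, cell = 20) grid_spec(nx, ny, cell)

# random monthly climate (optionally with diurnal extremes), all land
random_climate <- function(grid, seed = 1, with_extremes = FALSE) {
  with_seed(seed, {
    ny <- grid$ny; nx <- grid$nx
    tmean <- array(stats::rnorm(ny * nx * 12, 8, 5), c(ny, nx, 12))
    precip <- array(stats::rgamma(ny * nx * 12, shape = 2, scale = 30),
                    c(ny, nx, 12))
    if (with_extremes) {
      spread <- array(abs(stats::rnorm(ny * nx * 12, 5, 1)), c(ny, nx, 12))
      monthly_climate(grid, tmean, precip,
                      tmax = tmean + spread, tmin = tmean - spread)
    } else {
      monthly_climate(grid, tmean, precip)
    }
  })
}

# constant climate: tmean = t0 every month, precip = p0 every month
constant_climate <- function(grid, t0 = 10, p0 = 50) {
  ny <- grid$ny; nx <- grid$nx
  monthly_climate(grid,
                  array(t0, c(ny, nx, 12)),
                  array(p0, c(ny, nx, 12)))
}

# agents data.frame at given positions
make_agents <- function(x, y, u = 0, v = 0, population = "NEA") {
  n <- length(x)
  data.frame(id = seq_len(n), population = rep(population, n),
             x = x, y = y,
             u = rep_len(u, n), v = rep_len(v, n),
             alive = rep(TRUE, n), stringsAsFactors = FALSE)
}

# a small island landscape: land in the centre block, sea around it
island_world <- function(nx = 12, ny = 12, cell = 20, margin = 3) {
  g <- grid_spec(nx, ny, cell)
  land <- matrix(FALSE, ny, nx)
  land[(margin + 1):(ny - margin), (margin + 1):(nx - margin)] <- TRUE
  elev <- matrix(NA_real_, ny, nx); elev[land] <- 100
  rough <- matrix(NA_real_, ny, nx); rough[land] <- 10
  list(grid = g,
       landscape = landscape_bundle(
         elevation = raster_field(g, elev, units = "m", mask = land),
         roughness = raster_field(g, rough, units = "m", mask = land),
         land_mask = land))
}
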
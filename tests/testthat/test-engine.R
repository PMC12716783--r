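# small uniform world for engine tests: all-land grid, flat suitability
flat_scenario <- function(nx = 10, ny = 10, phi = 0.5, C = 5, ro = 0.05,
                          n0 = 40, t_end = 200, sigma = 15,
                          record_every = 0, dt = 1) {
  g <- grid_spec(nx, ny, 20)
  land <- matrix(TRUE, ny, nx)
  phi_ac <- raster_field(g, matrix(phi, ny, nx), mask = land)
  ctr <- km_to_lonlat(g, nx * 10, ny * 10)
  pops <- list(NEA = list(
    pop = population_params(C = C, ro = ro, rho_d = 1e-6),
    mobility = mobility_params(sigma = sigma),
    phi_ac = list(base = phi_ac),
    centers = data.frame(lon = ctr$lon, lat = ctr$lat, n0 = n0, std = 0.5)))
  scenario(g, land, pops,
           timeline = data.frame(t_start = 0, period = "base"),
           t_end = t_end, dt = dt, record_every = record_every,
           spinup_exclude = 0)
}

test_that("presets carry the published experiment parameters", {
  specs <- list("ExpNEA-H" = c(3, 0.05), "ExpNEA-C" = c(2, 0.02),
                "ExpNEA-L" = c(1, 0.01), "ExpAUR-C" = c(3, 0.02),
                "ExpMIX-C" = c(2, 0.02))
  for (nm in names(specs)) {
    p <- preset_params(nm)
    expect_equal(p$pop$C, specs[[nm]][1], info = nm)
    expect_equal(p$pop$ro, specs[[nm]][2], info = nm)
    expect_equal(p$mobility$alpha, 1250, info = nm)
    expect_equal(p$mobility$sigma, 15, info = nm)
  }
  expect_error(preset_params("ExpFOO"), "arg")
})

test_that("density fields convert counts to PDU and conserve the census", {
  g <- grid_spec(10, 10, 20)
  ag <- make_agents(rep(30, 8), rep(30, 8))   # 8 agents, one 400 km^2 cell
  rho <- density_field(ag, g)
  expect_equal(max(rho), 2)                   # 8 / 4 PDU
  expect_equal(sum(rho > 0), 1L)
  # conservation: sum(rho) * cell_area / 100 = census
  set.seed(61)
  ag2 <- make_agents(runif(57, 0, 200), runif(57, 0, 200))
  expect_equal(sum(density_field(ag2, g)) * 400 / 100, 57)
  expect_true(all(density_field(make_agents(numeric(0), numeric(0)), g) == 0))
})

test_that("initialization places the exact census with speed sigma", {
  g <- grid_spec(20, 20, 20)
  ctr <- km_to_lonlat(g, 200, 200)
  centers <- data.frame(lon = ctr$lon, lat = ctr$lat, n0 = 1000, std = 0.3)
  set.seed(62)
  ag <- init_population(centers, g, land_mask = NULL, sigma = 15)
  expect_equal(nrow(ag), 1000L)
  expect_true(all(ag$alive))
  expect_equal(sqrt(ag$u^2 + ag$v^2), rep(15, 1000))
  # sample mean within 3 std / sqrt(n) of the centre
  sc <- deg_to_km_scale(g)
  expect_lt(abs(mean(ag$x) - 200), 3 * 0.3 * sc$kx / sqrt(1000))
  expect_lt(abs(mean(ag$y) - 200), 3 * 0.3 * sc$ky / sqrt(1000))
})

test_that("initialization resamples sea draws and flags water-bound centres", {
  w <- island_world(12, 12, 20, margin = 3)
  ctr <- km_to_lonlat(w$grid, 120, 120)
  centers <- data.frame(lon = ctr$lon, lat = ctr$lat, n0 = 300, std = 1)
  set.seed(63)
  expect_warning(
    ag <- init_population(centers, w$grid, w$landscape$land_mask, sigma = 15),
    "land")
  expect_equal(nrow(ag), 300L)
  idx <- cell_index(w$grid, ag$x, ag$y)
  expect_true(all(w$landscape$land_mask[idx$cell]))
})

test_that("an empty scenario runs to completion without error", {
  scn <- flat_scenario(n0 = 0, t_end = 10)
  scn$populations$NEA$centers <- NULL
  out <- run_simulation(scn, seed = 1)
  expect_true(all(out$pop_size == 0))
  expect_equal(nrow(out$events), 0L)
})

test_that("runs are bit-identical under a fixed master seed", {
  scn <- flat_scenario(n0 = 30, t_end = 40)
  o1 <- run_simulation(scn, seed = 9)
  o2 <- run_simulation(scn, seed = 9)
  expect_identical(o1$pop_size, o2$pop_size)
  expect_identical(o1$agents, o2$agents)
  o3 <- run_simulation(scn, seed = 10)
  expect_false(identical(o1$pop_size, o3$pop_size))
})

test_that("a noise-free uniform run follows the logistic growth curve", {
  # sigma = 0, flat suitability: no net motion, Verhulst limit of the census
  scn <- flat_scenario(nx = 5, ny = 5, phi = 1, C = 4, ro = 0.05, n0 = 40,
                       t_end = 150, sigma = 0)
  K <- 4 * 25 * 4           # C * cells * agents-per-PDU-cell
  set.seed(64)
  finals <- sapply(1:20, function(s) {
    out <- suppressWarnings(run_simulation(scn, seed = s))
    out$pop_size[150, "NEA"]
  })
  # agents stay near the centre, so the local logistic ceiling is below the
  # domain-wide K but growth must have left n0 far behind
  expect_gt(mean(finals), 40 * 2)
  expect_lt(mean(finals), K * 1.1)
})

test_that("halving the suitability roughly halves the equilibrium census", {
  scn <- flat_scenario(nx = 8, ny = 8, phi = 1, C = 5, ro = 0.1, n0 = 200,
                       t_end = 260, sigma = 10)
  # switch to half suitability at t = 130
  g <- scn$grid
  land <- scn$land_mask
  scn$populations$NEA$phi_ac$half <-
    raster_field(g, matrix(0.5, 8, 8), mask = land)
  scn$timeline <- data.frame(t_start = c(0, 130), period = c("base", "half"))
  set.seed(65)
  ratio <- sapply(1:8, function(s) {
    out <- run_simulation(scn, seed = s)
    mean(out$pop_size[110:130, "NEA"]) / mean(out$pop_size[240:260, "NEA"])
  })
  expect_lt(abs(mean(1 / ratio) - 0.5), 0.2 * 0.5 + 0.05)
})

test_that("update-order choice does not materially shift equilibria", {
  scn <- flat_scenario(nx = 8, ny = 8, phi = 1, C = 5, ro = 0.1, n0 = 150,
                       t_end = 150, sigma = 10)
  eq <- function(order) {
    mean(sapply(1:6, function(s) {
      out <- run_simulation(scn, seed = s, step_order = order)
      mean(out$pop_size[120:150, "NEA"])
    }))
  }
  e1 <- eq("motion_first"); e2 <- eq("demography_first")
  expect_lt(abs(e1 - e2) / e1, 0.05)
})

test_that("admixture inside the engine creates MIX only where parents meet", {
  g <- grid_spec(8, 8, 20)
  land <- matrix(TRUE, 8, 8)
  phi <- raster_field(g, matrix(0.8, 8, 8), mask = land)
  ctr <- km_to_lonlat(g, 80, 80)
  mk_pop <- function(preset, n0) {
    pr <- preset_params(preset)
    pr$pop$rho_d <- 1e-6
    list(pop = pr$pop, mobility = pr$mobility,
         phi_ac = list(base = phi),
         centers = data.frame(lon = ctr$lon, lat = ctr$lat, n0 = n0, std = 0.5))
  }
  pops <- list(NEA = mk_pop("ExpNEA-C", 60), AMH = mk_pop("ExpAUR-C", 60),
               MIX = list(pop = preset_params("ExpMIX-C")$pop,
                          mobility = preset_params("ExpMIX-C")$mobility,
                          phi_ac = NULL, centers = NULL))
  scn <- scenario(g, land, pops,
                  timeline = data.frame(t_start = 0, period = "base"),
                  t_end = 60, dt = 1, admixture = admixture_config(p_adm = 0.01),
                  spinup_exclude = 0, record_every = 0)
  out <- run_simulation(scn, seed = 66)
  expect_gt(out$pop_size[60, "MIX"], 0)
  # bookkeeping: MIX census equals admixture births plus net MIX demography
  mix_ev <- out$events[out$events$population == "MIX", ]
  expect_equal(unname(out$pop_size[60, "MIX"]),
               sum(mix_ev$admix_births) + sum(mix_ev$births) - sum(mix_ev$deaths))
  # with p_adm = 0 no MIX agent ever appears
  scn0 <- scn; scn0$admixture$p_adm <- 0
  out0 <- run_simulation(scn0, seed = 66)
  expect_true(all(out0$pop_size[, "MIX"] == 0))
})

test_that("rate-of-change maps difference the ensemble-mean densities", {
  m0 <- matrix(1, 4, 4); m1 <- matrix(2, 4, 4); m2 <- matrix(2, 4, 4)
  rc <- rate_of_change(list(m0, m1, m2), snap_times = c(0, 500, 1000),
                       dt_lag = 500)
  expect_equal(length(rc$fields), 2L)
  expect_equal(unique(as.vector(rc$fields[[1]])), 1 / 500)  # 0.2 PDU/100yr
  expect_equal(unique(as.vector(rc$fields[[2]])), 0)        # stationary
  # antisymmetry under time reversal
  rc_rev <- rate_of_change(list(m2, m1, m0), snap_times = c(0, 500, 1000),
                           dt_lag = 500)
  expect_equal(rc_rev$fields[[2]], -rc$fields[[1]])
  expect_error(rate_of_change(list(m0, m1), c(0, 300), dt_lag = 500),
               "missing snapshot")
})

test_that("threshold fractions count member minima exactly", {
  # all-extinct ensemble
  dead <- lapply(1:4, function(i) cbind(NEA = c(5, 2, 0, 0)))
  expect_equal(unname(threshold_fractions(dead, c(0, 30, 50), "NEA")),
               c(1, 1, 1))
  # hand-built 10-member ensemble with known minima vs brute-force count
  set.seed(67)
  minima <- c(0, 5, 12, 25, 28, 31, 40, 55, 70, 90)
  members <- lapply(minima, function(m) {
    cbind(NEA = pmax(m, round(m + 30 * abs(sin(1:50)))))
  })
  fr <- threshold_fractions(members, c(0, 30, 50), "NEA")
  expect_equal(unname(fr), c(mean(minima == 0), mean(minima < 30),
                             mean(minima < 50)))
  expect_true(all(diff(fr) >= 0))       # nondecreasing in the threshold
  # window restriction
  two <- lapply(list(c(10, 0, 50), c(40, 45, 50)), function(v) cbind(NEA = v))
  fr_w <- threshold_fractions(two, 0, "NEA", times = c(1, 2, 3),
                              window = c(3, 3))
  expect_equal(unname(fr_w), 0)
  expect_error(threshold_fractions(two, 0, "NEA", times = 1:3,
                                   window = c(9, 10)), "empty window")
})

test_that("small perturbed ensembles are reproducible and sized", {
  scn <- flat_scenario(nx = 6, ny = 6, n0 = 25, t_end = 30, record_every = 10)
  e1 <- run_ensemble(scn, n_members = 3, perturb = 0.1, seed = 5)
  expect_equal(e1$n_members, 3L)
  expect_equal(length(e1$member_sizes), 3L)
  expect_equal(dim(e1$mean), c(30L, 1L))
  e2 <- run_ensemble(scn, n_members = 3, perturb = 0.1, seed = 5)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$sd, e2$sd)
  # perturb = 0: all members share parameters; spread is dynamics-only
  e0 <- run_ensemble(scn, n_members = 3, perturb = 0, seed = 5)
  draws <- sapply(e0$members, function(m) m$params$NEA$pop$C)
  expect_true(all(draws == draws[1]))
  # perturbed draws differ across members and stay within +-10%
  dC <- sapply(e1$members, function(m) m$params$NEA$pop$C)
  expect_gt(length(unique(dC)), 1L)
  expect_true(all(abs(dC / 5 - 1) <= 0.1 + 1e-12))
})

test_that("post-spin-up dynamics forget the initial placement", {
  base <- flat_scenario(nx = 8, ny = 8, phi = 1, C = 5, ro = 0.1, n0 = 120,
                        t_end = 200, sigma = 10)
  alt <- base
  ctr2 <- km_to_lonlat(base$grid, 40, 40)
  alt$populations$NEA$centers <- data.frame(lon = ctr2$lon, lat = ctr2$lat,
                                            n0 = 120, std = 0.5)
  m1 <- sapply(1:8, function(s) {
    mean(run_simulation(base, seed = s)$pop_size[150:200, "NEA"])
  })
  m2 <- sapply(1:8, function(s) {
    mean(run_simulation(alt, seed = 100 + s)$pop_size[150:200, "NEA"])
  })
  expect_gt(t.test(m1, m2)$p.value, 0.01)
})
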
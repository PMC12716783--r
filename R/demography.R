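#' Demographic parameters of one population
#'
#' @param C cultural carrying capacity, PDU (humans per 100 km^2 at full
#'   suitability); order 1-10 for Upper-Paleolithic foragers
#' @param ro asymptotic relative growth rate at high density, 1/yr
#' @param eta_g small negative floor of the relative growth rate: as density
#'   falls to 0 the mating network collapses and the per-capita rate tends to
#'   `eta_g * ro` (Allee effect); default -0.1
#' @param eps_g steepness of the logistic transition in log-density
#'   (default 2.5)
#' @param rho_d density scale of the mating-network transition, PDU
#'   (default 0.05)
#' @param eps_a,eta_a scale and shape of the Weibull attractiveness function
#'   (defaults 0.4 and 1.6; `eta_a` must exceed 1 so attractiveness vanishes
#'   at zero density)
#' @return object of class `population_params`
#' @export
population_params <- function(C, ro, eta_g = -0.1, eps_g = 2.5,
                              rho_d = 0.05, eps_a = 0.4, eta_a = 1.6) {
  if (C <= 0) stopf("parameter error: C must be > 0")
  if (ro <= 0) stopf("parameter error: ro must be > 0")
  if (eta_g >= 0) stopf("parameter error: eta_g must be < 0")
  if (rho_d <= 0) stopf("parameter error: rho_d must be > 0")
  if (eps_a <= 0) stopf("parameter error: eps_a must be > 0")
  if (eta_a <= 1) stopf("parameter error: eta_a must be > 1")
  structure(list(C = C, ro = ro, eta_g = eta_g, eps_g = eps_g,
                 rho_d = rho_d, eps_a = eps_a, eta_a = eta_a),
            class = "population_params")
}

#' Local carrying capacity from accessible HEP
#'
#' rho_c = C * Phi_Ac: a fully suitable cell supports the cultural carrying
#' capacity C, an unsuitable one nothing.
#'
#' @param phi_ac accessible HEP in [0, 1] (numeric or [raster_field()])
#' @param C cultural carrying capacity, PDU
#' @return carrying capacity, PDU, same shape as `phi_ac`
#' @export
carrying_capacity <- function(phi_ac, C) {
  if (C <= 0) stopf("parameter error: C must be > 0")
  if (inherits(phi_ac, "raster_field")) {
    raster_field(phi_ac$grid, C * phi_ac$values, units = "PDU",
                 mask = phi_ac$mask)
  } else {
    C * phi_ac
  }
}

# mode of the Weibull density in u: u* = ((eta-1)/eta)^(1/eta), eta > 1
.weibull_mode <- function(eta_a) ((eta_a - 1) / eta_a)^(1 / eta_a)

#' Population attractiveness (Weibull-shaped pull of occupied habitat)
#'
#' Two competing processes: gregariousness makes sparsely occupied habitat
#' unattractive, while crowding beyond the carrying capacity creates
#' population pressure. Both are encoded by a Weibull density in the scaled
#' density u = (rho/rho_c)/eps_a: w(u) = (eta/eps) u^(eta-1) exp(-u^eta),
#' normalized by its analytic maximum at the mode u* = ((eta-1)/eta)^(1/eta),
#' so f_pa = w/w_max lies in [0, 1] and equals 1 exactly at the mode.
#' Uninhabitable cells (rho_c = 0) get f_pa = 0.
#'
#' @param rho population density, PDU
#' @param rho_c carrying capacity, PDU
#' @param eps_a,eta_a Weibull scale and shape (defaults 0.4 and 1.6)
#' @return f_pa in [0, 1], same shape as `rho`
#' @export
attractiveness <- function(rho, rho_c, eps_a = 0.4, eta_a = 1.6) {
  if (eta_a <= 1) stopf("parameter error: eta_a must be > 1")
  u <- (rho / rho_c) / eps_a       # rho_c = 0 gives Inf/NaN, zeroed below
  us <- .weibull_mode(eta_a)
  f <- u
  f[] <- 0
  ok <- is.finite(u) & u > 0
  # f_pa = (u/u*)^(eta-1) * exp(u*^eta - u^eta), stable in log space
  f[ok] <- exp((eta_a - 1) * (log(u[ok]) - log(us)) + us^eta_a - u[ok]^eta_a)
  pmin(pmax(f, 0), 1)
}

#' Available HEP: habitat pull after population pressure
#'
#' Phi_Av = f_pa * rho_c. As accessible HEP spans 0 to 1, Phi_Av spans 0 to
#' C. Its gradient is the macroscopic drift driver of agent motion.
#'
#' @param f_pa attractiveness in [0, 1]
#' @param rho_c carrying capacity, PDU
#' @return Phi_Av in [0, C], PDU
#' @export
available_hep <- function(f_pa, rho_c) f_pa * rho_c

#' Density-dependent relative growth rate (mating-network Allee term)
#'
#' rB = ro * [(1 - eta)/(1 + exp(-x)) + eta] with x = eps * ln(rho/rho_d).
#' Monotone nondecreasing in density: rB -> eta*ro (< 0) as rho -> 0 (mating
#' network collapsed), rB = ro (1 + eta)/2 at rho = rho_d, and rB -> ro at
#' high density.
#'
#' @param rho population density, PDU (>= 0)
#' @param ro asymptotic growth rate, 1/yr
#' @param eta_g negative floor parameter
#' @param eps_g steepness
#' @param rho_d transition density, PDU
#' @return rB in 1/yr, same shape as `rho`
#' @export
growth_rate_rb <- function(rho, ro, eta_g = -0.1, eps_g = 2.5, rho_d = 0.05) {
  x <- eps_g * log(rho / rho_d)  # log(0) = -Inf handled by plogis
  ro * ((1 - eta_g) * stats::plogis(x) + eta_g)
}

# one-pass 3x3 uniform smoothing (edge cells average over in-domain
# neighbours only)
smooth3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    acc[ys - dy, xs - dx] <- acc[ys - dy, xs - dx] + m[ys, xs]
    cnt[ys - dy, xs - dx] <- cnt[ys - dy, xs - dx] + 1
  }
  acc / cnt
}

#' Stochastic births and deaths matching Verhulst growth in expectation
#'
#' Per cell the net per-capita rate is g = rB(rho) * (1 - rho/rho_c), with rB
#' the Allee-type rate of [growth_rate_rb()]. Each agent in the cell gives
#' birth with probability g*dt when g >= 0 and dies with probability -g*dt
#' when g < 0, so the expected net change follows the logistic law
#' d(rho)/dt = rho * rB * (1 - rho/rho_c). Where rho_c = 0 but agents are
#' present, the crowding factor is clamped at -1 (maximal per-capita death
#' hazard rB*dt). Newborns appear at the parent's position with a random
#' velocity of magnitude `sigma`.
#'
#' @param agents agent data.frame (see [init_population()])
#' @param rho density matrix, PDU (possibly smoothed)
#' @param rho_c carrying-capacity matrix, PDU
#' @param params a [population_params()]
#' @param dt time step, yr; `dt * max|g|` must stay <= 0.5 (stability error
#'   otherwise)
#' @param sigma newborn velocity magnitude, km/yr
#' @param grid a [grid_spec()]
#' @param next_id first id to assign to newborns (default: max id + 1)
#' @return list with `agents`, `n_births`, `n_deaths`
#' @export
step_births_deaths <- function(agents, rho, rho_c, params, dt, sigma, grid,
                               next_id = NULL) {
  n <- nrow(agents)
  if (n == 0) return(list(agents = agents, n_births = 0L, n_deaths = 0L))
  idx <- cell_index(grid, agents$x, agents$y)
  rho_a <- rho[idx$cell]
  rhoc_a <- rho_c[idx$cell]
  rb <- growth_rate_rb(rho_a, params$ro, params$eta_g, params$eps_g,
                       params$rho_d)
  crowd <- ifelse(!is.na(rhoc_a) & rhoc_a > 0,
                  pmax(1 - rho_a / rhoc_a, -1), -1)
  gr <- rb * crowd
  if (max(abs(gr), na.rm = TRUE) * dt > 0.5) {
    stopf("stability error: dt * |growth rate| exceeds 0.5 (max %g)",
          max(abs(gr), na.rm = TRUE) * dt)
  }
  u01 <- stats::runif(n)
  births <- which(gr >= 0 & u01 < gr * dt)
  deaths <- which(gr < 0 & u01 < -gr * dt)

  out <- agents
  if (length(deaths)) out <- out[-deaths, , drop = FALSE]
  if (length(births)) {
    if (is.null(next_id)) next_id <- max(agents$id) + 1L
    ang <- stats::runif(length(births), 0, 2 * pi)
    kids <- data.frame(id = next_id + seq_along(births) - 1L,
                       population = agents$population[births],
                       x = agents$x[births], y = agents$y[births],
                       u = sigma * cos(ang), v = sigma * sin(ang),
                       alive = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out, kids)
  }
  list(agents = out, n_births = length(births), n_deaths = length(deaths))
}
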
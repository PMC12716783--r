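#' Mobility parameters of the constrained random walk
#'
#' Agent velocity follows a damped (Ornstein-Uhlenbeck) stochastic process
#' with a deterministic acceleration up the gradient of available HEP:
#' dU = ((alpha/C) grad(Phi_Av) - gamma U) dt + beta dW, dX = U dt.
#' The drift coefficient alpha = Us * Gd / Dt couples a scaling migration
#' speed Us, a drift distance scale Gd (the gradient magnitude C/Gd
#' corresponds to steady drift at Us) and the human response time Dt. The
#' Lagrangian time scale is tau = Dt, the damping gamma = 1/tau, and the
#' noise amplitude is chosen as beta^2 = 2 sigma^2 gamma so the stationary
#' per-axis velocity standard deviation is exactly sigma.
#'
#' @param Us scaling drift velocity, km/yr (default 2.5; plausible range
#'   1-10)
#' @param Gd drift distance scale, km (default 500)
#' @param Dt response time, yr (default 1; plausible range 1-10)
#' @param sigma random-velocity standard deviation, km/yr (default 15)
#' @param alpha drift coefficient, km^2/yr^2; derived as Us*Gd/Dt when NULL
#'   (defaults give the standard simulation value 1250)
#' @param dt integration step, yr (default 1)
#' @return object of class `mobility_params` with derived `tau`, `gamma`,
#'   `beta`
#' @export
mobility_params <- function(Us = 2.5, Gd = 500, Dt = 1, sigma = 15,
                            alpha = NULL, dt = 1) {
  if (Us <= 0 || Gd <= 0 || Dt <= 0 || sigma < 0 || dt <= 0) {
    stopf("parameter error: Us, Gd, Dt, dt must be > 0 and sigma >= 0")
  }
  if (is.null(alpha)) alpha <- drift_coefficient(Us, Gd, Dt)
  if (alpha <= 0) stopf("parameter error: alpha must be > 0")
  tau <- Dt
  oc <- ou_coefficients(sigma, tau)
  structure(list(Us = Us, Gd = Gd, Dt = Dt, sigma = sigma, alpha = alpha,
                 tau = tau, gamma = oc$gamma, beta = oc$beta, dt = dt),
            class = "mobility_params")
}

#' Drift coefficient from its scaling ingredients
#'
#' alpha = Us * Gd / Dt, km^2/yr^2. With Gd = 500 km and the stated ranges
#' Us in [1, 10] km/yr and Dt in [1, 10] yr, alpha spans 50 to 5000 with a
#' maximum of 5000 km^2/yr^2 at (Us, Dt) = (10, 1).
#'
#' @param Us scaling drift velocity, km/yr
#' @param Gd drift distance scale, km
#' @param Dt response time, yr
#' @return alpha in km^2/yr^2
#' @export
drift_coefficient <- function(Us, Gd, Dt) {
  if (any(c(Us, Gd, Dt) <= 0)) stopf("parameter error: inputs must be > 0")
  Us * Gd / Dt
}

#' Damping and noise coefficients of the velocity process
#'
#' gamma = 1/tau; beta = sigma * sqrt(2 * gamma), the stationary-variance
#' convention under which the damped velocity process has per-axis standard
#' deviation exactly `sigma` (diffusivity sigma^2 * tau per axis).
#'
#' @param sigma velocity standard deviation, km/yr
#' @param tau Lagrangian time scale, yr
#' @return list with `gamma` (1/yr) and `beta` (km yr^-3/2)
#' @export
ou_coefficients <- function(sigma, tau) {
  if (sigma < 0 || tau <= 0) stopf("parameter error: sigma >= 0 and tau > 0 required")
  gamma <- 1 / tau
  list(gamma = gamma, beta = sigma * sqrt(2 * gamma))
}

#' Gradient of the available-HEP field
#'
#' Central finite differences on the grid; sea cells enter as Phi_Av = 0 (so
#' the gradient near a coast points inland toward higher Phi_Av), one-sided
#' differences at the domain edges. With agent positions given, the gradient
#' fields are bilinearly interpolated to the positions.
#'
#' @param phi_av [raster_field()] (or matrix) of available HEP, PDU
#' @param grid a [grid_spec()] (taken from `phi_av` when it is a field)
#' @param x,y optional agent positions, km; both or neither
#' @return with positions: list of vectors `gx`, `gy` (PDU/km); without:
#'   list of matrices `gx`, `gy`
#' @export
phi_av_gradient <- function(phi_av, grid = NULL, x = NULL, y = NULL) {
  if (inherits(phi_av, "raster_field")) {
    grid <- phi_av$grid
    v <- phi_av$values
    v[!phi_av$mask] <- 0
  } else {
    if (is.null(grid)) stopf("grid required when phi_av is a plain matrix")
    v <- phi_av
    v[is.na(v)] <- 0
  }
  cs <- grid$cell_size
  nx <- grid$nx; ny <- grid$ny
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:(nx - 1)] <- (v[, 3:nx] - v[, 1:(nx - 2)]) / (2 * cs)
  gx[, 1] <- (v[, 2] - v[, 1]) / cs
  gx[, nx] <- (v[, nx] - v[, nx - 1]) / cs
  gy[2:(ny - 1), ] <- (v[3:ny, ] - v[1:(ny - 2), ]) / (2 * cs)
  gy[1, ] <- (v[2, ] - v[1, ]) / cs
  gy[ny, ] <- (v[ny, ] - v[ny - 1, ]) / cs
  if (is.null(x)) return(list(gx = gx, gy = gy))
  if (anyNA(cell_index(grid, x, y)$cell)) stopf("position off-grid")
  list(gx = interp_bilinear(grid, gx, x, y),
       gy = interp_bilinear(grid, gy, x, y))
}

#' One motion step of all agents
#'
#' The velocity update is the exact one-step solution of the linear
#' (Ornstein-Uhlenbeck) velocity equation with the local drift acceleration
#' a_d = (alpha/C) grad(Phi_Av) held constant over the step:
#' U <- e^(-gamma dt) U + (1 - e^(-gamma dt)) a_d/gamma
#'      + sigma sqrt(1 - e^(-2 gamma dt)) N(0, I),
#' followed by X <- X + U dt and boundary reflection. This reduces to the
#' Euler-Maruyama update for small gamma*dt but is unconditionally stable and
#' keeps the stationary velocity std exactly sigma at any step size
#' (the default presets have gamma*dt = 1, where Euler-Maruyama would inflate
#' the velocity variance by a factor 2).
#'
#' @param agents agent data.frame with columns x, y, u, v
#' @param phi_av [raster_field()] of available HEP, PDU
#' @param mp a [mobility_params()]
#' @param C cultural carrying capacity, PDU (scales the drift term)
#' @param dt step, yr (default `mp$dt`)
#' @param land_mask logical matrix for reflection; NULL = no coast
#' @return updated agent data.frame (attribute `n_fallback`: agents whose
#'   reflection had to revert to the pre-move position)
#' @export
step_motion <- function(agents, phi_av, mp, C, dt = mp$dt, land_mask = NULL) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  if (anyNA(phi_av$values[phi_av$mask])) {
    bad <- which(is.na(phi_av$values) & phi_av$mask, arr.ind = TRUE)[1, ]
    stopf("NaN in phi_av at cell (iy=%d, ix=%d)", bad[1], bad[2])
  }
  gr <- phi_av_gradient(phi_av, x = agents$x, y = agents$y)
  a <- exp(-mp$gamma * dt)
  drift_u <- (mp$alpha / C) * gr$gx / mp$gamma
  drift_v <- (mp$alpha / C) * gr$gy / mp$gamma
  noise_sd <- mp$sigma * sqrt(1 - a^2)
  u_new <- a * agents$u + (1 - a) * drift_u + noise_sd * stats::rnorm(n)
  v_new <- a * agents$v + (1 - a) * drift_v + noise_sd * stats::rnorm(n)
  x_new <- agents$x + u_new * dt
  y_new <- agents$y + v_new * dt
  out <- agents
  out$x <- x_new; out$y <- y_new; out$u <- u_new; out$v <- v_new
  reflect_boundaries(out, land_mask, phi_av$grid,
                     x_prev = agents$x, y_prev = agents$y)
}

# safe land lookup: FALSE outside the domain
.is_land <- function(land_mask, grid, x, y) {
  idx <- cell_index(grid, x, y)
  ok <- !is.na(idx$cell)
  res <- rep(FALSE, length(x))
  if (is.null(land_mask)) {
    res[ok] <- TRUE
  } else {
    res[ok] <- land_mask[idx$cell[ok]]
  }
  res
}

#' Reflect agents off coastlines and the domain boundary
#'
#' Moves ending outside the domain are mirrored across the crossed domain
#' wall with the normal velocity component negated. Moves ending on a sea
#' cell are mirrored across the crossed cell edge (per axis; both if the move
#' crossed a corner). If no mirror lands on land — e.g. a one-cell channel —
#' the agent reverts to its pre-move position with fully reversed velocity
#' (counted in the `n_fallback` attribute). After the call no agent is on
#' water or outside the domain.
#'
#' @param agents agent data.frame after a tentative move
#' @param land_mask logical matrix, TRUE = land; NULL = all land
#' @param grid a [grid_spec()]
#' @param x_prev,y_prev pre-move positions (required to identify crossed
#'   edges)
#' @return corrected agent data.frame with attribute `n_fallback`
#' @export
reflect_boundaries <- function(agents, land_mask, grid, x_prev, y_prev) {
  n <- nrow(agents)
  if (n == 0) { attr(agents, "n_fallback") <- 0L; return(agents) }
  xmin <- grid$origin_x; xmax <- grid$origin_x + grid$nx * grid$cell_size
  ymin <- grid$origin_y; ymax <- grid$origin_y + grid$ny * grid$cell_size
  x <- agents$x; y <- agents$y; u <- agents$u; v <- agents$v

  # domain walls: mirror position, negate normal velocity
  lo <- x < xmin; hi <- x >= xmax
  u[lo | hi] <- -u[lo | hi]
  x[lo] <- 2 * xmin - x[lo]
  x[hi] <- 2 * xmax - x[hi]
  lo <- y < ymin; hi <- y >= ymax
  v[lo | hi] <- -v[lo | hi]
  y[lo] <- 2 * ymin - y[lo]
  y[hi] <- 2 * ymax - y[hi]
  # pathological overshoot beyond the far wall: treat below as fallback

  bad <- !.is_land(land_mask, grid, x, y)
  n_fallback <- 0L
  if (any(bad)) {
    cs <- grid$cell_size
    b <- which(bad)
    p0 <- cell_index(grid, x_prev[b], y_prev[b])
    p1 <- cell_index(grid, x[b], y[b])
    # edge of the previous cell in the direction of motion
    ex <- ifelse(!is.na(p1$ix) & p1$ix > p0$ix, xmin + p0$ix * cs,
          ifelse(!is.na(p1$ix) & p1$ix < p0$ix, xmin + (p0$ix - 1) * cs, NA))
    ey <- ifelse(!is.na(p1$iy) & p1$iy > p0$iy, ymin + p0$iy * cs,
          ifelse(!is.na(p1$iy) & p1$iy < p0$iy, ymin + (p0$iy - 1) * cs, NA))
    mx <- ifelse(is.na(ex), x[b], 2 * ex - x[b])
    my <- ifelse(is.na(ey), y[b], 2 * ey - y[b])
    # candidates in order: mirror x, mirror y, mirror both
    ok1 <- !is.na(ex) & .is_land(land_mask, grid, mx, y[b])
    ok2 <- !ok1 & !is.na(ey) & .is_land(land_mask, grid, x[b], my)
    ok3 <- !ok1 & !ok2 & !is.na(ex) & !is.na(ey) &
      .is_land(land_mask, grid, mx, my)
    none <- !(ok1 | ok2 | ok3)
    x[b][ok1] <- mx[ok1];            u[b][ok1] <- -u[b][ok1]
    y[b][ok2] <- my[ok2];            v[b][ok2] <- -v[b][ok2]
    x[b][ok3] <- mx[ok3];            y[b][ok3] <- my[ok3]
    u[b][ok3] <- -u[b][ok3];         v[b][ok3] <- -v[b][ok3]
    # trapped: revert to pre-move position, reverse full velocity
    x[b][none] <- x_prev[b][none];   y[b][none] <- y_prev[b][none]
    u[b][none] <- -u[b][none];       v[b][none] <- -v[b][none]
    n_fallback <- sum(none)
  }
  agents$x <- x; agents$y <- y; agents$u <- u; agents$v <- v
  attr(agents, "n_fallback") <- n_fallback
  agents
}
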
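.empty_agents <- function() {
  data.frame(id = integer(0), population = character(0),
             x = numeric(0), y = numeric(0),
             u = numeric(0), v = numeric(0), alive = logical(0),
             stringsAsFactors = FALSE)
}

# multiplicative uniform (or gaussian) perturbation of one scalar
.perturb <- function(value, perturb, mode) {
  if (perturb == 0) return(value)
  f <- if (mode == "uniform") stats::runif(1, 1 - perturb, 1 + perturb)
       else stats::rnorm(1, 1, perturb / 2)
  value * f
}

# perturb all perturbable scalars of one population's parameter set;
# invariant violations are clipped back into range and logged via attribute
.perturb_population <- function(pop, mob, perturb, mode) {
  clipped <- character(0)
  clip <- function(v, lo = NULL, hi = NULL, nm = "") {
    if (!is.null(lo) && v < lo) { clipped <<- c(clipped, nm); v <- lo }
    if (!is.null(hi) && v > hi) { clipped <<- c(clipped, nm); v <- hi }
    v
  }
  p <- population_params(
    C = clip(.perturb(pop$C, perturb, mode), lo = 1e-9, nm = "C"),
    ro = clip(.perturb(pop$ro, perturb, mode), lo = 1e-9, nm = "ro"),
    eta_g = clip(.perturb(pop$eta_g, perturb, mode), hi = -1e-9, nm = "eta_g"),
    eps_g = .perturb(pop$eps_g, perturb, mode),
    rho_d = clip(.perturb(pop$rho_d, perturb, mode), lo = 1e-9, nm = "rho_d"),
    eps_a = pop$eps_a, eta_a = pop$eta_a)
  m <- mobility_params(
    Us = mob$Us, Gd = mob$Gd,
    Dt = clip(.perturb(mob$Dt, perturb, mode), lo = 1e-9, nm = "Dt"),
    sigma = clip(.perturb(mob$sigma, perturb, mode), lo = 1e-9, nm = "sigma"),
    alpha = clip(.perturb(mob$alpha, perturb, mode), lo = 1e-9, nm = "alpha"),
    dt = mob$dt)
  list(pop = p, mobility = m, clipped = clipped)
}

#' Run a perturbed-parameter ensemble
#'
#' Per member, every perturbable scalar parameter (C, ro, eta_g, eps_g,
#' rho_d, alpha, sigma, Dt and the admixture probability) is multiplied by an
#' independent uniform draw from [1 - perturb, 1 + perturb] (default 10%;
#' Gaussian mode available), and the member is run with its own derived seed.
#' Perturbations that would break a parameter invariant are clipped into
#' range and logged.
#'
#' @param scn a [scenario()]
#' @param n_members ensemble size (>= 1; the full production configuration is
#'   1000)
#' @param perturb relative perturbation amplitude (default 0.10)
#' @param seed master seed
#' @param mode "uniform" (default) or "gaussian"
#' @return object of class `ensemble_summary`: `times`, `mean`/`sd` matrices
#'   (time x population) of population size, `member_sizes` (list of
#'   per-member matrices), `mean_density` (list per population at snapshot
#'   cadence), `members` (perturbed parameter draws), `n_members`
#' @export
run_ensemble <- function(scn, n_members, perturb = 0.10, seed = 1,
                         mode = c("uniform", "gaussian")) {
  mode <- match.arg(mode)
  if (n_members < 1) stopf("n_members must be >= 1")
  pops <- names(scn$populations)
  member_sizes <- vector("list", n_members)
  members <- vector("list", n_members)
  dens_sum <- NULL
  clip_log <- character(0)

  for (m in seq_len(n_members)) {
    ms <- derive_seed(seed, "member", m)
    drawn <- with_seed(derive_seed(ms, "perturb"), {
      ov <- lapply(scn$populations, function(pc) {
        .perturb_population(pc$pop, pc$mobility, perturb, mode)
      })
      p_adm <- if (!is.null(scn$admixture)) {
        min(max(.perturb(scn$admixture$p_adm, perturb, mode), 0), 1)
      } else NULL
      list(ov = ov, p_adm = p_adm)
    })
    clip_log <- c(clip_log, unlist(lapply(drawn$ov, `[[`, "clipped")))
    out <- run_simulation(scn, seed = ms, overrides = drawn$ov,
                          p_adm_override = drawn$p_adm)
    member_sizes[[m]] <- out$pop_size
    members[[m]] <- list(params = drawn$ov, p_adm = drawn$p_adm, seed = ms)
    if (scn$record_every > 0) {
      if (is.null(dens_sum)) {
        dens_sum <- lapply(out$snapshots, function(sl) lapply(sl, identity))
      } else {
        for (nm in pops) {
          for (k in seq_along(out$snapshots[[nm]])) {
            dens_sum[[nm]][[k]] <- dens_sum[[nm]][[k]] + out$snapshots[[nm]][[k]]
          }
        }
      }
    }
    snap_times <- out$snap_times
    times <- out$times
  }
  if (length(clip_log)) {
    warnf("parameter perturbations clipped to range: %s",
          paste(unique(clip_log), collapse = ", "))
  }

  arr <- simplify2array(member_sizes)  # time x pop x member
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  if (n_members == 1) sdv[] <- 0
  mean_density <- if (!is.null(dens_sum)) {
    lapply(dens_sum, function(sl) lapply(sl, function(m0) m0 / n_members))
  } else NULL
  structure(list(times = times, mean = mu, sd = sdv,
                 member_sizes = member_sizes, mean_density = mean_density,
                 snap_times = snap_times, members = members,
                 n_members = n_members, perturb = perturb,
                 spinup_exclude = scn$spinup_exclude),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d members, %d steps, populations: %s\n",
              x$n_members, length(x$times),
              paste(colnames(x$mean), collapse = ", ")))
  invisible(x)
}

#' Rate of change of the ensemble-mean density
#'
#' Per-cell finite difference (<rho(t + dt_lag)> - <rho(t)>) / dt_lag of the
#' ensemble-mean density snapshots, in PDU/yr (multiply by 100 for the
#' conventional PDU per century display).
#'
#' @param mean_density list of ensemble-mean density matrices
#' @param snap_times times (yr) of the snapshots
#' @param dt_lag differencing interval, yr (default 500)
#' @return list with `times` (start of each interval) and `fields` (list of
#'   matrices, PDU/yr)
#' @export
rate_of_change <- function(mean_density, snap_times, dt_lag = 500) {
  pairs <- lapply(seq_along(snap_times), function(i) {
    j <- match(snap_times[i] + dt_lag, snap_times)
    if (is.na(j)) NULL else c(i, j)
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) {
    stopf("missing snapshot: no pair of snapshots separated by %g yr", dt_lag)
  }
  list(times = vapply(pairs, function(p) snap_times[p[1]], numeric(1)),
       fields = lapply(pairs, function(p) {
         (mean_density[[p[2]]] - mean_density[[p[1]]]) / dt_lag
       }))
}

#' Fractions of ensemble members falling below population thresholds
#'
#' For each threshold, the fraction of members whose minimum population size
#' within the window is below it (exactly zero for the extinction threshold
#' 0). Fractions are nondecreasing in the threshold.
#'
#' @param member_sizes list of per-member population-size matrices (time x
#'   population), or a members x time matrix for a single population
#' @param thresholds numeric vector, e.g. c(0, 30, 50)
#' @param population column name when matrices are passed
#' @param times time vector matching rows; required with `window`
#' @param window optional c(t_min, t_max) restriction, yr
#' @return named numeric vector of fractions
#' @export
threshold_fractions <- function(member_sizes, thresholds,
                                population = NULL, times = NULL,
                                window = NULL) {
  series <- if (is.list(member_sizes)) {
    lapply(member_sizes, function(m) {
      if (!is.null(population)) m[, population] else m[, 1]
    })
  } else {
    lapply(seq_len(nrow(member_sizes)), function(i) member_sizes[i, ])
  }
  if (!is.null(window)) {
    if (is.null(times)) stopf("times required with a window")
    keep <- times >= window[1] & times <= window[2]
    if (!any(keep)) stopf("empty window")
    series <- lapply(series, function(s) s[keep])
  }
  mins <- vapply(series, min, numeric(1))
  out <- vapply(thresholds, function(th) {
    if (th == 0) mean(mins == 0) else mean(mins < th)
  }, numeric(1))
  stats::setNames(out, paste0("below_", thresholds))
}
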
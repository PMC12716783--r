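# common fixture: stack + presence pattern with a-priori structure
hep_world <- function(seed = 4, nx = 14, ny = 14) {
  g <- tiny_grid(nx, ny)
  st <- compute_bioclim(random_climate(g, seed = seed))
  thr <- apriori_thresholds()   # Bio1 in [-2, 16], Bio13 in [30, 250]
  list(g = g, st = st, thr = thr)
}

test_that("threshold objects enforce lower < upper", {
  expect_error(apriori_thresholds(list(Bio1 = c(5, 5))), "lower < upper")
  thr <- apriori_thresholds()
  expect_equal(thr$bounds$Bio1, c(-2, 16))
  expect_equal(thr$bounds$Bio13, c(30, 250))
})

test_that("cold cells without sites are labeled a-priori absent", {
  g <- tiny_grid(4, 4)
  clim <- constant_climate(g, t0 = 10, p0 = 50)
  clim$tmean[1, 1, ] <- -5          # BIO1 = -5 degC, below the -2 bound
  st <- compute_bioclim(clim)
  pres <- matrix(FALSE, 4, 4); pres[3, 3] <- TRUE
  lab <- label_cells(pres, st, apriori_thresholds(list(Bio1 = c(-2, 16))),
                     pa_option = 1, seed = 1)
  cold_cell <- which(lab$cells == 1L)  # linear cell 1 is (1,1)
  expect_equal(lab$class[cold_cell], "apriori")
  expect_equal(lab$y[cold_cell], 0)
  expect_equal(lab$y[lab$class == "presence"], 1)
})

test_that("presence beats a violated a-priori threshold, with a warning", {
  g <- tiny_grid(4, 4)
  clim <- constant_climate(g, t0 = 10, p0 = 50)
  clim$tmean[2, 2, ] <- -5
  st <- compute_bioclim(clim)
  pres <- matrix(FALSE, 4, 4); pres[2, 2] <- TRUE
  expect_warning(
    lab <- label_cells(pres, st, apriori_thresholds(list(Bio1 = c(-2, 16))),
                       pa_option = 1, seed = 1),
    "presence kept")
  expect_equal(lab$y[lab$class == "presence"], 1)
  expect_equal(length(lab$conflicts), 1L)
})

test_that("pseudo-absence options realize the prescribed label laws", {
  w <- hep_world()
  # force known Np/Npa: choose presence cells, no a-priori violations
  pres <- matrix(FALSE, w$g$ny, w$g$nx)
  pres[1:6, 1:10] <- TRUE           # Np = 60
  thr <- apriori_thresholds(list(Bio1 = c(-1e6, 1e6)))
  lab1 <- label_cells(pres, w$st, thr, pa_option = 1, seed = 1)
  expect_equal(lab1$Np, 60L)
  expect_equal(lab1$Npa, 14 * 14 - 60)
  # option 1: training set is exactly presence + apriori cells (none here)
  expect_equal(sum(!is.na(lab1$y)), 60L)

  # option 2: thirds relabeled presence / absence, remainder excluded
  lab2 <- label_cells(pres, w$st, thr, pa_option = 2, seed = 2)
  ps <- lab2$class == "pseudo"
  k <- floor(sum(ps) / 3)
  expect_equal(sum(lab2$y[ps] == 1, na.rm = TRUE), k)
  expect_equal(sum(lab2$y[ps] == 0, na.rm = TRUE), k)
  expect_equal(sum(is.na(lab2$y[ps])), sum(ps) - 2 * k)

  # option 3: per-cell relabel probability Np/(Np+Npa); empirical rate over
  # many realizations within 3 binomial sigma
  p_true <- 60 / 196
  draws <- 0L; total <- 0L
  for (s in 1:100) {
    y <- label_cells(pres, w$st, thr, pa_option = 3, seed = s)$y
    draws <- draws + sum(y[ps] == 1)
    total <- total + sum(ps)
  }
  se <- sqrt(p_true * (1 - p_true) / total)
  expect_lt(abs(draws / total - p_true), 3 * se)
})

test_that("the logistic map and closed-form intercepts behave", {
  p <- c("Bio1", "Bio4")
  model <- list(A = matrix(0, 2, 2, dimnames = list(p, p)),
                B = c(0, 0), c0 = 0, predictors = p)
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, p))
  expect_equal(predict_hep(model, Z), rep(0.5, 10))  # q = 0 -> 0.5
  model$c0 <- log(3)
  expect_equal(predict_hep(model, Z), rep(0.75, 10)) # logistic(ln 3) = 0.75
})

test_that("fit_hep recovers known quadratic-logistic coefficients", {
  set.seed(21)
  n <- 5000
  p <- c("Bio1", "Bio4", "Bio16")
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, p))
  A_true <- matrix(c(-0.8, 0.2, 0, 0.2, -0.4, 0, 0, 0, -0.5), 3, 3,
                   dimnames = list(p, p))
  B_true <- c(0.9, -0.6, 0.4); c0_true <- 0.3
  q <- 0.5 * rowSums((Z %*% A_true) * Z) + Z %*% B_true + c0_true
  y <- rbinom(n, 1, plogis(q))
  fit <- fit_hep(y, Z)
  expect_s3_class(fit, "hep_model")
  expect_equal(fit$A, t(fit$A))       # symmetry by construction

  # independent oracle: glm on a design built here, with its own SEs
  X <- cbind(Z, Z[, 1]^2, Z[, 1] * Z[, 2], Z[, 1] * Z[, 3],
             Z[, 2]^2, Z[, 2] * Z[, 3], Z[, 3]^2)
  or <- glm(y ~ X, family = binomial())
  se <- sqrt(diag(vcov(or)))
  truth <- c(c0_true, B_true, 0.5 * A_true[1, 1], A_true[1, 2], A_true[1, 3],
             0.5 * A_true[2, 2], A_true[2, 3], 0.5 * A_true[3, 3])
  mine <- c(fit$c0, fit$B, 0.5 * fit$A[1, 1], fit$A[1, 2], fit$A[1, 3],
            0.5 * fit$A[2, 2], fit$A[2, 3], 0.5 * fit$A[3, 3])
  expect_true(all(abs(mine - truth) < 3 * se))
  # and the two routes agree on the fitted surface
  expect_equal(unname(predict_hep(fit, Z)),
               unname(fitted(or)), tolerance = 1e-6)
})

test_that("separated data falls back to a flagged ridge fit", {
  set.seed(5)
  Z <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("Bio1", "Bio4")))
  y <- as.numeric(Z[, 1] > 0)      # perfectly separable
  fit <- suppressWarnings(fit_hep(y, Z))
  expect_true(fit$ridged)
  expect_true(all(is.finite(c(fit$A, fit$B, fit$c0))))
  phi <- predict_hep(fit, Z)
  expect_gt(auc_score(y, phi), 0.99)
})

test_that("fit_hep requires both classes", {
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_hep(rep(1, 10), Z), "positive and one negative")
})

test_that("hep ensembles are sized, seeded and deterministic", {
  w <- hep_world(seed = 8)
  tr <- true_hep_field(w$st, default_true_hep())
  pres <- matrix(FALSE, w$g$ny, w$g$nx)
  pres[as.vector(tr$field$values) > quantile(tr$field$values, 0.8, na.rm = TRUE)] <- TRUE
  thr <- apriori_thresholds(list(Bio1 = c(-1e6, 1e6)))
  e1 <- hep_ensemble(pres, w$st, thr, n_members = 7, seed = 3)
  expect_equal(e1$n_members, 7L)
  expect_equal(length(e1$members), 7L)
  e2 <- hep_ensemble(pres, w$st, thr, n_members = 7, seed = 3)
  expect_identical(e1$mean_field$values, e2$mean_field$values)
  expect_true(all(e1$mean_field$values[e1$mean_field$mask] >= 0 &
                  e1$mean_field$values[e1$mean_field$mask] <= 1))
})

test_that("ensemble spread vanishes when every member sees identical data", {
  w <- hep_world(seed = 12)
  pres <- matrix(FALSE, w$g$ny, w$g$nx)
  pres[seq(1, 196, by = 7)] <- TRUE
  # option 1 labels are deterministic; train_frac 1 removes split variation
  thr <- apriori_thresholds(list(Bio1 = c(quantile(w$st$layers$Bio1, 0.3,
                                                   na.rm = TRUE), 1e6)))
  ens <- suppressWarnings(
    hep_ensemble(pres, w$st, thr, pa_option = 1, train_frac = 1,
                 n_members = 5, seed = 2))
  expect_lt(max(ens$sd_field$values[ens$sd_field$mask]), 1e-12)
})

test_that("modification function reproduces plateau, floor and midpoint", {
  expect_equal(modification_g(100, 350, 2000), 1.0)
  expect_equal(modification_g(2500, 350, 2000), 0.8)
  expect_equal(modification_g((350 + 2000) / 2, 350, 2000), 0.9)
  expect_equal(modification_g(2000, 350, 2000), 0.8)  # continuous at xu
  # continuity at xl
  expect_equal(modification_g(350, 350, 2000),
               modification_g(350 - 1e-9, 350, 2000), tolerance = 1e-6)
  expect_error(modification_g(1, 400, 400), "xl must be")
})

test_that("population modification presets carry the published thresholds", {
  amh <- mod_func_params("AMH")
  expect_equal(amh$g1, c(350, 2000))
  expect_equal(amh$g2, c(70, 400))
  nea <- mod_func_params("NEA")
  expect_equal(nea$g1, c(450, 2000))
  expect_null(nea$g2)   # roughness excluded for Middle-Paleolithic sites
})

test_that("accessible HEP multiplies the modification chain", {
  w <- island_world()
  g <- w$grid
  phi <- raster_field(g, matrix(0.8, g$ny, g$nx),
                      mask = w$landscape$land_mask)
  amh <- mod_func_params("AMH")
  # elevation 100 m, roughness 10 m: all factors 1
  ac <- accessible_hep(phi, w$landscape, amh)
  expect_equal(unique(ac$values[ac$mask]), 0.8)
  expect_true(all(ac$values[!w$landscape$land_mask] %in% c(0, NA)))

  # elevation 2500 m -> plateau factor 0.8 -> 0.64
  high <- w$landscape
  high$elevation$values[high$land_mask] <- 2500
  ac2 <- accessible_hep(phi, high, amh)
  expect_equal(unique(ac2$values[ac2$mask]), 0.8 * 0.8)

  # forest cells are uninhabitable
  forested <- w$landscape
  forested$forest_mask[6, 6] <- TRUE
  ac3 <- accessible_hep(phi, forested, amh)
  expect_equal(ac3$values[6, 6], 0)

  # pointwise dominance by the unmodified suitability
  expect_true(all(ac$values[ac$mask] <= phi$values[phi$mask] + 1e-12))
})

test_that("HEP models round-trip through JSON", {
  tp <- default_true_hep()
  tp$stats <- data.frame(name = tp$predictors, mean = 1:5, sd = rep(2, 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_hep_model(tp, path)
  back <- read_hep_model(path)
  expect_equal(unname(back$A), unname(tp$A))
  expect_equal(back$B, tp$B)
  expect_equal(back$c0, tp$c0)
  Z <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, tp$predictors))
  expect_equal(predict_hep(back, Z), predict_hep(tp, Z))
})
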
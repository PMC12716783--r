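#' A-priori absence thresholds on bioclim variables
#'
#' Cells violating any (lower, upper) bound are treated as a-priori absences
#' (suitability 0) during HEP training. The shipped default is the modern-
#' human pair: annual mean temperature Bio1 in [-2, 16] degC and wettest-month
#' precipitation Bio13 in [30, 250] mm (95% bounds at known sites).
#'
#' @param bounds named list of c(lower, upper) per bioclim variable
#' @return object of class `apriori_thresholds`
#' @export
apriori_thresholds <- function(bounds = list(Bio1 = c(-2, 16),
                                             Bio13 = c(30, 250))) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2])) {
      stopf("threshold for %s must be c(lower, upper) with lower < upper", nm)
    }
  }
  structure(list(bounds = bounds), class = "apriori_thresholds")
}

#' Derive thresholds from presence cells (percentile rule)
#'
#' Mirrors the construction of the default bounds: central 95% interval of
#' each variable's distribution at presence cells. Used for populations whose
#' bounds are not prescribed (e.g. Neanderthals).
#'
#' @param stack a [compute_bioclim()] result
#' @param presence logical matrix/vector of presence cells
#' @param vars variables to bound
#' @param probs percentile pair (default 2.5%/97.5%)
#' @return an [apriori_thresholds()]
#' @export
thresholds_from_presence <- function(stack, presence,
                                     vars = c("Bio1", "Bio13"),
                                     probs = c(0.025, 0.975)) {
  cells <- which(as.vector(presence))
  if (!length(cells)) stopf("no presence cells")
  X <- bioclim_matrix(stack, vars, cells = cells)
  bounds <- lapply(stats::setNames(vars, vars), function(nm) {
    unname(stats::quantile(X[, nm], probs = probs, na.rm = TRUE))
  })
  apriori_thresholds(bounds)
}

# classify land cells into presence / apriori absence / pseudo absence.
# presence wins over a violated threshold (conflicts recorded).
.classify_pa <- function(presence, stack, thresholds) {
  land <- which(as.vector(stack$land_mask))
  pres <- as.vector(presence)[land]
  viol <- rep(FALSE, length(land))
  for (nm in names(thresholds$bounds)) {
    b <- thresholds$bounds[[nm]]
    v <- as.vector(stack$layers[[nm]])[land]
    viol <- viol | (!is.na(v) & (v < b[1] | v > b[2]))
  }
  cls <- ifelse(pres, "presence", ifelse(viol, "apriori", "pseudo"))
  conflicts <- land[pres & viol]
  if (length(conflicts)) {
    warnf("%d presence cell(s) violate a-priori thresholds; presence kept",
          length(conflicts))
  }
  list(cells = land, class = cls, conflicts = conflicts,
       Np = sum(cls == "presence"), Npa = sum(cls == "pseudo"))
}

#' Label cells for HEP training (presence / absence / pseudo-absence)
#'
#' Presence cells get label 1 and a-priori absences (any bioclim threshold
#' violated) label 0. Pseudo-absence cells — habitable but without record —
#' are realized per training option: (1) excluded entirely; (2) a random
#' third relabeled presence, a third absence, a third excluded; (3) each cell
#' independently relabeled presence with probability Np/(Np+Npa), else
#' absence. Options 2 and 3 are re-randomized per ensemble member.
#'
#' @param presence logical matrix/vector: cells with at least one site
#' @param stack a [compute_bioclim()] result
#' @param thresholds an [apriori_thresholds()]
#' @param pa_option pseudo-absence treatment, 1, 2 or 3 (default 3)
#' @param seed RNG seed for the realization
#' @return object of class `pa_labels`: list with `cells` (linear indices),
#'   `class` (presence/apriori/pseudo), `y` (realized 0/1, NA = excluded),
#'   `Np`, `Npa`, `conflicts`
#' @export
label_cells <- function(presence, stack, thresholds, pa_option = 3,
                        seed = NULL) {
  cls <- .classify_pa(presence, stack, thresholds)
  y <- with_seed(seed, .realize_pa(cls, pa_option))
  structure(list(cells = cls$cells, class = cls$class, y = y,
                 Np = cls$Np, Npa = cls$Npa, conflicts = cls$conflicts,
                 pa_option = pa_option), class = "pa_labels")
}

# one stochastic realization of the pseudo-absence treatment
.realize_pa <- function(cls, pa_option) {
  y <- rep(NA_real_, length(cls$cells))
  y[cls$class == "presence"] <- 1
  y[cls$class == "apriori"] <- 0
  ps <- which(cls$class == "pseudo")
  if (!length(ps)) return(y)
  if (pa_option == 1) {
    # excluded
  } else if (pa_option == 2) {
    perm <- sample(ps)
    k <- floor(length(ps) / 3)
    if (k > 0) {
      y[perm[seq_len(k)]] <- 1
      y[perm[k + seq_len(k)]] <- 0
    }
    # remainder excluded
  } else if (pa_option == 3) {
    p1 <- cls$Np / (cls$Np + cls$Npa)
    y[ps] <- as.numeric(stats::runif(length(ps)) < p1)
  } else {
    stopf("pa_option must be 1, 2 or 3")
  }
  y
}

# expanded design matrix: p linear columns then p*(p+1)/2 quadratic columns
# x_i * x_j for i <= j
.quad_design <- function(Z) {
  p <- ncol(Z)
  quads <- list()
  nm <- character(0)
  for (i in seq_len(p)) for (j in i:p) {
    quads[[length(quads) + 1]] <- Z[, i] * Z[, j]
    nm <- c(nm, paste0(colnames(Z)[i], ":", colnames(Z)[j]))
  }
  Q <- do.call(cbind, quads)
  colnames(Q) <- nm
  cbind(Z, Q)
}

# repack glm coefficients into symmetric A, linear B, intercept c0 such that
# q = 0.5 * t(P) A P + B . P + c0
.repack_quad <- function(coefs, names_p) {
  p <- length(names_p)
  B <- coefs[names_p]
  A <- matrix(0, p, p, dimnames = list(names_p, names_p))
  for (i in seq_len(p)) for (j in i:p) {
    th <- coefs[paste0(names_p[i], ":", names_p[j])]
    if (i == j) A[i, i] <- 2 * th else A[i, j] <- A[j, i] <- th
  }
  list(A = A, B = unname(B), c0 = unname(coefs["(Intercept)"]))
}

#' Fit the quadratic-logistic HEP model
#'
#' Maximum-likelihood logistic regression of realized presence/absence labels
#' on the expanded feature vector (all linear terms plus all unique quadratic
#' products of the standardized predictors), repacked into the symmetric
#' quadratic form q(P) = 0.5 P'AP + B.P + c0; suitability is
#' Phi_E = 1/(1 + exp(-q)). On (quasi-)separation the fit falls back to a
#' weak L2 ridge and is flagged.
#'
#' @param y realized 0/1 labels (NAs dropped)
#' @param Z standardized predictor matrix (rows matching `y`), with column
#'   names
#' @param ridge ridge strength for the separation fallback (default 1e-6)
#' @return object of class `hep_model`: A, B, c0, predictors, `ridged` flag
#' @export
fit_hep <- function(y, Z, ridge = 1e-6) {
  keep <- !is.na(y)
  y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  if (!any(y == 1) || !any(y == 0)) {
    stopf("need at least one positive and one negative label")
  }
  X <- .quad_design(Z)
  Xd <- cbind(`(Intercept)` = 1, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- stats::setNames(fit$coefficients, colnames(Xd))
  ridged <- sep || !fit$converged || anyNA(coefs)
  if (ridged) coefs <- .ridge_logistic(X, y, lambda = ridge)
  pk <- .repack_quad(coefs, colnames(Z))
  structure(list(A = pk$A, B = pk$B, c0 = pk$c0, predictors = colnames(Z),
                 ridged = ridged),
            class = "hep_model")
}

# L2-penalized logistic regression by IRLS (intercept unpenalized);
# fallback for separated fits, no external dependency
.ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)))
  b <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd * w, Xd) + pen
    bn <- solve(H, crossprod(Xd * w, z))
    if (max(abs(bn - b)) < 1e-10) { b <- bn; break }
    b <- bn
  }
  stats::setNames(drop(b), colnames(Xd))
}

#' Evaluate the quadratic-logistic suitability
#' @param model a [fit_hep()] result (or any list with A, B, c0)
#' @param Z standardized predictor matrix
#' @return vector of Phi_E in (0, 1)
#' @export
predict_hep <- function(model, Z) {
  Z <- as.matrix(Z)
  q <- 0.5 * rowSums((Z %*% model$A) * Z) + drop(Z %*% model$B) + model$c0
  stats::plogis(q)
}

#' Area under the ROC curve (rank statistic)
#' @param y 0/1 labels
#' @param p predicted scores
#' @return AUC in [0, 1]
#' @export
auc_score <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Train the HEP ensemble
#'
#' Per member: re-realize the pseudo-absence labels (options 2/3), draw a
#' random 80/20 train/validation split, fit the quadratic-logistic model,
#' score validation AUC, and predict suitability on all land cells. Members
#' with a degenerate split (a side missing a class) are resampled, never
#' silently skipped. The ensemble mean field <Phi_E> is the final suitability
#' estimate; the member spread is its uncertainty.
#'
#' @param presence logical matrix/vector of presence cells
#' @param stack a [compute_bioclim()] result
#' @param thresholds an [apriori_thresholds()]
#' @param predictors predictor layer names (default Bio1, Bio4, Bio16, Bio15,
#'   Bio17)
#' @param pa_option pseudo-absence treatment (default 3)
#' @param n_members ensemble size (default 1000)
#' @param train_frac training fraction of the 80/20 split (default 0.8)
#' @param seed master seed
#' @param keep_members keep per-member parameter sets (default TRUE)
#' @return object of class `hep_ensemble`: `mean_field` and `sd_field`
#'   ([raster_field()]s), `auc` per member, `members`, `stats`
#'   (standardization), `predictors`, `n_members`, `resampled` count
#' @export
hep_ensemble <- function(presence, stack, thresholds,
                         predictors = DEFAULT_PREDICTORS, pa_option = 3,
                         n_members = 1000, train_frac = 0.8, seed = 1,
                         keep_members = TRUE) {
  cls <- .classify_pa(presence, stack, thresholds)
  std <- standardize_bioclim(stack, predictors, training_cells = cls$cells)
  Zall <- std$values[cls$cells, , drop = FALSE]
  colnames(Zall) <- predictors
  land <- cls$cells
  nland <- length(land)

  run_mean <- rep(0, nland); run_m2 <- rep(0, nland)  # Welford accumulators
  auc <- rep(NA_real_, n_members)
  members <- if (keep_members) vector("list", n_members) else NULL
  resampled <- 0L

  for (m in seq_len(n_members)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      ms <- derive_seed(seed, "hep-member", m, attempt)
      fitted <- with_seed(ms, {
        y <- .realize_pa(cls, pa_option)
        obs <- which(!is.na(y))
        ntr <- max(1L, floor(train_frac * length(obs)))
        tr <- sort(sample(obs, ntr))  # sorted: identical data => identical fit
        va <- setdiff(obs, tr)
        ok_tr <- any(y[tr] == 1) && any(y[tr] == 0)
        ok_va <- train_frac >= 1 || (any(y[va] == 1) && any(y[va] == 0))
        if (!ok_tr || !ok_va) {
          NULL
        } else {
          fit <- fit_hep(y[tr], Zall[tr, , drop = FALSE])
          list(fit = fit,
               auc = if (length(va)) auc_score(y[va], predict_hep(fit, Zall[va, , drop = FALSE])) else NA_real_)
        }
      })
      if (!is.null(fitted)) break
      resampled <- resampled + 1L
      if (attempt > 50L) stopf("member %d: no valid split after 50 resamples", m)
    }
    phi <- predict_hep(fitted$fit, Zall)
    delta <- phi - run_mean
    run_mean <- run_mean + delta / m
    run_m2 <- run_m2 + delta * (phi - run_mean)
    auc[m] <- fitted$auc
    if (keep_members) {
      members[[m]] <- list(A = fitted$fit$A, B = fitted$fit$B,
                           c0 = fitted$fit$c0, auc = fitted$auc)
    }
  }

  g <- stack$grid
  mean_v <- matrix(NA_real_, g$ny, g$nx); mean_v[land] <- run_mean
  sd_v <- matrix(NA_real_, g$ny, g$nx)
  sd_v[land] <- sqrt(run_m2 / n_members)
  structure(list(
    mean_field = raster_field(g, mean_v, units = "", mask = stack$land_mask),
    sd_field = raster_field(g, sd_v, units = "", mask = stack$land_mask),
    auc = auc, members = members, stats = std$stats,
    predictors = predictors, n_members = n_members, pa_option = pa_option,
    resampled = resampled), class = "hep_ensemble")
}

#' @export
print.hep_ensemble <- function(x, ...) {
  cat(sprintf("hep_ensemble: %d members on %s; mean AUC %.3f\n",
              x$n_members, paste(x$predictors, collapse = ", "),
              mean(x$auc, na.rm = TRUE)))
  invisible(x)
}

#' Piecewise-linear accessibility modification function
#'
#' Value 1 below the lower threshold, a linear descent of slope
#' m = 0.2/(xu - xl) between the thresholds, and a plateau of 0.8 at and
#' above the upper threshold; continuous throughout. Applied to elevation
#' (g1) and terrain roughness (g2).
#'
#' @param x elevation or roughness, metres (vectorized)
#' @param xl,xu lower and upper thresholds, metres (xl < xu)
#' @return dimensionless factor in [0.8, 1]
#' @export
modification_g <- function(x, xl, xu) {
  if (!(xl < xu)) stopf("parameter error: xl must be < xu")
  m <- 0.2 / (xu - xl)
  ifelse(x < xl, 1.0, ifelse(x < xu, 1.0 - (x - xl) * m, 0.8))
}

#' Modification-function parameter sets per population
#'
#' Elevation thresholds (g1): modern humans 350/2000 m, Neanderthals
#' 450/2000 m. Roughness (g2): modern humans 70/400 m; disabled for
#' Neanderthals (no clear pattern at Middle-Paleolithic sites). Water cells
#' (g3 = 0) and dense forest (gx = 0) are uninhabitable for everyone.
#'
#' @param population "AMH", "NEA" or "custom"
#' @param g1,g2 c(xl, xu) in metres; `g2 = NULL` disables the roughness term
#' @return object of class `mod_func_params`
#' @export
mod_func_params <- function(population = c("AMH", "NEA", "custom"),
                            g1 = NULL, g2 = NULL) {
  population <- match.arg(population)
  if (population == "AMH") {
    g1 <- g1 %||% c(350, 2000); g2 <- g2 %||% c(70, 400)
  } else if (population == "NEA") {
    g1 <- g1 %||% c(450, 2000); g2 <- NULL
  }
  if (is.null(g1)) stopf("g1 thresholds required")
  if (!(g1[1] < g1[2])) stopf("parameter error: g1 xl must be < xu")
  if (!is.null(g2) && !(g2[1] < g2[2])) stopf("parameter error: g2 xl must be < xu")
  structure(list(population = population, g1 = g1, g2 = g2),
            class = "mod_func_params")
}

#' Accessible HEP: suitability after static-landscape modification
#'
#' Pointwise product Phi_Ac = <Phi_E> * g1(elevation) * g2(roughness) * g3 *
#' gx, where g3 = 0 on water and gx = 0 on dense forest. The roughness factor
#' is omitted (treated as 1) when disabled in `mods`.
#'
#' @param phi_e [raster_field()] of ensemble-mean suitability in [0, 1]
#' @param landscape a [landscape_bundle()]
#' @param mods a [mod_func_params()]
#' @return [raster_field()] of Phi_Ac in [0, 1]; 0 on water/forest, masked on
#'   sea
#' @export
accessible_hep <- function(phi_e, landscape, mods) {
  g <- phi_e$grid
  if (!identical(unclass(landscape$grid), unclass(g))) {
    stopf("phi_e and landscape are on different grids")
  }
  v <- phi_e$values * modification_g(landscape$elevation$values,
                                     mods$g1[1], mods$g1[2])
  if (!is.null(mods$g2)) {
    if (is.null(landscape$roughness)) stopf("roughness layer required by mods")
    v <- v * modification_g(landscape$roughness$values,
                            mods$g2[1], mods$g2[2])
  }
  v[landscape$water_mask] <- 0
  v[landscape$forest_mask] <- 0
  v[!landscape$land_mask] <- NA_real_
  raster_field(g, v, units = "", mask = landscape$land_mask)
}

#' Serialize / restore a HEP model as JSON
#' @param model a [fit_hep()] result or `hep_ensemble` member
#' @param path JSON path
#' @param stats optional standardization stats data.frame to embed
#' @return `path` invisibly; `read_hep_model` returns the restored model
#' @export
write_hep_model <- function(model, path, stats = NULL) {
  doc <- list(A = model$A, B = model$B, c0 = model$c0,
              predictors = model$predictors,
              stats = stats %||% model$stats)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hep_model
#' @export
read_hep_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(A = as.matrix(doc$A), B = as.numeric(doc$B),
                 c0 = as.numeric(doc$c0),
                 predictors = doc$predictors,
                 stats = if (!is.null(doc$stats)) as.data.frame(doc$stats) else NULL),
            class = "hep_model")
}
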
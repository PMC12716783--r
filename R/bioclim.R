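# canonical ordering of the 17 candidate predictors (tie-break order for
# cluster representatives): mean-temperature cluster, temperature
# seasonality, diurnal variation, mean precipitation, precipitation
# seasonality, mean dryness
BIOCLIM_VARS <- c("Bio1", "Bio5", "Bio6", "Bio10", "Bio11",
                  "Bio4", "Bio7", "Bio2", "Bio3",
                  "Bio12", "Bio13", "Bio16", "Bio19",
                  "Bio14", "Bio15", "Bio17", "Bio18")

# default predictor set used for HEP fitting
DEFAULT_PREDICTORS <- c("Bio1", "Bio4", "Bio16", "Bio15", "Bio17")

#' Monthly climate fields
#'
#' @param grid a [grid_spec()]
#' @param tmean array (ny, nx, 12) of monthly mean temperature, degC
#' @param precip array (ny, nx, 12) of monthly precipitation, mm/month (>= 0)
#' @param tmax,tmin optional arrays (ny, nx, 12) of monthly extreme
#'   temperatures; required only for Bio2/Bio3
#' @param land_mask logical (ny, nx); TRUE = land
#' @return object of class `monthly_climate`
#' @export
monthly_climate <- function(grid, tmean, precip, tmax = NULL, tmin = NULL,
                            land_mask = NULL) {
  dims <- c(grid$ny, grid$nx, 12L)
  for (nm in c("tmean", "precip")) {
    a <- get(nm)
    if (!identical(as.integer(dim(a)), dims)) {
      stopf("%s must be an array of shape (ny=%d, nx=%d, 12)", nm, grid$ny, grid$nx)
    }
  }
  if (is.null(land_mask)) land_mask <- matrix(TRUE, grid$ny, grid$nx)
  if (any(precip[rep(land_mask, 12)] < 0, na.rm = TRUE)) {
    stopf("precip must be >= 0 everywhere on land")
  }
  cl <- list(grid = grid, tmean = tmean, precip = precip,
             tmax = tmax, tmin = tmin, land_mask = land_mask)
  class(cl) <- "monthly_climate"
  cl
}

# (ny,nx,12) array -> (ncell, 12) matrix, one column per month
.as_month_matrix <- function(a) {
  d <- dim(a)
  matrix(a, d[1] * d[2], d[3])
}

# circular 3-month quarter aggregates: returns (ncell, 12) matrix where
# column k is the sum/mean over months k, k+1, k+2 (wrapping)
.quarter_stat <- function(m, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  q <- m[, 1:12] + m[, c(2:12, 1)] + m[, c(3:12, 1:2)]
  if (fun == "mean") q <- q / 3
  q
}

.rowmax_idx <- function(m) max.col(m, ties.method = "first")
.rowmin_idx <- function(m) max.col(-m, ties.method = "first")

#' Compute the 17 candidate bioclimatic variables
#'
#' Standard BIOCLIM conventions: Bio4 = 100 x standard deviation of monthly
#' mean temperature; Bio15 = coefficient of variation of monthly
#' precipitation (100 x sd/mean, 0 where the mean is 0); quarters are the
#' three consecutive calendar months (circular, Dec-Jan-Feb allowed)
#' maximizing or minimizing the relevant quantity. Bio2 (mean diurnal range)
#' and Bio3 (isothermality) need monthly tmax/tmin; when those are absent the
#' two layers are fully masked and cannot be selected as predictors.
#'
#' Layers: Bio1, Bio2, Bio3, Bio4, Bio5, Bio6, Bio7, Bio10, Bio11, Bio12,
#' Bio13, Bio14, Bio15, Bio16, Bio17, Bio18, Bio19.
#'
#' @param clim a [monthly_climate()]
#' @return object of class `bioclim_stack`: list with `grid`, `land_mask` and
#'   named `layers` (matrices ny x nx) with a `units` attribute each
#' @export
compute_bioclim <- function(clim) {
  g <- clim$grid
  tm <- .as_month_matrix(clim$tmean)
  pr <- .as_month_matrix(clim$precip)
  land <- as.vector(clim$land_mask)
  if (anyNA(tm[land, ]) || anyNA(pr[land, ])) {
    warnf("NaN/NA climate on land cells: propagated as masked")
  }

  hx <- if (!is.null(clim$tmax)) .as_month_matrix(clim$tmax) else tm
  hn <- if (!is.null(clim$tmin)) .as_month_matrix(clim$tmin) else tm

  n <- nrow(tm)
  L <- list()
  L$Bio1 <- rowMeans(tm)
  L$Bio4 <- apply(tm, 1, stats::sd) * 100
  L$Bio5 <- apply(hx, 1, max)
  L$Bio6 <- apply(hn, 1, min)
  L$Bio7 <- L$Bio5 - L$Bio6
  if (!is.null(clim$tmax) && !is.null(clim$tmin)) {
    L$Bio2 <- rowMeans(hx - hn)
    L$Bio3 <- ifelse(L$Bio7 > 0, L$Bio2 / L$Bio7 * 100, NA_real_)
  } else {
    L$Bio2 <- rep(NA_real_, n)
    L$Bio3 <- rep(NA_real_, n)
  }

  qt <- .quarter_stat(tm, "mean")
  qp <- .quarter_stat(pr, "sum")
  warmq <- .rowmax_idx(qt); coldq <- .rowmin_idx(qt)
  L$Bio10 <- qt[cbind(seq_len(n), warmq)]
  L$Bio11 <- qt[cbind(seq_len(n), coldq)]

  L$Bio12 <- rowSums(pr)
  L$Bio13 <- apply(pr, 1, max)
  L$Bio14 <- apply(pr, 1, min)
  prm <- rowMeans(pr)
  L$Bio15 <- ifelse(prm > 0, apply(pr, 1, stats::sd) / prm * 100, 0)
  L$Bio16 <- qp[cbind(seq_len(n), .rowmax_idx(qp))]
  L$Bio17 <- qp[cbind(seq_len(n), .rowmin_idx(qp))]
  L$Bio18 <- qp[cbind(seq_len(n), warmq)]
  L$Bio19 <- qp[cbind(seq_len(n), coldq)]

  units <- c(Bio1 = "degC", Bio2 = "degC", Bio3 = "", Bio4 = "degC",
             Bio5 = "degC", Bio6 = "degC", Bio7 = "degC",
             Bio10 = "degC", Bio11 = "degC",
             Bio12 = "mm", Bio13 = "mm", Bio14 = "mm", Bio15 = "",
             Bio16 = "mm", Bio17 = "mm", Bio18 = "mm", Bio19 = "mm")
  layers <- lapply(stats::setNames(names(units), names(units)), function(nm) {
    v <- matrix(L[[nm]], g$ny, g$nx)
    v[!clim$land_mask] <- NA_real_
    attr(v, "units") <- unname(units[nm])
    v
  })
  st <- list(grid = g, land_mask = clim$land_mask, layers = layers)
  class(st) <- "bioclim_stack"
  st
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: %d layers on %d x %d grid (%d land cells)\n",
              length(x$layers), x$grid$ny, x$grid$nx, sum(x$land_mask)))
  invisible(x)
}

#' Extract a predictor matrix (cells x variables) from a bioclim stack
#' @param stack a [compute_bioclim()] result
#' @param predictors character vector of layer names
#' @param cells optional linear cell indices (default: all cells)
#' @return numeric matrix with one column per predictor
#' @export
bioclim_matrix <- function(stack, predictors = DEFAULT_PREDICTORS, cells = NULL) {
  bad <- setdiff(predictors, names(stack$layers))
  if (length(bad)) stopf("unknown layer(s): %s", paste(bad, collapse = ", "))
  X <- vapply(predictors, function(nm) {
    v <- as.vector(stack$layers[[nm]])
    if (is.null(cells)) v else v[cells]
  }, numeric(if (is.null(cells)) stack$grid$ny * stack$grid$nx else length(cells)))
  colnames(X) <- predictors
  X
}

#' Standardize bioclim predictors over training cells
#'
#' Fits per-layer means and standard deviations over the training cells and
#' returns standardized fields; stored statistics are applied unchanged at
#' prediction time (pass them as `stats`).
#'
#' @param stack a [compute_bioclim()] result
#' @param predictors layer names to standardize
#' @param training_cells linear indices of training (land) cells; required
#'   when fitting
#' @param stats a previous result's `stats`, to apply without refitting
#' @return list with `values` (matrix ncell x p, standardized), `stats`
#'   (data.frame name/mean/sd) and `predictors`
#' @export
standardize_bioclim <- function(stack, predictors = DEFAULT_PREDICTORS,
                                training_cells = NULL, stats = NULL) {
  X <- bioclim_matrix(stack, predictors)
  if (is.null(stats)) {
    if (is.null(training_cells)) stopf("training_cells required to fit statistics")
    land <- which(as.vector(stack$land_mask))
    if (!all(training_cells %in% land)) stopf("training cells must be on land")
    mu <- colMeans(X[training_cells, , drop = FALSE])
    sd_ <- apply(X[training_cells, , drop = FALSE], 2, stats::sd)
    zero <- which(sd_ < 1e-12 | !is.finite(sd_))
    if (length(zero)) {
      stopf("zero-variance predictor(s) over training cells: %s",
            paste(predictors[zero], collapse = ", "))
    }
    stats <- data.frame(name = predictors, mean = mu, sd = sd_,
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!identical(stats$name, predictors)) {
      X <- bioclim_matrix(stack, stats$name)
      predictors <- stats$name
    }
  }
  Z <- sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
  list(values = Z, stats = stats, predictors = predictors)
}

#' Hierarchical correlation clustering of candidate predictors
#'
#' Average-linkage hierarchical clustering on the distance 1 - |Pearson r|
#' over land cells, cut at `threshold`. The representative of each cluster is
#' the member with the strongest univariate presence/absence separation
#' (absolute point-biserial correlation); without presence labels, or on
#' ties, the canonical Table-order first member wins.
#'
#' @param stack a [compute_bioclim()] result
#' @param candidates candidate layer names (default: all 17)
#' @param presence optional logical matrix/vector of presence cells used for
#'   representative selection
#' @param threshold dissimilarity cut height (default 0.3)
#' @return list with `clusters` (named integer vector) and `representatives`
#'   (character vector, one per cluster)
#' @export
cluster_predictors <- function(stack, candidates = BIOCLIM_VARS,
                               presence = NULL, threshold = 0.3) {
  if (length(candidates) < 2) stopf("need at least 2 candidate predictors")
  land <- which(as.vector(stack$land_mask))
  if (length(land) < 10) stopf("need at least 10 land cells")
  X <- bioclim_matrix(stack, candidates, cells = land)
  keep <- colSums(is.na(X)) == 0
  if (!all(keep)) X <- X[, keep, drop = FALSE]
  candidates <- colnames(X)
  if (length(candidates) < 2) stopf("fewer than 2 usable candidates")
  r <- stats::cor(X)
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = threshold)
  ord <- match(candidates, BIOCLIM_VARS)
  pb <- rep(0, length(candidates))
  if (!is.null(presence)) {
    y <- as.numeric(as.vector(presence)[land])
    if (stats::sd(y) > 0) {
      pb <- abs(apply(X, 2, function(v) stats::cor(v, y)))
      pb[is.na(pb)] <- 0
    }
  }
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    best <- members[order(-pb[members], ord[members])]
    candidates[best[1]]
  }, character(1))
  list(clusters = cl, representatives = reps)
}

#' Serialize a bioclim stack to one multi-layer raster file
#' @param stack a [compute_bioclim()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bioclim <- function(stack, path) {
  fields <- lapply(stack$layers, function(v) {
    raster_field(stack$grid, unclass(v), units = attr(v, "units") %||% "",
                 mask = stack$land_mask & !is.na(v))
  })
  write_raster(fields, path)
}
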
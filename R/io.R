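#' Write gridded layers to a self-describing text raster file
#'
#' One file holds one grid and any number of named layers. The format is a
#' plain-text key/value header (grid metadata, required: nx, ny, cell_size,
#' origin, lon0/lat0) followed by one block per layer: a `layer <name> <units>`
#' line and `ny` rows of `nx` whitespace-separated values, row iy = 1 first.
#' Masked (sea) cells are written as NA. Round-trips are exact: values are
#' written with full double precision.
#'
#' @param fields a named list of [raster_field()] objects sharing one grid,
#'   or a single `raster_field` (then `name` must be given)
#' @param path output file path
#' @param name layer name when a single field is passed
#' @return `path`, invisibly
#' @export
write_raster <- function(fields, path, name = NULL) {
  if (inherits(fields, "raster_field")) {
    if (is.null(name)) stopf("a single raster_field needs a layer `name`")
    fields <- stats::setNames(list(fields), name)
  }
  if (!length(fields) || is.null(names(fields)) || any(names(fields) == "")) {
    stopf("fields must be a non-empty named list of raster_field objects")
  }
  g <- fields[[1]]$grid
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!inherits(f, "raster_field")) stopf("layer '%s' is not a raster_field", nm)
    if (!identical(unclass(f$grid), unclass(g))) {
      stopf("layer '%s' is on a different grid", nm)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("hepsim_raster 1",
               sprintf("nx %d", g$nx), sprintf("ny %d", g$ny),
               sprintf("cell_size %.17g", g$cell_size),
               sprintf("origin_x %.17g", g$origin_x),
               sprintf("origin_y %.17g", g$origin_y),
               sprintf("lon0 %.17g", g$lon0), sprintf("lat0 %.17g", g$lat0),
               sprintf("nlayers %d", length(fields))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    v <- f$values
    v[!f$mask] <- NA
    writeLines(sprintf("layer %s %s", nm,
                       if (nzchar(f$units)) f$units else "-"), con)
    utils::write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read one layer from a text raster file
#'
#' @param path file written by [write_raster()]
#' @param layer_name name of the layer to extract
#' @param grid optional session [grid_spec()]; if given, the file's grid must
#'   match it exactly (dimension error otherwise)
#' @return a [raster_field()]; cells stored as NA are masked
#' @export
read_raster <- function(path, layer_name, grid = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "hepsim_raster")) {
    stopf("format error: %s is not a hepsim raster file", path)
  }
  meta <- list()
  i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "layer ")) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  need <- c("nx", "ny", "cell_size", "origin_x", "origin_y", "lon0", "lat0")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys)) {
    stopf("format error: missing grid metadata (%s) in %s",
          paste(missing_keys, collapse = ", "), path)
  }
  fg <- grid_spec(nx = as.integer(meta$nx), ny = as.integer(meta$ny),
                  cell_size = as.numeric(meta$cell_size),
                  origin_x = as.numeric(meta$origin_x),
                  origin_y = as.numeric(meta$origin_y),
                  lon0 = as.numeric(meta$lon0), lat0 = as.numeric(meta$lat0))
  if (!is.null(grid) && !identical(unclass(fg), unclass(grid))) {
    stopf("dimension error: grid in %s does not match the session grid", path)
  }
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (hdr[1] != "layer") stopf("format error: expected layer header at line %d", i)
    nm <- hdr[2]
    units <- if (length(hdr) >= 3 && hdr[3] != "-") hdr[3] else ""
    block <- lines[(i + 1):(i + fg$ny)]
    i <- i + fg$ny + 1L
    if (nm == layer_name) {
      rows <- lapply(block, function(l) {
        tok <- strsplit(trimws(l), "\\s+")[[1]]
        tok[tok == "NA"] <- NA_character_
        as.numeric(tok)
      })
      if (any(lengths(rows) != fg$nx)) {
        stopf("dimension error: layer '%s' rows do not have nx=%d values", nm, fg$nx)
      }
      v <- do.call(rbind, rows)
      return(raster_field(fg, v, units = units, mask = !is.na(v)))
    }
  }
  stopf("format error: layer '%s' not found in %s", layer_name, path)
}

#' Static landscape layers sharing one grid
#'
#' @param elevation [raster_field()], metres
#' @param roughness [raster_field()], metres (local elevation variability)
#' @param land_mask logical matrix, TRUE = land
#' @param water_mask logical matrix of inland/any water cells; default = sea
#'   (`!land_mask`)
#' @param forest_mask logical matrix of dense-forest cells; default none
#' @return object of class `landscape_bundle`
#' @export
landscape_bundle <- function(elevation, roughness, land_mask,
                             water_mask = NULL, forest_mask = NULL) {
  g <- elevation$grid
  if (!identical(unclass(roughness$grid), unclass(g))) {
    stopf("dimension error: elevation and roughness are on different grids")
  }
  dims <- c(g$ny, g$nx)
  for (nm in c("land_mask", "water_mask", "forest_mask")) {
    m <- get(nm)
    if (!is.null(m) && !all(dim(m) == dims)) {
      stopf("dimension error: %s shape does not match the grid", nm)
    }
  }
  if (is.null(water_mask)) water_mask <- !land_mask
  if (is.null(forest_mask)) forest_mask <- matrix(FALSE, g$ny, g$nx)
  b <- list(grid = g, elevation = elevation, roughness = roughness,
            land_mask = land_mask, water_mask = water_mask,
            forest_mask = forest_mask)
  class(b) <- "landscape_bundle"
  b
}

#' Read and write archaeological site tables
#'
#' CSV with header columns `site_id, lon, lat, techno_tag, age_ka` (age
#' optional, may be NA).
#'
#' @param path CSV path
#' @return `read_sites`: data.frame of class `site_table`
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lon", "lat", "techno_tag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("format error: site table lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!"age_ka" %in% names(df)) df$age_ka <- NA_real_
  if (anyDuplicated(df$site_id)) stopf("site_id values must be unique")
  class(df) <- c("site_table", "data.frame")
  df
}

#' @rdname read_sites
#' @param sites a site table data.frame
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Construct a site table in code
#' @param site_id unique identifiers
#' @param lon,lat degrees
#' @param techno_tag techno-complex tag (MP, CHAT, AUR-P1, AUR-P2, TEST)
#' @param age_ka optional ages
#' @return data.frame of class `site_table`
#' @export
site_table <- function(site_id, lon, lat, techno_tag = "TEST", age_ka = NA_real_) {
  if (anyDuplicated(site_id)) stopf("site_id values must be unique")
  n <- length(site_id)
  df <- data.frame(site_id = site_id, lon = lon, lat = lat,
                   techno_tag = rep_len(techno_tag, n),
                   age_ka = rep_len(age_ka, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("site_table", "data.frame")
  df
}

#' Aggregate sites to per-cell presence counts (spatial blocking)
#'
#' Multiple sites in one cell count as a single presence record, reducing
#' site-clustering bias. Sites falling on sea cells or outside the grid are
#' reported in `rejects` (with a warning), never silently dropped.
#'
#' @param sites a site table (lon/lat in degrees)
#' @param grid a [grid_spec()]
#' @param land_mask logical (ny, nx) matrix, TRUE = land; if NULL all cells
#'   are treated as land
#' @param rejects_path optional CSV path for a sidecar listing rejected sites
#' @return list with `counts` (integer matrix ny x nx), `presence` (logical
#'   matrix, count >= 1) and `rejects` (data.frame with a `reason` column)
#' @export
sites_to_cells <- function(sites, grid, land_mask = NULL, rejects_path = NULL) {
  km <- lonlat_to_km(grid, sites$lon, sites$lat)
  idx <- cell_index(grid, km$x, km$y)
  reason <- rep(NA_character_, nrow(sites))
  reason[is.na(idx$cell)] <- "outside domain"
  if (!is.null(land_mask)) {
    on_grid <- !is.na(idx$cell)
    sea <- rep(FALSE, nrow(sites))
    sea[on_grid] <- !land_mask[cbind(idx$iy[on_grid], idx$ix[on_grid])]
    reason[sea] <- "sea cell"
  }
  ok <- is.na(reason)
  counts <- matrix(0L, grid$ny, grid$nx)
  if (any(ok)) {
    tab <- table(idx$cell[ok])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  rejects <- cbind(as.data.frame(sites)[!ok, , drop = FALSE],
                   reason = reason[!ok])
  if (nrow(rejects)) {
    warnf("%d site(s) rejected (%s)", nrow(rejects),
          paste(unique(rejects$reason), collapse = "; "))
    if (!is.null(rejects_path)) utils::write.csv(rejects, rejects_path, row.names = FALSE)
  }
  list(counts = counts, presence = counts >= 1L, rejects = rejects)
}
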
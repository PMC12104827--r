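# Geographic range area from habitat-suitability rasters.
#
# Cells with suitability below a threshold are excluded; the remaining
# cells are summed using exact spherical cell areas (so a 1-degree cell
# near a pole contributes far less than one at the equator).

#' Authalic Earth radius in km
#'
#' Radius of the sphere with the same surface area as the WGS84 ellipsoid.
#' @export
earth_radius_km <- function() 6371.0088

#' Construct a longitude/latitude suitability raster
#'
#' @param values numeric matrix of suitability in `[0,1]`; row 1 is the
#'   northernmost row, column 1 the westernmost column (ESRI ASCII grid
#'   layout).  `NA` entries are nodata.
#' @param xll,yll longitude/latitude of the lower-left corner, degrees.
#' @param cellsize cell edge in degrees (square cells).
#' @return object of class `suitability_raster`.
#' @export
suitability_raster <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  lat_top <- yll + nrow(values) * cellsize
  lon_right <- xll + ncol(values) * cellsize
  if (yll < -90 - 1e-9 || lat_top > 90 + 1e-9 ||
      xll < -360 - 1e-9 || lon_right > 360 + 1e-9) {
    stop("raster extent is not geographic (lon/lat degrees); ",
         "projected rasters are not supported", call. = FALSE)
  }
  finite <- values[is.finite(values)]
  if (length(finite) > 0 && (min(finite) < 0 || max(finite) > 1)) {
    stop("suitability values outside [0,1]; declare nodata as NA",
         call. = FALSE)
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize),
            class = "suitability_raster")
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by the
#' grid values, northernmost row first.  Only geographic (lon/lat)
#' rasters are accepted.
#'
#' @param path file path.
#' @return a `suitability_raster`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[a-zA-Z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing_keys <- setdiff(need, names(hdr))
  if (length(missing_keys) > 0) {
    stop("ESRI ASCII header missing: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  suitability_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param raster a `suitability_raster`.
#' @param path output file path.
#' @param nodata_value numeric code written for `NA` cells.
#' @export
write_esri_ascii <- function(raster, path, nodata_value = -9999) {
  stopifnot(inherits(raster, "suitability_raster"))
  m <- raster$values
  m[is.na(m)] <- nodata_value
  hdr <- c(paste("ncols", ncol(m)),
           paste("nrows", nrow(m)),
           paste("xllcorner", format(raster$xll, digits = 12)),
           paste("yllcorner", format(raster$yll, digits = 12)),
           paste("cellsize", format(raster$cellsize, digits = 12)),
           paste("nodata_value", nodata_value))
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Threshold a suitability raster
#'
#' A cell is retained iff its suitability is at least `threshold` (cells
#' with suitability strictly below the threshold are excluded) and it is
#' not nodata.  Nodata means "no information", never zero suitability.
#'
#' @param raster a `suitability_raster`.
#' @param threshold suitability cutoff in `[0,1]` (default 0.2).
#' @return logical matrix of retained cells.
#' @export
mask_suitability <- function(raster, threshold = 0.2) {
  stopifnot(inherits(raster, "suitability_raster"),
            threshold >= 0, threshold <= 1)
  v <- raster$values
  if (all(is.na(v))) warning("raster is entirely nodata; empty mask")
  mask <- !is.na(v) & v >= threshold
  mask
}

#' Spherical area of a longitude/latitude cell
#'
#' Exact area on a sphere of a cell bounded by two parallels and two
#' meridians: `R^2 * dlon * (sin(lat_n) - sin(lat_s))` with `dlon` in
#' radians.
#'
#' @param lat_south,lat_north southern and northern cell edges, degrees,
#'   with `-90 <= lat_south < lat_north <= 90`.
#' @param lon_width cell width in degrees of longitude (> 0; 0 allowed
#'   and gives area 0).
#' @param radius_km sphere radius; authalic Earth radius by default.
#' @return area in km^2.
#' @export
cell_area_km2 <- function(lat_south, lat_north, lon_width,
                          radius_km = earth_radius_km()) {
  if (any(lat_south >= lat_north)) {
    stop("lat_south must be strictly below lat_north", call. = FALSE)
  }
  if (any(lat_south < -90 - 1e-9) || any(lat_north > 90 + 1e-9)) {
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  }
  if (any(lon_width < 0)) stop("lon_width must be nonnegative", call. = FALSE)
  radius_km^2 * (lon_width * pi / 180) *
    (sin(lat_north * pi / 180) - sin(lat_south * pi / 180))
}

#' Range area from a thresholded suitability raster
#'
#' Sums latitude-corrected spherical cell areas over all retained cells.
#'
#' @param raster a `suitability_raster`.
#' @param threshold suitability cutoff (default 0.2).
#' @param radius_km sphere radius in km.
#' @return list with `area_km2`, `n_cells`, `threshold`.
#' @export
range_area <- function(raster, threshold = 0.2,
                       radius_km = earth_radius_km()) {
  mask <- mask_suitability(raster, threshold)
  nr <- nrow(mask)
  cs <- raster$cellsize
  # row i (1 = northernmost) spans latitudes
  lat_n <- raster$yll + (nr - seq_len(nr) + 1) * cs
  row_area <- cell_area_km2(lat_n - cs, lat_n, cs, radius_km)
  counts <- rowSums(mask)
  list(area_km2 = sum(counts * row_area),
       n_cells = as.integer(sum(counts)),
       threshold = threshold)
}

#' Range areas for a set of species rasters
#'
#' @param rasters named list of `suitability_raster` objects (names are
#'   species).
#' @param threshold suitability cutoff.
#' @param radius_km sphere radius in km.
#' @return data frame `species`, `area_km2`, `n_cells`, `threshold`.
#' @export
range_table <- function(rasters, threshold = 0.2,
                        radius_km = earth_radius_km()) {
  stopifnot(is.list(rasters), !is.null(names(rasters)))
  rows <- lapply(names(rasters), function(sp) {
    est <- range_area(rasters[[sp]], threshold, radius_km)
    data.frame(species = sp, area_km2 = est$area_km2,
               n_cells = est$n_cells, threshold = est$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge range estimates for lumped taxa
#'
#' When several named taxa are analysed as one (e.g. a species pair that
#' cannot be separated in the field), the lumped taxon's range area is the
#' arithmetic mean of its members' areas.
#'
#' @param estimates data frame from [range_table()].
#' @param groups named list: `list(lumped_name = c(member, member, ...))`.
#' @return estimates with each group's members replaced by one merged row
#'   (its `n_cells` is the mean member cell count, rounded).
#' @export
merge_taxa <- function(estimates, groups) {
  stopifnot(is.data.frame(estimates))
  if (length(groups) == 0) return(estimates)
  out <- estimates
  for (lumped in names(groups)) {
    members <- groups[[lumped]]
    hit <- out$species %in% members
    if (sum(hit) != length(members)) {
      stop("missing range estimate for group member(s): ",
           paste(setdiff(members, out$species[hit]), collapse = ", "),
           call. = FALSE)
    }
    merged <- data.frame(species = lumped,
                         area_km2 = mean(out$area_km2[hit]),
                         n_cells = as.integer(round(mean(out$n_cells[hit]))),
                         threshold = out$threshold[hit][1],
                         stringsAsFactors = FALSE)
    out <- rbind(out[!hit, , drop = FALSE], merged)
  }
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}
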
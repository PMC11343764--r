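#' Occurrence sets and spatial helpers
#'
#' Occurrence records are plain data frames with columns `species`, `lon`,
#' `lat` (WGS84 decimal degrees).  Grid operations (thinning, area of
#' occupancy) are defined on a world cylindrical equal-area projection
#' (x = R * lon_rad, y = R * sin(lat_rad), R = 6371.0088 km) so that a
#' "1 km cell" is an area statement; the grid is anchored at the
#' projection origin.
#'
#' @param df Data frame with `species`, `lon`, `lat`.
#' @return An `occurrence_set` data frame.
#' @export
occurrence_set <- function(df) {
  stopifnot(all(c("species", "lon", "lat") %in% names(df)))
  if (any(df$lon < -180 | df$lon > 180, na.rm = TRUE) ||
      any(df$lat < -90 | df$lat > 90, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  if (any(is.na(df$lon) | is.na(df$lat))) stop("missing coordinates")
  df$species <- as.character(df$species)
  class(df) <- c("occurrence_set", "data.frame")
  df
}

EARTH_RADIUS_KM <- 6371.0088

cea_project <- function(lon, lat) {
  list(x = EARTH_RADIUS_KM * lon * pi / 180,
       y = EARTH_RADIUS_KM * sin(lat * pi / 180))
}

cell_index <- function(occ, cell_km) {
  if (cell_km <= 0) stop("cell_km must be > 0")
  p <- cea_project(occ$lon, occ$lat)
  paste(floor(p$x / cell_km), floor(p$y / cell_km), sep = ":")
}

#' Remove duplicate and off-mask occurrence records
#'
#' Collapses exact `(species, lon, lat)` duplicates to a single record and
#' drops records falling outside the land-mask polygons.  Every removal is
#' recorded in the provenance log (attribute `"log"`, a data frame with a
#' `reason` column).
#'
#' @param raw An [occurrence_set].
#' @param land_mask Polygon vertices as a 2-column matrix/data frame
#'   (lon, lat), multiple rings separated by `NA` rows, or a list of such
#'   matrices; `NULL` skips the mask filter.
#' @return Cleaned `occurrence_set` with a `"log"` attribute.
#' @export
clean_occurrences <- function(raw, land_mask = NULL) {
  raw <- occurrence_set(as.data.frame(raw))
  log_entries <- list()
  dup <- duplicated(raw[, c("species", "lon", "lat")])
  if (any(dup)) {
    e <- raw[dup, , drop = FALSE]
    e$reason <- "duplicate"
    log_entries$dup <- e
  }
  occ <- raw[!dup, , drop = FALSE]
  if (!is.null(land_mask)) {
    mask <- as_mask_matrix(land_mask)
    inside <- mgcv::in.out(mask, cbind(occ$lon, occ$lat))
    if (!any(inside)) stop("all records removed by the land mask")
    if (any(!inside)) {
      e <- occ[!inside, , drop = FALSE]
      e$reason <- "off-mask"
      log_entries$mask <- e
    }
    occ <- occ[inside, , drop = FALSE]
  }
  if (nrow(occ) == 0L) stop("all records removed")
  rownames(occ) <- NULL
  out <- occurrence_set(occ)
  lg <- if (length(log_entries)) do.call(rbind, log_entries) else
    data.frame(species = character(), lon = numeric(), lat = numeric(),
               reason = character())
  rownames(lg) <- NULL
  attr(out, "log") <- lg
  out
}

as_mask_matrix <- function(land_mask) {
  if (is.list(land_mask) && !is.data.frame(land_mask))
    land_mask <- do.call(rbind, lapply(land_mask, function(m)
      rbind(as.matrix(m), c(NA, NA))))
  m <- as.matrix(land_mask)
  if (ncol(m) != 2 || nrow(m[stats::complete.cases(m), , drop = FALSE]) < 3)
    stop("land mask must contain at least one polygon (>= 3 vertices)")
  m
}

#' Read a land mask from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries (outer rings only), as
#' a `Feature`, `FeatureCollection` or bare geometry.
#'
#' @param path GeoJSON file path.
#' @return `NA`-separated polygon vertex matrix usable as a land mask.
#' @export
read_land_mask <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$features)) g$features$geometry else
    if (!is.null(g$geometry)) g$geometry else g
  rings <- list()
  push <- function(coords) rings[[length(rings) + 1L]] <<- coords
  collect <- function(type, coords) {
    if (identical(type, "Polygon")) {
      push(coords[1, , , drop = TRUE])
    } else if (identical(type, "MultiPolygon")) {
      for (i in seq_len(dim(coords)[1])) push(coords[i, 1, , ])
    } else stop("unsupported geometry type: ", type)
  }
  if (is.data.frame(geom)) {
    for (i in seq_len(nrow(geom)))
      collect(geom$type[i], geom$coordinates[[i]])
  } else collect(geom$type, geom$coordinates)
  as_mask_matrix(rings)
}

#' Spatially thin occurrences to one record per species per grid cell
#'
#' Per species, at most one record is retained per cell of an equal-area
#' grid of side `cell_km`; the retained record is the first under a
#' deterministic `(species, lat, lon)` sort, so thinning is idempotent.
#'
#' @param occ An [occurrence_set] (cleaned).
#' @param cell_km Cell side in km (default 1, i.e. one record per km^2).
#' @return Thinned `occurrence_set`.
#' @export
thin_one_per_cell <- function(occ, cell_km = 1.0) {
  occ <- occurrence_set(as.data.frame(occ))
  ord <- order(occ$species, occ$lat, occ$lon)
  occ <- occ[ord, , drop = FALSE]
  key <- paste(occ$species, cell_index(occ, cell_km))
  out <- occ[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  occurrence_set(out)
}

#' Simple georeferenced raster grid
#'
#' A minimal lon/lat-gridded layer: regularly spaced cells with an origin
#' at the lower-left corner, stored as a matrix indexed `[row = y, col = x]`.
#'
#' @param values Numeric or character matrix (`ny` rows, `nx` cols).
#' @param origin_lon,origin_lat Lower-left corner of the grid.
#' @param dlon,dlat Cell sizes in degrees.
#' @return A `grid_layer`.
#' @export
grid_layer <- function(values, origin_lon, origin_lat, dlon, dlat) {
  stopifnot(is.matrix(values), dlon > 0, dlat > 0)
  structure(list(values = values, origin_lon = origin_lon,
                 origin_lat = origin_lat, dlon = dlon, dlat = dlat),
            class = "grid_layer")
}

layer_extract <- function(layer, lon, lat) {
  col <- floor((lon - layer$origin_lon) / layer$dlon) + 1
  row <- floor((lat - layer$origin_lat) / layer$dlat) + 1
  ok <- col >= 1 & col <= ncol(layer$values) &
    row >= 1 & row <= nrow(layer$values)
  out <- rep(NA, length(lon))
  out[ok] <- layer$values[cbind(row[ok], col[ok])]
  out
}

#' Read/write a gridded-CSV raster layer
#'
#' Plain-text format: `#key=value` header lines (`origin_lon`,
#' `origin_lat`, `dlon`, `dlat`) followed by comma-separated rows of cell
#' values, first row = southernmost.
#'
#' @param path File path.
#' @param layer A [grid_layer] (for writing).
#' @return A `grid_layer` (reading) or `invisible(path)` (writing).
#' @export
read_grid_layer <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  vals <- do.call(rbind, lapply(strsplit(body, ","), function(r) {
    n <- suppressWarnings(as.numeric(r))
    if (anyNA(n) && any(nzchar(trimws(r)))) trimws(r) else n
  }))
  grid_layer(vals, meta$origin_lon, meta$origin_lat, meta$dlon, meta$dlat)
}

#' @rdname read_grid_layer
#' @export
write_grid_layer <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%.10g",
                     c("origin_lon", "origin_lat", "dlon", "dlat"),
                     c(layer$origin_lon, layer$origin_lat,
                       layer$dlon, layer$dlat)), con)
  writeLines(apply(layer$values, 1, paste, collapse = ","), con)
  invisible(path)
}

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tb <- sort(table(x), decreasing = TRUE)
  nm <- names(tb)[tb == max(tb)]
  sort(nm)[1]   # deterministic tie-break by value
}

#' Per-species environmental summaries from raster layers
#'
#' Extracts each layer at every (thinned) occurrence and summarizes per
#' species: median for continuous layers, most common value (mode) for
#' categorical ones.  No-data cells are skipped and counted.
#'
#' @param occ An [occurrence_set] (thinned).
#' @param layers Named list of [grid_layer]s.
#' @param kinds Character vector over `c("continuous","categorical")`,
#'   one per layer (default all continuous).
#' @return Data frame with one row per species, one column per layer, plus
#'   `n_records`; attribute `"n_nodata"` counts skipped extractions.
#' @export
summarize_layers <- function(occ, layers, kinds = NULL) {
  occ <- occurrence_set(as.data.frame(occ))
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  if (is.null(kinds)) kinds <- rep("continuous", length(layers))
  stopifnot(length(kinds) == length(layers),
            all(kinds %in% c("continuous", "categorical")))
  sp <- sort(unique(occ$species))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  nodata <- setNames(numeric(length(layers)), names(layers))
  for (j in seq_along(layers)) {
    vals <- layer_extract(layers[[j]], occ$lon, occ$lat)
    nodata[j] <- sum(is.na(vals))
    agg <- if (kinds[j] == "continuous") {
      v <- suppressWarnings(as.numeric(vals))
      tapply(v, occ$species, function(z)
        if (all(is.na(z))) NA_real_ else median(z, na.rm = TRUE))
    } else {
      tapply(as.character(vals), occ$species, stat_mode)
    }
    out[[names(layers)[j]]] <- unname(agg[sp])
  }
  out$n_records <- as.integer(table(occ$species)[sp])
  attr(out, "n_nodata") <- nodata
  out
}

#' Area of occupancy from occurrence records
#'
#' AOO = (number of occupied `cell_km` x `cell_km` equal-area grid cells)
#' x `cell_km^2`, computed per species on the cleaned (pre-thinning)
#' records.  Grid anchored at the projection origin.
#'
#' @param occ An [occurrence_set] (cleaned, not thinned).
#' @param cell_km Cell side in km (default 0.1).
#' @return Data frame `species`, `aoo_km2`.
#' @export
compute_aoo <- function(occ, cell_km = 0.1) {
  occ <- occurrence_set(as.data.frame(occ))
  cells <- cell_index(occ, cell_km)
  n <- tapply(cells, occ$species, function(z) length(unique(z)))
  data.frame(species = names(n),
             aoo_km2 = as.numeric(n) * cell_km^2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation of log-AOO across two grid cell sizes
#'
#' Cross-check that range-size ranks are insensitive to the AOO cell size:
#' Pearson correlation across species of log AOO at the two sizes.
#'
#' @param occ An [occurrence_set].
#' @param cell_km Two cell sizes (default `c(0.1, 2)`).
#' @return Pearson r (scalar).
#' @export
compare_aoo_cellsizes <- function(occ, cell_km = c(0.1, 2)) {
  stopifnot(length(cell_km) == 2)
  a1 <- compute_aoo(occ, cell_km[1])
  a2 <- compute_aoo(occ, cell_km[2])
  if (nrow(a1) < 3) stop("need at least 3 species")
  m <- merge(a1, a2, by = "species")
  if (sd(m$aoo_km2.x) == 0 || sd(m$aoo_km2.y) == 0)
    stop("zero variance in AOO; correlation undefined")
  cor(log(m$aoo_km2.x), log(m$aoo_km2.y))
}

GROWTH_FORM_0 <- c("globose solitary", "globose caespitose", "barrel")
GROWTH_FORM_1 <- c("arborescent", "shrubby", "columnar", "treelike")
POLLINATION_0 <- c("bee", "mellitophily")
POLLINATION_1 <- c("bird", "ornithophily", "bat", "chiropterophily",
                   "moth", "sphingophily")

parse_size_max <- function(txt) {
  if (is.na(txt)) return(NA_real_)
  if (grepl("barely above ground level", txt, ignore.case = TRUE))
    return(0)
  nums <- regmatches(txt, gregexpr("[0-9]+\\.?[0-9]*", txt))[[1]]
  if (!length(nums)) return(NA_real_)
  max(as.numeric(nums))
}

#' Score raw trait descriptions into analysis variables
#'
#' Applies the scoring rules: plant size = maximum of the reported range
#' (descriptions like "barely above ground level" score 0); growth form
#' binarised 0 = globose solitary / globose caespitose / barrel vs 1 =
#' arborescent / shrubby / columnar; pollination binarised 0 = bee
#' (ancestral) vs 1 = bird / bat / moth (derived); chromosome count =
#' median of the reported counts.  Unknown labels become `NA` and are
#' logged.
#'
#' @param raw Data frame with columns `species` and any of `size`
#'   (text range), `growth_form`, `pollination`, `epiphyte`,
#'   `chromosomes` (text list of counts).
#' @return Data frame of scored traits with a `"log"` attribute listing
#'   unrecognised labels.
#' @export
score_traits <- function(raw) {
  stopifnot("species" %in% names(raw))
  dup <- unique(raw$species[duplicated(raw$species)])
  if (length(dup)) {
    conflicting <- vapply(dup, function(s) {
      rows <- raw[raw$species == s, setdiff(names(raw), "species"),
                  drop = FALSE]
      nrow(unique(rows)) > 1
    }, TRUE)
    if (any(conflicting))
      stop("contradictory duplicate rows for: ",
           paste(dup[conflicting], collapse = ", "))
    raw <- raw[!duplicated(raw$species), , drop = FALSE]
  }
  out <- data.frame(species = as.character(raw$species),
                    stringsAsFactors = FALSE)
  log <- list()
  if ("size" %in% names(raw))
    out$size_cm <- vapply(as.character(raw$size), parse_size_max,
                          numeric(1), USE.NAMES = FALSE)
  if ("growth_form" %in% names(raw)) {
    gf <- tolower(trimws(as.character(raw$growth_form)))
    out$growth_form_bin <- ifelse(gf %in% GROWTH_FORM_0, 0L,
                                  ifelse(gf %in% GROWTH_FORM_1, 1L,
                                         NA_integer_))
    bad <- !is.na(gf) & is.na(out$growth_form_bin)
    if (any(bad))
      log$growth_form <- data.frame(species = out$species[bad],
                                    field = "growth_form",
                                    value = gf[bad])
  }
  if ("pollination" %in% names(raw)) {
    po <- tolower(trimws(as.character(raw$pollination)))
    out$pollination_bin <- ifelse(po %in% POLLINATION_0, 0L,
                                  ifelse(po %in% POLLINATION_1, 1L,
                                         NA_integer_))
    bad <- !is.na(po) & is.na(out$pollination_bin)
    if (any(bad))
      log$pollination <- data.frame(species = out$species[bad],
                                    field = "pollination", value = po[bad])
  }
  if ("epiphyte" %in% names(raw))
    out$epiphyte <- as.integer(as.logical(raw$epiphyte))
  if ("chromosomes" %in% names(raw))
    out$chromosome_n <- vapply(as.character(raw$chromosomes), function(txt) {
      if (is.na(txt)) return(NA_real_)
      nums <- as.numeric(regmatches(txt, gregexpr("[0-9]+", txt))[[1]])
      if (!length(nums)) NA_real_ else median(nums)
    }, numeric(1), USE.NAMES = FALSE)
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else NULL
  out
}
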
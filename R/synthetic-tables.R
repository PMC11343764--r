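#' Specification for a synthetic species-by-variable trait table
#'
#' Emulates the structure of a mixed-type macroevolutionary predictor
#' table: correlated continuous nuisance variables, thresholded binary
#' variables, quantile-binned categorical variables, missing entries
#' inserted completely at random, and a positive per-species speciation
#' rate driven by zero or more planted variables.
#'
#' @param n_species Number of species rows (default 850).
#' @param n_vars Number of predictor variables (default 39).
#' @param planted Named list mapping a variable name (`"V3"`) to a
#'   [speciation_fn] describing its contribution to the rate.
#' @param interaction Optional `list(vars = c("Va","Vb"), effect = e)`
#'   adding `e * x_a * x_b` to the rate signal.
#' @param cor Correlation matrix for the latent normals (default
#'   identity); must be positive semi-definite.
#' @param missing_frac Fraction of predictor cells set missing, MCAR
#'   (default 0.2159; the response is never missing).
#' @param type_map Character vector of length `n_vars` over
#'   `c("continuous","binary","categorical")`; default 33 continuous,
#'   4 binary, 2 categorical.
#' @param binary_prev Prevalence used to threshold binary variables.
#' @param n_levels Number of levels for categorical variables.
#' @param noise_sd Standard deviation of the multiplicative lognormal
#'   noise on the rate.
#' @param baseline Rate used when no variables are planted.
#' @return A `table_spec` object.
#' @export
table_spec <- function(n_species = 850L, n_vars = 39L, planted = list(),
                       interaction = NULL, cor = NULL,
                       missing_frac = 0.2159, type_map = NULL,
                       binary_prev = 0.5, n_levels = 7L,
                       noise_sd = 0.3, baseline = 0.2) {
  stopifnot(n_species >= 2, n_vars >= 1,
            missing_frac >= 0, missing_frac < 1, noise_sd >= 0,
            baseline > 0)
  vars <- paste0("V", seq_len(n_vars))
  if (is.null(type_map)) {
    type_map <- rep("continuous", n_vars)
    if (n_vars >= 10) {
      type_map[seq_len(4) + n_vars - 6] <- "binary"
      type_map[c(n_vars - 1, n_vars)] <- "categorical"
    }
  }
  stopifnot(length(type_map) == n_vars,
            all(type_map %in% c("continuous", "binary", "categorical")))
  names(type_map) <- vars
  if (length(planted)) {
    if (!all(names(planted) %in% vars))
      stop("planted variables not in the variable set: ",
           paste(setdiff(names(planted), vars), collapse = ", "))
    stopifnot(all(vapply(planted, inherits, TRUE, "speciation_fn")))
  }
  if (!is.null(interaction))
    stopifnot(all(interaction$vars %in% vars), is.numeric(interaction$effect))
  if (!is.null(cor)) {
    stopifnot(nrow(cor) == n_vars, ncol(cor) == n_vars)
    ev <- eigen(cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", signif(min(ev), 4), ")")
  }
  structure(list(n_species = as.integer(n_species),
                 n_vars = as.integer(n_vars), vars = vars,
                 planted = planted, interaction = interaction, cor = cor,
                 missing_frac = missing_frac, type_map = type_map,
                 binary_prev = binary_prev, n_levels = as.integer(n_levels),
                 noise_sd = noise_sd, baseline = baseline),
            class = "table_spec")
}

#' Generate a synthetic trait table with planted rate drivers
#'
#' Draws the latent variables, applies the type map, computes the
#' per-species rate signal as the sum of the planted speciation-function
#' responses (plus any interaction term), multiplies by mean-one lognormal
#' noise, and inserts MCAR missingness into the predictors.
#'
#' @param spec A [table_spec].
#' @param seed Integer seed.
#' @return List with `table` (data frame `species` + predictors), `rates`
#'   (a [tip_rates] with `source = "synthetic"`), `signal` (the noiseless
#'   rates) and `seed`.
#' @export
generate_predictor_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "table_spec"))
  set.seed(seed)
  n <- spec$n_species
  p <- spec$n_vars
  z <- matrix(rnorm(n * p), n, p)
  if (!is.null(spec$cor)) {
    ev <- eigen(spec$cor, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    z <- z %*% rt
  }
  colnames(z) <- spec$vars

  # rate signal uses the latent (pre-typing, pre-missingness) values
  signal <- rep(0, n)
  if (length(spec$planted)) {
    for (v in names(spec$planted))
      signal <- signal + eval_speciation(spec$planted[[v]], z[, v])
  } else {
    signal <- rep(spec$baseline, n)
  }
  if (!is.null(spec$interaction)) {
    va <- spec$interaction$vars[1]; vb <- spec$interaction$vars[2]
    signal <- signal + spec$interaction$effect * z[, va] * z[, vb]
  }
  signal <- pmax(signal, 1e-4)
  noise <- if (spec$noise_sd > 0)
    rlnorm(n, -spec$noise_sd^2 / 2, spec$noise_sd) else rep(1, n)
  rate <- signal * noise

  tab <- data.frame(species = sprintf("sp%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in spec$vars) {
    col <- switch(spec$type_map[[v]],
      continuous  = z[, v],
      binary      = as.integer(z[, v] > qnorm(1 - spec$binary_prev)),
      categorical = {
        br <- quantile(z[, v], probs = seq(0, 1, length.out =
                                             spec$n_levels + 1))
        br[1] <- -Inf; br[length(br)] <- Inf
        as.character(cut(z[, v], br, labels = LETTERS[seq_len(spec$n_levels)]))
      })
    tab[[v]] <- col
  }
  if (spec$missing_frac > 0) {
    for (v in spec$vars) {
      miss <- runif(n) < spec$missing_frac
      tab[[v]][miss] <- NA
    }
  }
  list(table = tab,
       rates = tip_rates(tab$species, rate, source = "synthetic"),
       signal = signal, seed = as.integer(seed))
}

#' Generate clustered synthetic occurrence records
#'
#' Per species, cluster centres are drawn uniformly over a bounding box
#' and points scattered around each centre with an isotropic spread given
#' in km.  Optional fractions of exact-duplicate records and of points at
#' a fixed off-mask location are appended for testing cleaning filters.
#'
#' @param n_species Number of species.
#' @param clusters_per_species Cluster centres per species.
#' @param spread_km Point scatter (km) around each centre; 0 collapses a
#'   cluster onto its centre.
#' @param points_per_cluster Points per cluster.
#' @param seed Integer seed.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in decimal degrees.
#' @param duplicate_frac Fraction of rows to duplicate exactly.
#' @param offmask_frac Fraction of rows replaced by `offmask_point`.
#' @param offmask_point Longitude/latitude of the planted off-mask point.
#' @return Data frame `species, lon, lat` (an `occurrence_set`).
#' @export
generate_occurrences <- function(n_species, clusters_per_species = 3L,
                                 spread_km = 20, points_per_cluster = 5L,
                                 seed = 1L,
                                 bbox = c(-115, -40, -35, 30),
                                 duplicate_frac = 0, offmask_frac = 0,
                                 offmask_point = c(0, 0)) {
  stopifnot(n_species >= 1, clusters_per_species >= 1,
            points_per_cluster >= 1, spread_km >= 0)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("empty bounding box")
  set.seed(seed)
  rows <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    cl_lon <- runif(clusters_per_species, bbox[1], bbox[2])
    cl_lat <- runif(clusters_per_species, bbox[3], bbox[4])
    lon <- rep(cl_lon, each = points_per_cluster)
    lat <- rep(cl_lat, each = points_per_cluster)
    if (spread_km > 0) {
      npt <- length(lon)
      dlat <- rnorm(npt, 0, spread_km) / 111.32
      dlon <- rnorm(npt, 0, spread_km) / (111.32 * pmax(cos(lat * pi / 180),
                                                        0.05))
      lon <- lon + dlon
      lat <- pmin(pmax(lat + dlat, -89.9), 89.9)
    }
    rows[[s]] <- data.frame(species = sprintf("sp%04d", s),
                            lon = lon, lat = lat,
                            stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, rows)
  n <- nrow(occ)
  if (offmask_frac > 0) {
    k <- round(offmask_frac * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      occ$lon[idx] <- offmask_point[1]
      occ$lat[idx] <- offmask_point[2]
    }
  }
  if (duplicate_frac > 0) {
    k <- round(duplicate_frac * n)
    if (k > 0) occ <- rbind(occ, occ[sample.int(n, k), ])
  }
  rownames(occ) <- NULL
  occurrence_set(occ)
}
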
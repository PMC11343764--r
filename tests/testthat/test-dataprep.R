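square_mask <- function(lon0, lon1, lat0, lat1)
  matrix(c(lon0, lat0, lon1, lat0, lon1, lat1, lon0, lat1),
         ncol = 2, byrow = TRUE)

test_that("cleaning removes duplicates and off-mask points, with provenance", {
  occ <- occurrence_set(data.frame(
    species = c("a", "a", "a", "b"),
    lon = c(-70, -70, 0, -70),
    lat = c(-10, -10, 0, -10)))
  mask <- square_mask(-80, -60, -20, 0)
  out <- clean_occurrences(occ, mask)
  expect_equal(nrow(out), 2L)
  lg <- attr(out, "log")
  expect_equal(nrow(lg), 2L)
  expect_setequal(lg$reason, c("duplicate", "off-mask"))
  # every dropped record appears exactly once in the log
  expect_equal(nrow(occ), nrow(out) + nrow(lg))

  # idempotence on an already-clean set
  again <- clean_occurrences(out, mask)
  expect_equal(as.data.frame(again), as.data.frame(out),
               ignore_attr = TRUE)
  expect_equal(nrow(attr(again, "log")), 0L)

  expect_error(clean_occurrences(occ, matrix(numeric(), ncol = 2)), "mask")
  expect_error(clean_occurrences(occurrence_set(
    data.frame(species = "a", lon = 0, lat = 0)), mask), "all records")
})

test_that("thinning keeps one record per species per equal-area cell", {
  base <- data.frame(species = "a", lon = -70, lat = -10)
  near <- data.frame(species = "a", lon = -70 + 0.0009, lat = -10) # ~100 m
  far <- data.frame(species = "a", lon = -70 + 0.02, lat = -10)    # ~2 km
  other <- data.frame(species = "b", lon = -70, lat = -10)

  expect_equal(nrow(thin_one_per_cell(occurrence_set(rbind(base, near)))), 1L)
  expect_equal(nrow(thin_one_per_cell(occurrence_set(rbind(base, far)))), 2L)
  # thinning is per species: two species at one point both survive
  expect_equal(nrow(thin_one_per_cell(occurrence_set(rbind(base, other)))), 2L)

  occ <- generate_occurrences(20, clusters_per_species = 2, spread_km = 3,
                              points_per_cluster = 10, seed = 5)
  t1 <- thin_one_per_cell(occ, 1)
  expect_lte(nrow(t1), nrow(occ))
  # fixed point
  expect_equal(as.data.frame(thin_one_per_cell(t1, 1)), as.data.frame(t1))
  expect_error(thin_one_per_cell(occ, 0), "cell_km")
})

test_that("layer summaries take medians and modes, skipping no-data", {
  # 4 x 4 one-degree grid over lon [0,4], lat [0,4], values 1..16 row-wise
  vals <- matrix(1:16, 4, 4, byrow = TRUE)
  lay <- grid_layer(vals, 0, 0, 1, 1)
  # five placed points: rows 1,1,2,3 cols 1,2,3,4 -> values 1,2,7,12, one off-grid
  occ <- occurrence_set(data.frame(
    species = "a",
    lon = c(0.5, 1.5, 2.5, 3.5, 10),
    lat = c(0.5, 0.5, 1.5, 2.5, 10)))
  s <- summarize_layers(occ, list(v = lay))
  expect_equal(s$v, median(c(1, 2, 7, 12)))
  expect_equal(unname(attr(s, "n_nodata")["v"]), 1)

  cst <- grid_layer(matrix(7, 4, 4), 0, 0, 1, 1)
  s2 <- summarize_layers(occ, list(v = cst))
  expect_equal(s2$v, 7)

  cat_lay <- grid_layer(matrix(c("x", "x", "y", "y"), 2, 2), 0, 0, 2, 2)
  s3 <- summarize_layers(occ, list(b = cat_lay), kinds = "categorical")
  expect_equal(s3$b, "x")
})

test_that("grid layers round-trip through the gridded-CSV format", {
  lay <- grid_layer(matrix(rnorm(12), 3, 4), -80.5, -30.25, 0.5, 0.25)
  f <- tempfile(fileext = ".csv")
  write_grid_layer(lay, f)
  back <- read_grid_layer(f)
  expect_equal(back$values, lay$values, tolerance = 1e-9)
  expect_equal(back$origin_lon, -80.5)
  expect_equal(back$dlat, 0.25)
})

test_that("AOO counts occupied cells times cell area", {
  one <- occurrence_set(data.frame(species = "a", lon = -70, lat = -10))
  expect_equal(compute_aoo(one, 0.1)$aoo_km2, 0.01)

  # four records far enough apart to occupy four 0.1 km cells
  four <- occurrence_set(data.frame(
    species = "a", lon = -70 + c(0, 0.002, 0.004, 0.006), lat = -10))
  expect_equal(compute_aoo(four, 0.1)$aoo_km2, 0.04)
  # at 2 km they all land in one cell of area 4
  expect_equal(compute_aoo(four, 2)$aoo_km2, 4)

  # occupied-cell count is monotone non-increasing in cell size
  occ <- generate_occurrences(30, clusters_per_species = 2, spread_km = 5,
                              points_per_cluster = 8, seed = 8)
  n01 <- compute_aoo(occ, 0.1)$aoo_km2 / 0.01
  n2 <- compute_aoo(occ, 2)$aoo_km2 / 4
  expect_true(all(n2 <= n01))
  # AOO monotone in record count
  sub <- occurrence_set(occ[seq_len(nrow(occ) / 2), ])
  a_all <- compute_aoo(occ, 0.1)
  a_sub <- compute_aoo(sub, 0.1)
  m <- merge(a_all, a_sub, by = "species")
  expect_true(all(m$aoo_km2.x >= m$aoo_km2.y))
})

test_that("log-AOO at 0.1 km and 2 km cells correlates strongly", {
  # heterogeneous range sizes: batches differing in cluster count, spread
  # and sampling intensity, relabelled to 100 distinct species
  batches <- list(
    generate_occurrences(40, clusters_per_species = 1, spread_km = 1,
                         points_per_cluster = 3, seed = 12),
    generate_occurrences(30, clusters_per_species = 3, spread_km = 10,
                         points_per_cluster = 6, seed = 13),
    generate_occurrences(30, clusters_per_species = 6, spread_km = 40,
                         points_per_cluster = 12, seed = 14))
  for (i in 2:3)
    batches[[i]]$species <- sprintf("b%d_%s", i, batches[[i]]$species)
  occ <- occurrence_set(do.call(rbind, batches))
  expect_gt(compare_aoo_cellsizes(occ), 0.9)

  single <- occurrence_set(data.frame(
    species = c("a", "b", "c"), lon = c(-70, -71, -72), lat = -10))
  expect_error(compare_aoo_cellsizes(single), "zero variance")
})

test_that("trait scoring follows the maximum-size and binarisation rules", {
  raw <- data.frame(
    species = c("s1", "s2", "s3", "s4"),
    size = c("30-45.74 cm", "barely above ground level", "12 cm", NA),
    growth_form = c("columnar", "globose solitary", "Barrel", "weird"),
    pollination = c("bee", "bat", "sphingophily", "unknown"),
    chromosomes = c("22", "22;44", NA, "11;22;33"))
  sc <- score_traits(raw)
  expect_equal(sc$size_cm, c(45.74, 0, 12, NA))
  expect_equal(sc$growth_form_bin, c(1L, 0L, 0L, NA))
  expect_equal(sc$pollination_bin, c(0L, 1L, 1L, NA))
  expect_equal(sc$chromosome_n, c(22, 33, NA, 22))
  lg <- attr(sc, "log")
  expect_true("weird" %in% lg$value && "unknown" %in% lg$value)

  dup <- rbind(raw, within(raw[1, ], size <- "99 cm"))
  expect_error(score_traits(dup), "s1")
  # an exact duplicate row is tolerated
  expect_silent(score_traits(rbind(raw, raw[2, ])))
})

test_that("GeoJSON masks load as polygon rings", {
  f <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(-80, -20), c(-60, -20),
                                            c(-60, 0), c(-80, 0),
                                            c(-80, -20)))),
    properties = NULL), auto_unbox = TRUE), f)
  m <- read_land_mask(f)
  expect_true(is.matrix(m))
  inside <- mgcv::in.out(m, cbind(-70, -10))
  outside <- mgcv::in.out(m, cbind(0, 0))
  expect_true(inside)
  expect_false(outside)
})
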
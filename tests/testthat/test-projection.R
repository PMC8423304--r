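test_that("binarize applies the >= convention and rejects bad thresholds", {
  g <- toy_grid(2, 2)
  m <- suitability_map(matrix(c(0.3, 0.5, 0.7, NA), 2, 2), g)
  b <- binarize(m, 0.5)
  expect_equal(b$values, matrix(c(0, 1, 1, NA), 2, 2))
  expect_true(all(binarize(m, 0)$values[!is.na(m$values)] == 1))
  expect_error(binarize(m, 1 + 1e-9), "threshold")
  expect_error(binarize(m, -0.1), "threshold")
})

test_that("consensus takes the majority of qualifying maps, ties to presence", {
  g <- toy_grid(1, 1)
  mk <- function(v) binary_map(matrix(v, 1, 1), g)
  expect_equal(consensus(list(mk(1), mk(1), mk(0)), c(1, 1, 1))$consensus$values[1], 1)
  expect_equal(consensus(list(mk(1), mk(0)), c(1, 1))$consensus$values[1], 1)
  expect_equal(consensus(list(mk(0), mk(0), mk(1)), c(1, 1, 1))$consensus$values[1], 0)
  # non-qualifying maps are excluded from the frequency
  cns <- consensus(list(mk(1), mk(1), mk(0)), c(1, 0, 1))
  expect_equal(cns$frequency[1], 0.5)
  expect_equal(cns$n_contributing, 2)
  # a single qualifying map is returned unchanged
  one <- consensus(list(mk(1), mk(0)), c(0, 1))
  expect_equal(one$consensus$values[1], 0)
  expect_error(consensus(list(mk(1)), 0), "no valid replicates")
})

test_that("suitable areas follow the spherical band closed form", {
  # single 5-arc-minute cell on the equator
  g1 <- niche_grid(xmin = 0, ymax = 1 / 24, cellsize = 1 / 12,
                   nrow = 1, ncol = 1)
  a1 <- suitable_area_km2(binary_map(matrix(1, 1, 1), g1))
  expect_equal(a1, 85.86, tolerance = 0.01 / 85.86)
  expect_equal(suitable_area_km2(binary_map(matrix(0, 1, 1), g1)), 0)
  # a one-degree-square patch from the equator: cell sum matches the
  # closed-form band integral 2*pi*R^2*sin(1 deg)/360
  g2 <- niche_grid(xmin = 0, ymax = 1, cellsize = 1 / 12,
                   nrow = 12, ncol = 12)
  a2 <- suitable_area_km2(binary_map(matrix(1, 12, 12), g2))
  band <- 2 * pi * 6371^2 * sin(pi / 180) / 360
  expect_equal(a2, band, tolerance = 1e-3)
  expect_equal(a2, 12364, tolerance = 1e-4)
})

test_that("change stats report loss, gain and cellwise stability", {
  g <- toy_grid(1, 2)
  a <- cell_area_by_row(g)[1]
  cur <- binary_map(matrix(c(1, 1), 1, 2), g, scenario = "current")
  fut <- binary_map(matrix(c(1, 0), 1, 2), g, scenario = "future")
  cs <- change_stats(cur, list(future = fut))
  expect_s3_class(cs, "scenario_comparison")
  expect_equal(cs$loss_pct[2], 50)
  expect_equal(cs$stable_km2[2], a, tolerance = 1e-9)
  expect_equal(cs$lost_km2[2], a, tolerance = 1e-9)
  # identical maps: zero loss, everything stable
  cs2 <- change_stats(cur, list(same = cur))
  expect_equal(cs2$loss_pct[2], 0)
  expect_equal(cs2$stable_km2[2], cs2$area_km2[1])
  # disjoint equal areas: zero net loss but no stability
  d1 <- binary_map(matrix(c(1, 0), 1, 2), g)
  d2 <- binary_map(matrix(c(0, 1), 1, 2), g)
  cs3 <- change_stats(d1, list(flip = d2))
  expect_equal(cs3$loss_pct[2], 0)
  expect_equal(cs3$gain_pct[2], 0)
  expect_equal(cs3$stable_km2[2], 0)
  expect_equal(cs3$lost_km2[2], a, tolerance = 1e-9)
  expect_equal(cs3$gained_km2[2], a, tolerance = 1e-9)
})

test_that("polygon overlap counts present cells by centre inclusion", {
  g <- toy_grid(1, 4, cellsize = 1 / 12, xmin = 0)  # centres at lon 1/24 + k/12
  bm <- binary_map(matrix(1, 1, 4), g)
  total <- suitable_area_km2(bm)
  rect <- function(x0, x1, y0, y1, name)
    list(name = name,
         rings = list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))))
  whole <- polygon_set(list(rect(-1, 1, -1, 1, "all")))
  none <- polygon_set(list(rect(2, 3, -1, 1, "none")))
  half <- polygon_set(list(rect(0, 2 / 12, -1, 1, "west_half")))
  o_all <- overlap_with_polygons(bm, whole)
  expect_equal(o_all$overlap_km2, total, tolerance = 1e-9)
  expect_equal(o_all$overlap_pct, 100)
  expect_equal(attr(o_all, "union_pct"), 100)
  expect_equal(overlap_with_polygons(bm, none)$overlap_km2, 0)
  o_half <- overlap_with_polygons(bm, half)
  expect_equal(o_half$overlap_km2, total / 2, tolerance = 1e-9)
  # additivity over disjoint polygons, never exceeding the total
  both <- polygon_set(list(rect(0, 2 / 12, -1, 1, "west"),
                           rect(2 / 12, 1, -1, 1, "east")))
  o2 <- overlap_with_polygons(bm, both)
  expect_equal(sum(o2$overlap_km2), total, tolerance = 1e-9)
  expect_true(all(o2$overlap_km2 <= total))
})

test_that("geojson polygons round-trip with holes honoured", {
  dir <- withr::local_tempdir()
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "donut"),
    geometry = list(type = "Polygon", coordinates = list(
      list(list(0, 0), list(4, 0), list(4, 4), list(0, 4), list(0, 0)),
      list(list(1, 1), list(3, 1), list(3, 3), list(1, 3), list(1, 1)))))))
  path <- file.path(dir, "poly.geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  ps <- read_geojson(path)
  expect_equal(ps$polygons[[1]]$name, "donut")
  inside <- points_in_polygon(c(0.5, 2, 5), c(0.5, 2, 5),
                              ps$polygons[[1]]$rings)
  expect_equal(inside, c(TRUE, FALSE, FALSE))  # the hole excludes (2, 2)
})
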
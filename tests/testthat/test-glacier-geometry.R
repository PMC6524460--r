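test_that("mean boundary offset handles identity, uniform shift and noise", {
  b0 <- flat_boundary(1939, 100)
  expect_identical(mean_boundary_offset(b0, b0), 0)

  b1 <- flat_boundary(1995, 110, scale = 0.5)
  b0h <- flat_boundary(1939, 100, scale = 0.5)
  expect_equal(mean_boundary_offset(b0h, b1), 5.0)

  # sinuous boundaries with a known 42 px mean shift at 1.2 m/px
  set.seed(42)
  x <- seq(0, 500, length.out = 120)
  w1 <- 5 * sin(x / 30) + rnorm(120)
  w2 <- 4 * cos(x / 55) + rnorm(120)
  y1 <- 100 + w1
  y2 <- 100 + 42 + w2
  expected <- (mean(y2) - mean(y1)) * 1.2  # brute-force oracle
  got <- mean_boundary_offset(glacier_boundary(1939, cbind(x, y1), 1.2),
                              glacier_boundary(2015, cbind(x, y2), 1.2))
  expect_equal(got, expected)
  expect_equal(got, 42 * 1.2, tolerance = 0.02)
})

test_that("offset is antisymmetric and rejects bad input", {
  b0 <- flat_boundary(1939, 100)
  b1 <- flat_boundary(1995, 137)
  expect_equal(mean_boundary_offset(b0, b1), -mean_boundary_offset(b1, b0))
  b2 <- flat_boundary(1995, 137, scale = 2)
  expect_error(mean_boundary_offset(b0, b2), "pixel_scale")
  expect_error(glacier_boundary(1939, cbind(1, 1), 1), "at least 2")
})

test_that("retreat rate matches the historical epoch arithmetic", {
  # 64.96 m over 56 years -> 1.16 m/a
  b0 <- flat_boundary(1939, 100)
  b1 <- flat_boundary(1995, 164.96)
  rr <- retreat_rate(b0, b1)
  expect_equal(rr$rate_m_per_a, 1.16)
  expect_equal(rr$mean_offset_m, 64.96)
  expect_equal(retreat_rate(b0, flat_boundary(1995, 100))$rate_m_per_a, 0)
  expect_error(retreat_rate(b1, b0), "postdate")
  # simulator ground truth round trip
  gb <- gen_boundaries(3, years = c(2000, 2010), rates_m_per_a = 3.0)
  expect_equal(retreat_rate(gb$boundaries[[1]],
                            gb$boundaries[[2]])$rate_m_per_a, 3.0)
})

test_that("polyline length: exact cases and quadrature oracle", {
  expect_equal(polyline_length(glacier_boundary(1, rbind(c(0, 0), c(3, 4)),
                                                1)), 5)
  sq <- glacier_boundary(1, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), 1)
  expect_equal(polyline_length(sq), 30)

  # dense sinusoid vs numerical quadrature of the arclength integrand
  x <- seq(0, 100, length.out = 4000)
  y <- 10 * sin(x / 7)
  oracle <- pracma::integral(function(t) sqrt(1 + (10 / 7 * cos(t / 7))^2),
                             0, 100)
  got <- polyline_length(glacier_boundary(1, cbind(x, y), 1))
  expect_lt(abs(got - oracle) / oracle, 1e-3)

  # rigid rotation invariance and linear scaling in pixel_scale
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- cbind(x[1:50], y[1:50])
  expect_equal(polyline_length(glacier_boundary(1, pts %*% R, 1)),
               polyline_length(glacier_boundary(1, pts, 1)))
  expect_equal(polyline_length(glacier_boundary(1, pts, 2.5)),
               2.5 * polyline_length(glacier_boundary(1, pts, 1)))
})

test_that("swept region area agrees with the shoelace oracle", {
  b0 <- flat_boundary(1939, 100)
  expect_equal(swept_region(b0, b0)$area_m2, 0)

  b1 <- flat_boundary(1995, 110)  # 10 m apart, 100 m long
  expect_equal(swept_region(b0, b1, "polyline")$area_m2, 1000)
  expect_equal(swept_region(b0, b1, "chord")$area_m2, 1000)

  set.seed(9)
  x <- seq(0, 200, length.out = 60)
  y1 <- 50 + 6 * sin(x / 12) + rnorm(60)
  y2 <- 90 + 5 * cos(x / 17) + rnorm(60)
  sr <- swept_region(glacier_boundary(1939, cbind(x, y1), 1),
                     glacier_boundary(2015, cbind(x, y2), 1))
  poly <- rbind(cbind(x, y1), cbind(rev(x), rev(y2)))
  expect_equal(sr$area_m2, abs(pracma::polyarea(poly[, 1], poly[, 2])))

  # crossing boundaries must be rejected
  yc <- seq(40, 120, length.out = 60)  # crosses y1
  expect_error(swept_region(glacier_boundary(1939, cbind(x, y1), 1),
                            glacier_boundary(2015, cbind(x, yc), 1)),
               "self-intersecting")
})

test_that("melt volume: uniform, zero, additive and monotone", {
  grid <- bathymetry_grid(matrix(10, 40, 120), origin = c(0, 0),
                          cell_size = 1)
  rect <- rbind(c(0, 0), c(100, 0), c(100, 10), c(0, 10))
  expect_equal(melt_volume(rect, grid), 10000)
  grid0 <- bathymetry_grid(matrix(0, 40, 120), cell_size = 1)
  expect_equal(melt_volume(rect, grid0), 0)
  expect_equal(melt_volume(rect[1:2, ], grid), 0)  # degenerate region
  far <- rbind(c(500, 500), c(600, 500), c(600, 600), c(500, 600))
  expect_error(melt_volume(far, grid), "outside")

  # additivity over disjoint halves
  left <- rbind(c(0, 0), c(50, 0), c(50, 10), c(0, 10))
  right <- rbind(c(50, 0), c(100, 0), c(100, 10), c(50, 10))
  expect_equal(melt_volume(left, grid) + melt_volume(right, grid),
               melt_volume(rect, grid))
  # monotone in depth
  grid2 <- bathymetry_grid(matrix(25, 40, 120), cell_size = 1)
  expect_gt(melt_volume(rect, grid2), melt_volume(rect, grid))
})

test_that("paraboloid basin volume converges to the closed form", {
  R <- 500; dmax <- 169
  analytic_disk <- function(r) dmax * pi * r^2 * (1 - r^2 / (2 * R^2))
  theta <- seq(0, 2 * pi, length.out = 360)
  disk <- cbind(R + 450 * cos(theta), R + 450 * sin(theta))
  errs <- vapply(c(20, 10, 5), function(cs) {
    grid <- gen_bathymetry("paraboloid", depth_m = dmax, extent_m = R,
                           cell_size = cs)$grid
    abs(melt_volume(disk, grid) - analytic_disk(450)) / analytic_disk(450)
  }, numeric(1))
  expect_lt(errs[3], 0.01)            # fine grid within 1 %
  expect_lt(errs[3], errs[1])         # error decreases with refinement
})

test_that("scenario bracketing: chord vs polyline and the mean contract", {
  # straight boundaries: both scenarios coincide
  b0 <- flat_boundary(1939, 100)
  b1 <- flat_boundary(2015, 150)
  grid <- bathymetry_grid(matrix(20, 100, 120), cell_size = 1)
  est <- melt_volume_scenarios(b0, b1, grid)
  expect_equal(est$half_range_m3, 0)
  expect_equal(est$mean_m3, est$v_chord_m3)

  # sinuous boundary over uniform depth: mean = depth x mean area
  x <- seq(0, 100, length.out = 50)
  bs0 <- glacier_boundary(1939, cbind(x, 20 + 5 * sin(x / 9)), 1)
  bs1 <- glacier_boundary(2015, cbind(x, 70 + 4 * cos(x / 13)), 1)
  a_chord <- swept_region(bs0, bs1, "chord")$area_m2
  a_poly <- swept_region(bs0, bs1, "polyline")$area_m2
  est2 <- melt_volume_scenarios(bs0, bs1, grid, exact = TRUE, subdiv = 8)
  expect_equal(est2$mean_m3, 20 * (a_chord + a_poly) / 2, tolerance = 0.01)

  # arithmetic contract on the reported mean +/- half-range form
  v <- list(v_chord_m3 = 5.76e7, v_polyline_m3 = 9.90e7)
  expect_equal((v$v_chord_m3 + v$v_polyline_m3) / 2, 7.83e7)
  expect_equal(abs(v$v_chord_m3 - v$v_polyline_m3) / 2, 2.07e7)
})

test_that("ESRI ASCII grids round-trip", {
  g <- gen_bathymetry("paraboloid", depth_m = 42, extent_m = 80,
                      cell_size = 10)$grid
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  g2 <- read_esri_ascii(f)
  expect_equal(g2$depths, g$depths, tolerance = 1e-6)
  expect_equal(g2$cell_size, g$cell_size)
  expect_equal(g2$origin, g$origin)
})
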
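test_that("stenosis ratio follows the area definition", {
  expect_equal(compute_stenosis_ratio(7, 3), 70)
  expect_equal(compute_stenosis_ratio(0, 5), 0)
  expect_error(compute_stenosis_ratio(3, 0), class = "atheromech_invalid_geometry")
  expect_error(compute_stenosis_ratio(-1, 2), class = "atheromech_invalid_geometry")
})

test_that("idealized builder hits the requested stenosis ratio and cap", {
  geom <- base_geometry()
  # polygon-area oracle on the emitted contours, independent of the
  # builder's internals
  area_of <- function(region) {
    cc <- geom$contours[geom$contours$region == region, ]
    abs(atheromech:::polygon_area(cc$x, cc$y))
  }
  A_lum <- area_of("lumen")
  A_int <- area_of("intima")
  sr_poly <- compute_stenosis_ratio(A_int - A_lum, A_lum)
  expect_lt(abs(sr_poly - 70), 0.5)
  # minimum lumen-core distance equals the cap thickness
  lum <- geom$contours[geom$contours$region == "lumen", ]
  core <- geom$contours[geom$contours$region == "core", ]
  dmin <- atheromech:::min_polyline_distance(lum$x, lum$y, core$x, core$y)
  expect_lt(abs(dmin - 0.065), 0.065 * 0.05)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(geometry_params(cap_thk = 0), class = "atheromech_invalid_geometry")
  expect_error(geometry_params(cap_thk = 500), class = "atheromech_invalid_geometry")
  expect_error(geometry_params(core_thk = 100), class = "atheromech_invalid_geometry")
  expect_error(geometry_params(phi_lum = 7), class = "atheromech_invalid_geometry")
})

test_that("every grid combination builds with SR within 0.5 pp", {
  grid <- enumerate_idealized_grid()
  # subsample across the whole grid; the full sweep runs in the
  # campaign tests
  idx <- seq(1, nrow(grid), by = 37)
  for (i in idx) {
    p <- grid[i, ]
    geom <- build_idealized(geometry_params(SR = p$SR, cap_thk = p$cap_thk,
                                            core_thk = p$core_thk))
    expect_lt(abs(geom$SR - p$SR), 0.5)
  }
})

test_that("idealized grid enumerates the full factorial", {
  grid <- enumerate_idealized_grid()
  expect_equal(nrow(grid), 540)
  expect_equal(sort(unique(grid$SR)), seq(40, 80, by = 5))
  expect_length(unique(grid$cap_thk), 10)
  expect_equal(range(grid$cap_thk), c(65, 300))
  expect_length(unique(grid$core_thk), 6)
  expect_equal(range(grid$core_thk), c(300, 800))
  expect_identical(grid, enumerate_idealized_grid()) # pure function
})

test_that("material grid spans the ranges with log core spacing", {
  mg <- enumerate_material_grid()
  expect_length(mg$E_core, 300)
  expect_equal(range(mg$E_core), c(1, 100))
  expect_equal(mg$E_plaque, seq(390, 1200, by = 90))
  expect_true(all(diff(diff(mg$E_core)) > 0)) # gaps strictly increasing
  expect_equal(enumerate_material_grid(3, 2)$E_core, c(1, 10, 100))
})

test_that("realistic family crosses cap variants with materials deterministically", {
  fam <- generate_realistic_family(n_cap = 4,
                                   material_grid = enumerate_material_grid(5, 2),
                                   seed = 11)
  expect_equal(nrow(fam$cases), 4 * 5 * 2)
  expect_equal(range(fam$cap_grid), c(65, 300))
  fam2 <- generate_realistic_family(n_cap = 4,
                                    material_grid = enumerate_material_grid(5, 2),
                                    seed = 11)
  expect_identical(fam$geometries[[2]]$contours, fam2$geometries[[2]]$contours)
  # perturbed lumen is genuinely non-circular
  lum <- fam$geometries[[1]]$contours
  lum <- lum[lum$region == "lumen", ]
  ctr <- c(fam$geometries[[1]]$shape$xc, 0)
  r <- sqrt((lum$x - ctr[1])^2 + lum$y^2)
  expect_gt(diff(range(r)) / mean(r), 0.005)
  # every member passes the validator
  for (g in fam$geometries) expect_silent(validate_geometry(g))
})

test_that("default realistic family sizes follow the study conditions", {
  fam <- generate_realistic_family(n_cap = 2, seed = 3)
  # default material grid is 50 x 10 -> 500 combinations per variant
  expect_equal(nrow(fam$cases) / 2, 500)
})

test_that("contours round-trip through CSV", {
  geom <- base_geometry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(geom, path)
  back <- read_contours(path)
  expect_equal(back$x, geom$contours$x, tolerance = 1e-9)
  expect_equal(back$region, geom$contours$region)
})

test_that("mirror symmetry: full-model area is twice the half-model area", {
  geom <- base_geometry()
  lum <- geom$contours[geom$contours$region == "lumen", ]
  A_full <- abs(atheromech:::polygon_area(lum$x, lum$y))
  # half-model (y >= 0) area by quadrature of the polar radius about
  # the lumen center
  gl <- atheromech:::gauss_legendre(64, 0, pi)
  r <- atheromech:::shape_radius(geom$shape, "lumen", gl$nodes)
  A_half <- 0.5 * sum(gl$weights * r^2)
  expect_equal(A_full, 2 * A_half, tolerance = 1e-3)
})
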
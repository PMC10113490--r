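test_that("meshes partition the geometry and resolve the cap", {
  geom <- base_geometry()
  mesh <- mesh_geometry(geom, h = 0.2)
  # partition property: element areas sum to the half-model area
  A_elems <- sum(atheromech:::tri_areas(mesh$nodes, mesh$tri))
  adv <- geom$contours[geom$contours$region == "adventitia", ]
  lum <- geom$contours[geom$contours$region == "lumen", ]
  A_geom <- (abs(atheromech:::polygon_area(adv$x, adv$y)) -
               abs(atheromech:::polygon_area(lum$x, lum$y))) / 2
  expect_lt(abs(A_elems - A_geom) / A_geom, 0.005)
  # cap band resolved by at least two element rows
  expect_gte(mesh$rings[1], 2)
  # all region labels assigned
  expect_setequal(unique(mesh$region), c("core", "plaque", "media", "adventitia"))
  # refinement scaling: halving h grows the element count about 4x
  mesh2 <- mesh_geometry(geom, h = 0.1)
  ratio <- nrow(mesh2$tri) / nrow(mesh$tri)
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("assembled energy gradient matches finite differences", {
  layers <- data.frame(r_in = c(1.8, 2.3), r_out = c(2.3, 2.8),
                       region = c("inner", "outer"))
  mesh <- mesh_ring(layers, h = 0.5)
  mats <- list(inner = neo_hookean(600), outer = table2_materials()$media)
  fs <- atheromech:::fem_setup(mesh, mats, solver_config())
  set.seed(1)
  nn <- nrow(mesh$nodes)
  u <- matrix(rnorm(2 * nn, sd = 0.01), nn, 2)
  res <- atheromech:::fem_energy_grad(fs, mesh$nodes + u, 5)
  idx <- sample(2 * nn, 15)
  for (i in idx) {
    h <- 1e-6
    up <- u; um <- u
    if (i <= nn) {
      up[i, 1] <- up[i, 1] + h; um[i, 1] <- um[i, 1] - h
    } else {
      up[i - nn, 2] <- up[i - nn, 2] + h; um[i - nn, 2] <- um[i - nn, 2] - h
    }
    fd <- (atheromech:::fem_energy_grad(fs, mesh$nodes + up, 5, FALSE)$E -
             atheromech:::fem_energy_grad(fs, mesh$nodes + um, 5, FALSE)$E) / (2 * h)
    expect_equal(res$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("zero end pressure produces zero displacement and zero features", {
  layers <- oracle_ring_layers()
  layers$region <- "plaque" # so the strain features have a region
  mesh <- mesh_ring(layers, h = 0.3)
  sol <- solve_inflation(mesh, list(plaque = neo_hookean(600)),
                         load_protocol(end_kPa = 0, n_inc = 2))
  # zero up to the solver's force tolerance
  expect_lt(max(abs(sol$U[[3]])), 1e-6)
  f <- extract_features(sol, mode = "full")
  expect_lt(abs(f$eps_theta), 1e-6)
  expect_lt(abs(f$eps1), 1e-6)
})

test_that("lumen area grows monotonically with pressure", {
  mesh <- mesh_ring(oracle_ring_layers(), h = 0.25)
  sol <- solve_inflation(mesh, list(wall = neo_hookean(600)),
                         load_protocol(n_inc = 7))
  expect_true(all(diff(sol$lumen_diameter) > 0))
  expect_true(all(sol$convergence$converged))
})

test_that("missing material assignment is a clear error", {
  geom <- base_geometry()
  mesh <- mesh_geometry(geom, h = 0.3)
  expect_error(solve_inflation(mesh, list(core = neo_hookean(5))),
               class = "atheromech_domain_error")
})

test_that("relative lumen-diameter change follows its definition", {
  # hand-built solution: uniform radial scaling of a ring by 1%
  mesh <- mesh_ring(oracle_ring_layers(), h = 0.4)
  lam <- 3.636 / 3.6
  U1 <- mesh$nodes * (lam - 1)
  sol <- structure(list(
    U = list(matrix(0, nrow(mesh$nodes), 2), U1),
    pressures = c(0, 1),
    lumen_diameter = c(3.6, 3.636),
    convergence = tibble::tibble(converged = TRUE),
    mesh = mesh), class = "fem_solution")
  f <- extract_features(sol, mode = "full")
  expect_equal(f$eps_theta, 0.01, tolerance = 1e-12)
  # uniform scaling: principal Green-Lagrange strain (lam^2 - 1)/2
  # everywhere; the ring mesh has no fibrotic region label, so check
  # the strain field helper directly
  pr <- atheromech:::principal_incremental_strains(mesh, sol$U[[1]], sol$U[[2]],
                                                   region = "wall")
  expect_equal(pr$eps1, (lam^2 - 1) / 2, tolerance = 1e-9)
  expect_equal(pr$eps2, (lam^2 - 1) / 2, tolerance = 1e-9)
})

test_that("features are invariant under mirroring of the half-model", {
  geom <- base_geometry()
  mesh <- mesh_geometry(geom, h = 0.3)
  mirrored <- mesh
  mirrored$nodes[, 2] <- -mirrored$nodes[, 2]
  mirrored$tri <- mirrored$tri[, c(1, 3, 2)]
  mirrored$lumen_chain <- rev(mirrored$lumen_chain)
  mats <- base_plaque_materials()
  proto <- load_protocol(n_inc = 4)
  f1 <- extract_features(solve_inflation(mesh, mats, proto), geom)
  f2 <- extract_features(solve_inflation(mirrored, mats, proto), geom)
  # identical up to the solver's convergence tolerance
  expect_equal(f1$eps_theta, f2$eps_theta, tolerance = 1e-3)
  expect_equal(f1$eps_cap, f2$eps_cap, tolerance = 1e-3)
  expect_equal(f1$eps1, f2$eps1, tolerance = 1e-3)
})

test_that("solution stays nearly incompressible in neo-Hookean regions", {
  geom <- base_geometry()
  mesh <- mesh_geometry(geom, h = 0.25)
  sol <- solve_inflation(mesh, base_plaque_materials())
  expect_gte(min(sol$J_range$core), 0.95)
  expect_lte(max(sol$J_range$core), 1.05)
  expect_gte(min(sol$J_range$plaque), 0.95)
  expect_lte(max(sol$J_range$plaque), 1.05)
})

test_that("stiffer fibrotic tissue deforms less (paired runs)", {
  geom <- base_geometry()
  mesh <- mesh_geometry(geom, h = 0.25)
  sol_soft <- solve_inflation(mesh, base_plaque_materials(5, 500))
  sol_stiff <- solve_inflation(mesh, base_plaque_materials(5, 1000))
  f_soft <- extract_features(sol_soft, geom)
  f_stiff <- extract_features(sol_stiff, geom)
  expect_lt(abs(f_stiff$eps_cap), abs(f_soft$eps_cap))
  expect_lt(f_stiff$eps_theta, f_soft$eps_theta)
})

test_that("mesh refinement changes the response by less than 1%", {
  geom <- base_geometry()
  mats <- base_plaque_materials()
  proto <- load_protocol(n_inc = 4)
  d_coarse <- solve_inflation(mesh_geometry(geom, h = 0.2), mats, proto)
  d_fine <- solve_inflation(mesh_geometry(geom, h = 0.1), mats, proto)
  n <- length(d_coarse$lumen_diameter)
  u_c <- d_coarse$lumen_diameter[n] - d_coarse$lumen_diameter[1]
  u_f <- d_fine$lumen_diameter[n] - d_fine$lumen_diameter[1]
  expect_lt(abs(u_c - u_f) / abs(u_f), 0.01)
})

test_that("meshes export to legacy VTK", {
  mesh <- mesh_ring(oracle_ring_layers(), h = 0.4)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(mesh, path, displacement = mesh$nodes * 0.01)
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^VECTORS displacement", txt)))
})
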
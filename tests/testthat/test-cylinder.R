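test_that("closed-form inflation: zero load, monotonicity, stiffness ordering", {
  ring <- oracle_ring_layers()
  expect_equal(cylinder_closed_form(ring, 0), 0)
  u1 <- cylinder_closed_form(ring, 5)
  u2 <- cylinder_closed_form(ring, 10)
  expect_gt(u1, 0)
  expect_gt(u2, u1)
  stiff <- transform(ring, C10 = C10 * 2)
  expect_lt(cylinder_closed_form(stiff, 10), u1 * 2)
  expect_lt(cylinder_closed_form(stiff, 10), cylinder_closed_form(ring, 10))
})

test_that("thin-wall limit matches the linearized Laplace estimate", {
  # sigma_theta - sigma_r ~ 8 C10 eps for small strain; equilibrium of
  # a thin ring gives u = P r^2 / (8 C10 t)
  r <- 10; t <- 0.05; C10 <- 100; P <- 0.02 # small load: linear regime
  thin <- data.frame(r_in = r, r_out = r + t, C10 = C10)
  u <- cylinder_closed_form(thin, P)
  u_laplace <- P * r^2 / (8 * C10 * t)
  expect_lt(abs(u - u_laplace) / u_laplace, 0.05)
})

test_that("layer bookkeeping is validated", {
  gap <- data.frame(r_in = c(1, 2.5), r_out = c(2, 3), C10 = c(1, 1))
  expect_error(cylinder_inflation(gap, 1), class = "atheromech_domain_error")
  bad <- data.frame(r_in = 2, r_out = 1, C10 = 1)
  expect_error(cylinder_inflation(bad, 1), class = "atheromech_domain_error")
  expect_error(cylinder_inflation(oracle_ring_layers(), -1),
               class = "atheromech_domain_error")
})

test_that("multi-layer stack is consistent with a merged single layer", {
  # two contiguous layers of equal stiffness behave as one thick layer
  one <- data.frame(r_in = 1.8, r_out = 2.8, C10 = 50)
  two <- data.frame(r_in = c(1.8, 2.2), r_out = c(2.2, 2.8), C10 = c(50, 50))
  expect_equal(cylinder_closed_form(one, 8), cylinder_closed_form(two, 8),
               tolerance = 1e-8)
})

test_that("analytic GOH stress difference matches the energy derivative", {
  m <- table2_materials()$media
  f <- atheromech:::layer_stress_functions(
    data.frame(r_in = 1, r_out = 2, material = I(list(m))))[[1]]
  for (lam in c(1.01, 1.05, 1.1)) {
    h <- 1e-6
    What <- function(l) goh_energy(diag(c(l^(-2), l^2, 1)), m, circ = c(0, 1))
    expect_equal(f(lam), lam * (What(lam + h) - What(lam - h)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("vectorized multi-pressure solve matches individual solves", {
  ring <- oracle_ring_layers()
  Ps <- c(3, 9, 15)
  multi <- cylinder_inflation(ring, Ps)
  for (i in seq_along(Ps)) {
    expect_equal(multi$u_inner[i], cylinder_closed_form(ring, Ps[i]),
                 tolerance = 1e-7)
  }
})
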
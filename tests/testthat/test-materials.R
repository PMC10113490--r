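test_that("C10 relates to Young's modulus as E/6", {
  expect_equal(c10_from_E(6), 1)
  expect_equal(c10_from_E(600), 100)
  expect_equal(c10_from_E(1), 1 / 6, tolerance = 1e-6)
  expect_error(c10_from_E(0), class = "atheromech_domain_error")
  expect_error(c10_from_E(-3), class = "atheromech_domain_error")
})

test_that("neo-Hookean energy is zero at rotations and matches closed form", {
  expect_equal(nh_energy(diag(2), 1), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(nh_energy(R, 2.5), 0, tolerance = 1e-12)
  # isochoric plane-strain uniaxial stretch
  lam <- 1.1
  W <- nh_energy(diag(c(lam, 1 / lam)), 1)
  expect_equal(W, (lam^2 + lam^(-2) + 1) - 3, tolerance = 1e-12)
  # frame indifference: W(F) = W(RF)
  F <- diag(c(1.05, 1 / 1.05))
  expect_equal(nh_energy(R %*% F, 3), nh_energy(F, 3), tolerance = 1e-12)
  expect_error(nh_energy(matrix(c(1, 0, 2, 0), 2), 1),
               class = "atheromech_domain_error")
})

test_that("neo-Hookean stress matches numerical differentiation of the energy", {
  set.seed(5)
  # random isochoric plane-strain F
  A <- matrix(rnorm(4, sd = 0.1), 2)
  F <- diag(2) + A
  F <- F / sqrt(det(F))
  C10 <- 2
  sig <- nh_stress(F, C10)
  expect_equal(sig, t(sig)) # symmetric
  # finite-difference first Piola, mapped to Cauchy: sigma = P F' / J
  F3 <- diag(3); F3[1:2, 1:2] <- F
  P_fd <- matrix(0, 3, 3)
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Fp <- F3; Fm <- F3
    Fp[i, j] <- Fp[i, j] + h; Fm[i, j] <- Fm[i, j] - h
    P_fd[i, j] <- (nh_energy(Fp, C10) - nh_energy(Fm, C10)) / (2 * h)
  }
  sig_fd <- P_fd %*% t(F3) / det(F3)
  expect_equal(sig, sig_fd, tolerance = 1e-6)
  # zero deviatoric stress at identity and at pure rotations
  expect_equal(nh_stress(diag(2), 5), matrix(0, 3, 3), tolerance = 1e-14)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(max(abs(nh_stress(R, 5))), 0, tolerance = 1e-12)
})

test_that("GOH energy: reference zero, dispersion limit, oracle value", {
  mats <- table2_materials()
  expect_equal(mats$media$k1, 206.16)
  expect_equal(mats$media$mu, 1.4)
  expect_equal(mats$media$k2, 58.55)
  expect_equal(mats$media$kappa, 0.29)
  expect_equal(mats$adventitia$mu, 8.44)
  expect_equal(mats$adventitia$k1, 547.67)
  expect_equal(mats$adventitia$k2, 568.01)
  expect_equal(mats$adventitia$kappa, 0.26)
  expect_true(all(c(mats$media$kappa, mats$adventitia$kappa) <= 1 / 3))

  expect_equal(goh_energy(diag(2), mats$media), 0)

  # kappa = 1/3: fiber term independent of fiber direction
  iso <- goh_material(mu = 2, k1 = 10, k2 = 5, kappa = 1 / 3, beta = 30)
  C <- diag(c(1.1, 0.95, 1 / (1.1 * 0.95)))
  e1 <- goh_energy(C, iso, circ = c(1, 0))
  e2 <- goh_energy(C, iso, circ = c(0.3, 0.8))
  expect_equal(e1, e2, tolerance = 1e-12)

  # independent evaluation of the dispersed-fiber formula at an
  # equibiaxial in-plane stretch (J = 1 so invariants are unmodified)
  lam <- 1.05
  C <- diag(c(lam^2, lam^2, lam^(-4)))
  m <- mats$media
  I1 <- sum(diag(C))
  b <- m$beta * pi / 180
  a4 <- c(cos(b), sin(b), 0)
  I4 <- drop(a4 %*% C %*% a4)
  E <- m$kappa * (I1 - 3) + (1 - 3 * m$kappa) * (I4 - 1)
  W_ref <- m$mu / 2 * (I1 - 3) + 2 * (m$k1 / (2 * m$k2)) * (exp(m$k2 * E^2) - 1)
  expect_equal(goh_energy(C, m), W_ref, tolerance = 1e-10)

  expect_error(goh_energy(diag(c(1, -1, 1)), mats$media),
               class = "atheromech_domain_error")
  expect_error(goh_material(1, 1, 1, kappa = 0.5),
               class = "atheromech_domain_error")
})

test_that("materials serialize to JSON and back", {
  mats <- c(list(core = neo_hookean(5)), table2_materials())
  path <- withr::local_tempfile(fileext = ".json")
  write_materials(mats, path)
  back <- read_materials(path)
  expect_equal(back$core$C10, mats$core$C10)
  expect_equal(back$media$k1, mats$media$k1)
  expect_equal(back$adventitia$kappa, mats$adventitia$kappa)
})
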
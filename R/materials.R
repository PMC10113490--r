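#' Constitutive models for the artery wall
#'
#' Two hyperelastic laws cover the four regions of the cross-section:
#' the lipid core and the fibrotic tissue (including the cap) are
#' isotropic incompressible neo-Hookean solids, while the media and
#' adventitia are fiber-reinforced Gasser-Ogden-Holzapfel (GOH)
#' materials with two dispersed collagen families. Incompressibility is
#' enforced by the solver through a volumetric penalty; the energies
#' here use the isochoric (volume-preserving) invariants.
#'
#' @name materials
NULL

#' Neo-Hookean stiffness parameter from Young's modulus
#'
#' For an incompressible neo-Hookean solid the single stiffness
#' parameter relates to the small-strain Young's modulus as
#' \eqn{C_{10} = E/6}.
#'
#' @param E Young's modulus (kPa), strictly positive.
#' @return `C10` in kPa.
#' @examples
#' c10_from_E(600) # 100
#' @export
c10_from_E <- function(E) {
  if (any(E <= 0)) ath_abort("Young's modulus must be strictly positive.",
                             "atheromech_domain_error")
  E / 6
}

#' Neo-Hookean material
#'
#' @param E Young's modulus (kPa).
#' @return A material object (`ath_material`).
#' @export
neo_hookean <- function(E) {
  structure(list(model = "neo_hookean", E = E, C10 = c10_from_E(E)),
            class = "ath_material")
}

#' Gasser-Ogden-Holzapfel material
#'
#' @param mu Ground-matrix shear parameter (kPa).
#' @param k1 Fiber stiffness (kPa).
#' @param k2 Fiber exponent (dimensionless).
#' @param kappa Fiber dispersion, in `[0, 1/3]` (1/3 = isotropic).
#' @param beta Mean fiber angle from the circumferential direction
#'   (degrees); two symmetric families at +/- `beta`. Not reported with
#'   the layer parameter set used here; configurable, default 45.
#' @return A material object (`ath_material`).
#' @export
goh_material <- function(mu, k1, k2, kappa, beta = 45) {
  if (mu <= 0 || k1 <= 0 || k2 <= 0) {
    ath_abort("GOH parameters mu, k1, k2 must be strictly positive.",
              "atheromech_domain_error")
  }
  if (kappa < 0 || kappa > 1 / 3) {
    ath_abort("GOH dispersion kappa must lie in [0, 1/3].", "atheromech_domain_error")
  }
  structure(list(model = "goh", mu = mu, k1 = k1, k2 = k2,
                 kappa = kappa, beta = beta),
            class = "ath_material")
}

#' Literature GOH parameters for media and adventitia
#'
#' Fixed layer properties used for every simulated case (these layers
#' are not prediction targets): media mu = 1.4 kPa, k1 = 206.16 kPa,
#' k2 = 58.55, kappa = 0.29; adventitia mu = 8.44 kPa, k1 = 547.67 kPa,
#' k2 = 568.01, kappa = 0.26.
#'
#' @param beta Fiber angle (degrees) applied to both layers; see
#'   [goh_material()].
#' @return A named list with `media` and `adventitia` materials.
#' @export
table2_materials <- function(beta = 45) {
  list(
    media = goh_material(mu = 1.4, k1 = 206.16, k2 = 58.55, kappa = 0.29, beta = beta),
    adventitia = goh_material(mu = 8.44, k1 = 547.67, k2 = 568.01, kappa = 0.26, beta = beta)
  )
}

# embed a 2x2 plane-strain tensor into 3x3 with out-of-plane entry 1
embed3 <- function(M) {
  if (all(dim(M) == c(3, 3))) return(M)
  out <- diag(3)
  out[1:2, 1:2] <- M
  out
}

#' Neo-Hookean strain-energy density
#'
#' Isochoric neo-Hookean energy \eqn{W = C_{10}(\bar I_1 - 3)} with
#' \eqn{\bar I_1 = J^{-2/3} I_1}; zero at any rigid rotation. The
#' volumetric response is owned by the solver.
#'
#' @param F Deformation gradient, 2x2 (plane strain, out-of-plane
#'   stretch 1 implied) or 3x3; `det F > 0`.
#' @param C10 Stiffness parameter (kPa), or an `ath_material` from
#'   [neo_hookean()].
#' @return Energy density in kPa.
#' @export
nh_energy <- function(F, C10 = 1) {
  if (inherits(C10, "ath_material")) C10 <- C10$C10
  F <- embed3(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    ath_abort("deformation gradient must have positive determinant", "atheromech_domain_error")
  }
  I1 <- sum(F^2)
  C10 * (J^(-2 / 3) * I1 - 3)
}

#' Neo-Hookean Cauchy stress (isochoric part)
#'
#' Analytic derivative of [nh_energy()]:
#' \eqn{\sigma = \frac{2 C_{10}}{J} J^{-2/3} \,\mathrm{dev}(B)} with
#' \eqn{B = F F^T}. Consistent with numerical differentiation of the
#' energy; the (indeterminate) hydrostatic pressure of the
#' incompressibility constraint is not included.
#'
#' @inheritParams nh_energy
#' @return Symmetric 3x3 Cauchy stress tensor (kPa).
#' @export
nh_stress <- function(F, C10 = 1) {
  if (inherits(C10, "ath_material")) C10 <- C10$C10
  F <- embed3(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    ath_abort("deformation gradient must have positive determinant", "atheromech_domain_error")
  }
  B <- F %*% t(F)
  devB <- B - diag(3) * sum(diag(B)) / 3
  2 * C10 * J^(-5 / 3) * devB
}

#' Gasser-Ogden-Holzapfel strain-energy density
#'
#' Standard two-family dispersed-fiber form on isochoric invariants:
#' \deqn{\Psi = \frac{\mu}{2}(\bar I_1 - 3) +
#'   \frac{k_1}{2 k_2} \sum_{i=4,6} \left[\exp(k_2 \bar E_i^2) - 1\right],}
#' \eqn{\bar E_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_i - 1)},
#' with the fiber term engaged only in tension (\eqn{\bar E_i > 0}).
#' Fiber families lie in-plane at angles +/- `beta` from the local
#' circumferential axis.
#'
#' @param C Right Cauchy-Green tensor, 2x2 (plane strain) or 3x3,
#'   symmetric positive-definite.
#' @param mat A `goh` material from [goh_material()].
#' @param circ Unit vector of the local circumferential direction in
#'   the reference configuration (length 2 or 3; default along x).
#' @return Energy density in kPa.
#' @export
goh_energy <- function(C, mat, circ = c(1, 0)) {
  stopifnot(inherits(mat, "ath_material"), identical(mat$model, "goh"))
  C <- embed3(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    ath_abort("C must be symmetric positive-definite", "atheromech_domain_error")
  }
  J2 <- det(C) # J^2
  I1b <- J2^(-1 / 3) * sum(diag(C))

  circ <- c(circ, 0, 0)[1:3]
  circ <- circ / sqrt(sum(circ^2))
  # in-plane normal to circ
  nrm <- c(-circ[2], circ[1], 0)
  b <- mat$beta * pi / 180
  a4 <- cos(b) * circ + sin(b) * nrm
  a6 <- cos(b) * circ - sin(b) * nrm

  fiber <- function(a) {
    I4b <- J2^(-1 / 3) * drop(a %*% C %*% a)
    E <- mat$kappa * (I1b - 3) + (1 - 3 * mat$kappa) * (I4b - 1)
    if (E > 0) (mat$k1 / (2 * mat$k2)) * (exp(mat$k2 * E^2) - 1) else 0
  }
  mat$mu / 2 * (I1b - 3) + fiber(a4) + fiber(a6)
}

#' Serialize material assignments to JSON
#'
#' @param materials Named list of `ath_material` objects (one per region).
#' @param path File path.
#' @return `write_materials()` returns `path` invisibly;
#'   `read_materials()` the named list.
#' @export
write_materials <- function(materials, path) {
  payload <- lapply(materials, function(m) unclass(m))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_materials
#' @export
read_materials <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    if (identical(m$model, "neo_hookean")) neo_hookean(m$E)
    else goh_material(m$mu, m$k1, m$k2, m$kappa, m$beta)
  })
}
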
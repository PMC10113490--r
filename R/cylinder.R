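#' Closed-form inflation of an incompressible layered cylinder
#'
#' Independent verification oracle for the finite element solver: a
#' thick-walled multi-layer cylinder under internal pressure, plane
#' strain, exactly incompressible. Incompressibility fixes the
#' kinematics to \eqn{r^2 = R^2 + c} with a single constant `c` shared
#' by all contiguous layers; the circumferential stretch is
#' \eqn{\lambda = r/R}. Radial equilibrium integrates to the pressure
#' balance
#' \deqn{P = \sum_{layers} \int_{R_a}^{R_b}
#'   (\sigma_\theta - \sigma_r)\, \frac{R}{R^2 + c}\, dR,}
#' evaluated by Gauss-Legendre quadrature; for a neo-Hookean layer
#' \eqn{\sigma_\theta - \sigma_r = 2 C_{10} (\lambda^2 - \lambda^{-2})},
#' for a general layer it is \eqn{\lambda\, \hat W'(\lambda)} with
#' \eqn{\hat W} the plane-strain incompressible energy, differentiated
#' numerically. The pressure is monotone in `c`, so `c` is found by
#' safeguarded root bracketing.
#'
#' @param layers A data frame with columns `r_in`, `r_out` (mm,
#'   contiguous from the inside out) and either a numeric `C10` column
#'   (kPa) or a `material` list-column of [neo_hookean()]/
#'   [goh_material()] objects.
#' @param P Internal pressure (kPa), non-negative.
#' @param n_gauss Quadrature points per layer.
#' @return `cylinder_closed_form()`: the inner-radius displacement
#'   (mm). `cylinder_inflation()`: a list with `c` (kinematic
#'   constant), `u_inner`, and `interfaces`, a tibble of reference and
#'   deformed radii of every layer boundary.
#' @examples
#' ring <- data.frame(r_in = 1.8, r_out = 2.8, C10 = 100)
#' cylinder_closed_form(ring, 18.66)
#' @export
cylinder_closed_form <- function(layers, P, n_gauss = 32) {
  cylinder_inflation(layers, P, n_gauss)$u_inner
}

#' @rdname cylinder_closed_form
#' @export
cylinder_inflation <- function(layers, P, n_gauss = 32) {
  layers <- as.data.frame(layers)
  stopifnot(all(c("r_in", "r_out") %in% names(layers)), nrow(layers) >= 1)
  if (any(layers$r_out <= layers$r_in) || layers$r_in[1] <= 0) {
    ath_abort("layer radii must be positive with r_out > r_in", "atheromech_domain_error")
  }
  if (nrow(layers) > 1 &&
      any(abs(layers$r_in[-1] - layers$r_out[-nrow(layers)]) > 1e-9)) {
    ath_abort("layers must be contiguous (each r_in equals the previous r_out)",
              "atheromech_domain_error")
  }
  if (any(P < 0)) ath_abort("pressure must be non-negative", "atheromech_domain_error")

  sigma_diffs <- layer_stress_functions(layers)
  gls <- lapply(seq_len(nrow(layers)), function(i)
    gauss_legendre(n_gauss, layers$r_in[i], layers$r_out[i]))

  pressure_of <- function(cc) {
    tot <- 0
    for (i in seq_len(nrow(layers))) {
      gl <- gls[[i]]
      lam <- sqrt(gl$nodes^2 + cc) / gl$nodes
      tot <- tot + sum(gl$weights * sigma_diffs[[i]](lam) * gl$nodes / (gl$nodes^2 + cc))
    }
    tot
  }

  solve_c <- function(P, lo = 0) {
    if (P == 0) return(0)
    hi <- max(lo, layers$r_in[1]^2 * 0.01)
    while (pressure_of(hi) < P) {
      hi <- hi * 2
      if (hi > 100 * layers$r_out[nrow(layers)]^2) {
        ath_abort("pressure balance did not bracket: load too large for this wall",
                  "atheromech_domain_error")
      }
    }
    uniroot(function(z) pressure_of(z) - P, c(lo, hi), tol = 3e-9)$root
  }

  radii <- c(layers$r_in[1], layers$r_out)
  if (length(P) == 1) {
    cc <- solve_c(P)
    r <- sqrt(radii^2 + cc)
    return(list(c = cc, u_inner = r[1] - radii[1],
                interfaces = data.frame(R = radii, r = r)))
  }
  # multiple pressures: reuse each root as the bracket for the next
  ord <- order(P)
  cs <- numeric(length(P))
  lo <- 0
  for (i in ord) {
    cs[i] <- solve_c(P[i], lo = lo)
    lo <- cs[i]
  }
  list(c = cs, u_inner = sqrt(radii[1]^2 + cs) - radii[1],
       interfaces = lapply(cs, function(cc)
         data.frame(R = radii, r = sqrt(radii^2 + cc))))
}

# per-layer (sigma_theta - sigma_r)(lambda), vectorized over lambda
layer_stress_functions <- function(layers) {
  lapply(seq_len(nrow(layers)), function(i) {
    if ("material" %in% names(layers)) {
      mat <- layers$material[[i]]
    } else {
      mat <- neo_hookean(6 * layers$C10[i])
    }
    if (identical(mat$model, "neo_hookean")) {
      C10 <- mat$C10
      function(lam) 2 * C10 * (lam^2 - lam^(-2))
    } else {
      # analytic lambda * dW/dlambda for GOH with in-plane fibers at
      # +/- beta from circumferential (both families share I4 here)
      cb2 <- cos(mat$beta * pi / 180)^2
      sb2 <- 1 - cb2
      function(lam) {
        li2 <- lam^(-2); li3 <- li2 / lam
        I1 <- lam^2 + li2 + 1
        I4 <- cb2 * lam^2 + sb2 * li2
        Ef <- mat$kappa * (I1 - 3) + (1 - 3 * mat$kappa) * (I4 - 1)
        dI1 <- 2 * lam - 2 * li3
        dI4 <- 2 * cb2 * lam - 2 * sb2 * li3
        dE <- mat$kappa * dI1 + (1 - 3 * mat$kappa) * dI4
        fib <- (Ef > 0) * 2 * mat$k1 * Ef * exp(pmin(mat$k2 * Ef^2, 60)) * dE
        lam * (mat$mu / 2 * dI1 + fib)
      }
    }
  })
}
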
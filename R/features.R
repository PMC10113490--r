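#' Deformation features of an inflation solution
#'
#' Computes the predictor set used for inverse stiffness estimation
#' from a converged [solve_inflation()] run:
#' \itemize{
#' \item `eps_theta`: relative lumen diameter change
#'   \eqn{(\phi^{end} - \phi^{init})/\phi^{init}};
#' \item `eps_cap`, `eps_core`: the analogous relative thickness
#'   changes of the fibrous cap and the lipid core, measured along the
#'   symmetry axis through the cap midpoint;
#' \item `eps1`, `eps2`: extremal principal Green-Lagrange strains of
#'   the incremental deformation over the fibrotic tissue (cap
#'   included), per element with quad-patch averaging;
#' \item `SR`: the geometry's stenosis ratio;
#' \item squared variants of the three relative-change features.
#' }
#' The measurement window is, by default, the last pressure increment
#' (about 135 to 140 mmHg) -- the window in which intravascular
#' ultrasound captures frame-to-frame deformation; `mode = "full"`
#' instead uses the whole ramp from the unloaded state.
#'
#' @param sol A `fem_solution`.
#' @param geom The `plaque_geometry` that was meshed (`NULL` for ring
#'   meshes; cap/core features are then `NA`).
#' @param mode `"window"` (default, last increment) or `"full"`.
#' @return A one-row tibble of class `feature_vector`.
#' @export
extract_features <- function(sol, geom = NULL, mode = c("window", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sol, "fem_solution"))
  mesh <- sol$mesh
  n_states <- length(sol$U)
  if (n_states < 2) ath_abort("solution has no load increments", "atheromech_domain_error")
  i0 <- if (mode == "window") n_states - 1L else 1L
  i1 <- n_states
  if (!all(sol$convergence$converged)) {
    ath_abort("cannot extract features from a non-converged solution",
              "atheromech_solver_error")
  }

  phi0 <- sol$lumen_diameter[i0]
  phi1 <- sol$lumen_diameter[i1]
  eps_theta <- (phi1 - phi0) / phi0

  fn <- mesh$feature_nodes
  axis_thickness <- function(state, from, to) {
    xd <- mesh$nodes + sol$U[[state]]
    xd[to, 1] - xd[from, 1]
  }
  if (!is.na(fn$core_in)) {
    cap0 <- axis_thickness(i0, fn$lumen_cap, fn$core_in)
    cap1 <- axis_thickness(i1, fn$lumen_cap, fn$core_in)
    core0 <- axis_thickness(i0, fn$core_in, fn$core_out)
    core1 <- axis_thickness(i1, fn$core_in, fn$core_out)
    eps_cap <- (cap1 - cap0) / cap0
    eps_core <- (core1 - core0) / core0
  } else {
    eps_cap <- NA_real_
    eps_core <- NA_real_
  }

  pr <- principal_incremental_strains(mesh, sol$U[[i0]], sol$U[[i1]],
                                      region = "plaque")
  SR <- if (!is.null(geom)) geom$SR else NA_real_

  tibble::new_tibble(tibble::tibble(
    eps1 = pr$eps1, eps2 = pr$eps2,
    eps_core = eps_core, eps_cap = eps_cap, eps_theta = eps_theta,
    SR = SR,
    eps_core_sq = eps_core^2, eps_cap_sq = eps_cap^2,
    eps_theta_sq = eps_theta^2
  ), class = "feature_vector")
}

# Extremal principal Green-Lagrange strains of the deformation from
# state U0 to state U1, over the elements of one region, with
# quad-patch averaging of the strain components for mesh stability.
principal_incremental_strains <- function(mesh, U0, U1, region = "plaque") {
  sel <- mesh$region == region
  if (!any(sel)) return(list(eps1 = NA_real_, eps2 = NA_real_))
  tri <- mesh$tri
  # deformation gradients of both states wrt the reference mesh
  grads <- function(U) {
    xd <- mesh$nodes + U
    x1 <- xd[tri[, 1], ]; x2 <- xd[tri[, 2], ]; x3 <- xd[tri[, 3], ]
    X1 <- mesh$nodes[tri[, 1], ]; X2 <- mesh$nodes[tri[, 2], ]; X3 <- mesh$nodes[tri[, 3], ]
    d1x <- X2[, 1] - X1[, 1]; d1y <- X2[, 2] - X1[, 2]
    d2x <- X3[, 1] - X1[, 1]; d2y <- X3[, 2] - X1[, 2]
    det <- d1x * d2y - d2x * d1y
    e1x <- x2[, 1] - x1[, 1]; e1y <- x2[, 2] - x1[, 2]
    e2x <- x3[, 1] - x1[, 1]; e2y <- x3[, 2] - x1[, 2]
    # F = [e1 e2] %*% inv([d1 d2])
    list(F11 = (e1x * d2y - e2x * d1y) / det, F12 = (e2x * d1x - e1x * d2x) / det,
         F21 = (e1y * d2y - e2y * d1y) / det, F22 = (e2y * d1x - e1y * d2x) / det)
  }
  G0 <- grads(U0); G1 <- grads(U1)
  # incremental F = F1 F0^{-1}
  det0 <- G0$F11 * G0$F22 - G0$F12 * G0$F21
  i11 <- G0$F22 / det0; i12 <- -G0$F12 / det0
  i21 <- -G0$F21 / det0; i22 <- G0$F11 / det0
  F11 <- G1$F11 * i11 + G1$F12 * i21
  F12 <- G1$F11 * i12 + G1$F12 * i22
  F21 <- G1$F21 * i11 + G1$F22 * i21
  F22 <- G1$F21 * i12 + G1$F22 * i22
  # Green-Lagrange E = (F'F - I)/2
  E11 <- (F11^2 + F21^2 - 1) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  # patch-average the components over quad pairs
  A <- tri_areas(mesh$nodes, tri)
  pav <- function(v) {
    num <- rowsum(A * v, mesh$quad)
    den <- rowsum(A, mesh$quad)
    (num / den)[as.character(mesh$quad), 1]
  }
  E11 <- pav(E11); E22 <- pav(E22); E12 <- pav(E12)
  mid <- (E11 + E22) / 2
  rad <- sqrt(((E11 - E22) / 2)^2 + E12^2)
  list(eps1 = max((mid + rad)[sel]), eps2 = min((mid - rad)[sel]))
}
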
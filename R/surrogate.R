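#' Fast surrogate for the inflation feature map
#'
#' Large simulation campaigns (hundreds of thousands of finite element
#' solves at full scale) are impractical on a single workstation, so
#' the package provides a physics-based surrogate: each cross-section
#' is mapped to an equivalent concentric layered cylinder (cap, lipid
#' core, remaining fibrotic tissue, media, adventitia, with radii
#' matched to the region areas) whose inflation is solved in closed
#' form by [cylinder_inflation()]; the resulting features are then
#' multiplied by smooth correction factors fitted once against a set
#' of finite element solutions ([calibrate_surrogate()]).
#'
#' The surrogate is defined on the representative-core slice of the
#' geometry family: its lipid-core layer has a fixed 0.55 mm
#' thickness and the corrections carry no core-thickness term. This
#' is deliberate. The inverse problem recovers two moduli from three
#' strain features (plus the stenosis ratio); adding a fourth
#' independent latent influence would make distinct cases collide in
#' feature space and destroy the invertibility the estimation network
#' depends on. The finite element model does respond to core size
#' (strongly so at mild stenosis), so surrogate features approximate
#' FE features of the representative-core geometry, not of arbitrary
#' core thicknesses — the realistic-family studies, which hold the
#' core fixed, are unaffected.
#'
#' @name surrogate
NULL

# equivalent concentric layer stack for a parameter combination
.surrogate_cache <- new.env(parent = emptyenv())
surrogate_layers <- function(SR, cap_thk, E_core, E_plaque,
                             phi_int = 5.596, phi_med = 6.05, phi_adv = 6.5,
                             core_rep = 0.55, wall_mats = NULL) {
  if (is.null(wall_mats)) {
    if (is.null(.surrogate_cache$wall_mats)) {
      .surrogate_cache$wall_mats <- table2_materials()
    }
    wall_mats <- .surrogate_cache$wall_mats
  }
  R_int <- phi_int / 2
  r_eq <- R_int * sqrt(1 - SR / 100)
  cap <- um_to_mm(cap_thk)
  r1 <- r_eq + cap
  # The core layer saturates smoothly toward its representative
  # thickness as wall space allows (soft-min), so the layer stack --
  # and with it the base feature map -- stays smooth in (SR, cap):
  # a hard clamp here puts a kink right in the middle of the
  # stenosis range that the correction surface then has to chase.
  avail <- R_int - r1
  core_sc <- core_rep * avail / (avail + core_rep)
  r2 <- r1 + core_sc
  out <- data.frame(
    r_in = c(r_eq, r1, r2, R_int, phi_med / 2),
    r_out = c(r1, r2, R_int, phi_med / 2, phi_adv / 2))
  out$material <- list(neo_hookean(E_plaque), neo_hookean(E_core),
                       neo_hookean(E_plaque), wall_mats$media,
                       wall_mats$adventitia)
  out
}

# cylinder-based raw features over the feature window
surrogate_raw_features <- function(SR, cap_thk, E_core, E_plaque,
                                   protocol = load_protocol(), ...) {
  layers <- surrogate_layers(SR, cap_thk, E_core, E_plaque, ...)
  n <- protocol$n_inc
  P0 <- protocol$pressures[max(n - 1L, 1L)]
  P1 <- protocol$pressures[n]
  s <- cylinder_inflation(layers, c(P0, P1), n_gauss = 16)
  r0 <- s$interfaces[[1]]$r; r1 <- s$interfaces[[2]]$r
  # interfaces: 1 lumen, 2 cap/core, 3 core/plaque, 4 intima, ...
  cap0 <- r0[2] - r0[1]; cap1 <- r1[2] - r1[1]
  core0 <- r0[3] - r0[2]; core1 <- r1[3] - r1[2]
  eps_theta <- (r1[1] - r0[1]) / r0[1]
  eps_cap <- (cap1 - cap0) / cap0
  eps_core <- (core1 - core0) / core0
  # principal incremental Green-Lagrange strains in the fibrotic
  # tissue peak at the lumen surface; incompressibility gives the
  # radial counterpart
  lam_inc <- r1[1] / r0[1]
  eps1 <- (lam_inc^2 - 1) / 2
  eps2 <- (lam_inc^(-2) - 1) / 2
  data.frame(eps1 = eps1, eps2 = eps2, eps_core = eps_core,
             eps_cap = eps_cap, eps_theta = eps_theta, SR = SR)
}

# Centred regressors of the correction response surface: quadratic in
# centred stenosis ratio, log cap thickness, log core modulus and
# fibrotic modulus, plus the healthy-side wall thickness implied by
# the placement rule (t), which carries the piecewise-linear regime
# switch of the eccentric layout that pure polynomials cannot track.
correction_terms <- function(SR, cap_thk, E_core, E_plaque) {
  s <- (SR - 60) / 20
  cc <- log(cap_thk / 140) / log(300 / 140)
  e <- (log(E_core) - log(10)) / log(10)
  p <- (E_plaque - 795) / 405
  t <- (thin_wall_of(SR, cap_thk) - 0.18) / 0.07
  cbind(`(Intercept)` = 1, s = s, c = cc, e = e, p = p, t = t,
        s2 = s^2, c2 = cc^2, e2 = e^2, p2 = p^2, t2 = t^2,
        sc = s * cc, se = s * e, sp = s * p,
        ce = cc * e, cp = cc * p, ep = e * p,
        te = t * e, tp = t * p)
}

#' Calibrate the surrogate against the finite element model
#'
#' Runs a designed set of finite element inflations spanning the
#' study's parameter ranges — a half-fraction factorial plus seeded
#' space-filling points (156 solves by default, within a 200-solve
#' budget) — and fits, per feature, a multiplicative correction
#' factor whose logarithm is a full quadratic response surface in
#' centred stenosis ratio, log cap thickness, log core modulus and
#' fibrotic modulus. The modulus terms matter: in the incompressible
#' equivalent cylinder the layer thickness changes are kinematically
#' fixed, so the raw cylinder features underrepresent the deviatoric
#' response of a soft core that the finite element model exhibits;
#' modulus-dependent corrections restore both fidelity and the
#' invertibility of the feature-to-modulus map. All fit and holdout
#' cases use the representative 0.55 mm core (see [surrogate]); the
#' regressors also include the healthy-wall thickness implied by the
#' eccentric placement rule, whose regime switch pure polynomials in
#' the design variables cannot track. Fit quality is evaluated on
#' held-out FE cases and recorded in the returned object; the frozen
#' calibration ships with the package
#' (`inst/extdata/surrogate_calibration.json`).
#'
#' @param n_fill Space-filling fit points beyond the 36-run fraction.
#' @param n_holdout Held-out FE cases for validation.
#' @param h Mesh edge length for the calibration FE solves (mm).
#' @param seed Seed for the designs.
#' @param protocol Load protocol shared by FE and surrogate.
#' @param verbose Print progress.
#' @param fe_tables Optional list with precomputed `fit` and `hold`
#'   tables (design columns, `fe_*` and `cyl_*` features), bypassing
#'   the FE solves; used to refit the response surface.
#' @return A `surrogate_calibration` object: per-feature coefficient
#'   vectors, holdout relative errors, and provenance.
#' @export
calibrate_surrogate <- function(n_fill = 120, n_holdout = 20, h = 0.2,
                                seed = 1L, protocol = load_protocol(),
                                verbose = TRUE, fe_tables = NULL) {
  if (is.null(fe_tables)) {
    fit_a <- tidyr::expand_grid(
      iSR = 1:3, icap = 1:3, icore = 1:2, iEc = 1:2, iEp = 1:2
    ) |>
      dplyr::filter((.data$iSR + .data$icap + .data$icore + .data$iEc +
                       .data$iEp) %% 2 == 0) |>
      dplyr::transmute(
        SR = c(40, 60, 80)[.data$iSR],
        cap_thk = c(65, 140, 300)[.data$icap],
        core_thk = 550, # the surrogate's representative core slice
        E_core = c(4, 60)[.data$iEc],
        E_plaque = c(480, 1110)[.data$iEp]
      ) |> dplyr::distinct()
    set.seed(seed + 1L)
    fit_b <- tibble::tibble(
      SR = runif(n_fill, 40, 80),
      cap_thk = exp(runif(n_fill, log(65), log(300))),
      core_thk = 550,
      E_core = exp(runif(n_fill, log(1), log(100))),
      E_plaque = runif(n_fill, 390, 1200))
    set.seed(seed)
    hold_design <- tibble::tibble(
      SR = runif(n_holdout, 40, 80),
      cap_thk = exp(runif(n_holdout, log(65), log(300))),
      core_thk = 550,
      E_core = exp(runif(n_holdout, log(1), log(100))),
      E_plaque = runif(n_holdout, 390, 1200))

    run_fe <- function(d, label) {
      purrr::map_dfr(seq_len(nrow(d)), function(i) {
        r <- d[i, ]
        f <- tryCatch(
          fe_case_features(r$SR, r$cap_thk, r$core_thk, r$E_core, r$E_plaque,
                           h = h, protocol = protocol),
          error = function(e) NULL)
        if (verbose) message(label, " case ", i, "/", nrow(d),
                             if (is.null(f)) " [failed]" else "")
        if (is.null(f)) return(tibble::tibble())
        dplyr::bind_cols(r, dplyr::rename_with(f, ~ paste0("fe_", .x)))
      })
    }
    add_raw <- function(tbl) {
      raw <- purrr::map_dfr(seq_len(nrow(tbl)), function(i)
        surrogate_raw_features(tbl$SR[i], tbl$cap_thk[i], tbl$E_core[i],
                               tbl$E_plaque[i], protocol = protocol))
      dplyr::bind_cols(tbl, dplyr::rename_with(raw, ~ paste0("cyl_", .x)))
    }
    fit_tbl <- add_raw(run_fe(dplyr::bind_rows(fit_a, fit_b), "fit"))
    hold_tbl <- add_raw(run_fe(hold_design, "holdout"))
  } else {
    fit_tbl <- fe_tables$fit
    hold_tbl <- fe_tables$hold
  }

  feats <- c("eps1", "eps2", "eps_core", "eps_cap", "eps_theta")
  Xf <- correction_terms(fit_tbl$SR, fit_tbl$cap_thk, fit_tbl$E_core,
                         fit_tbl$E_plaque)
  # trend + kernel-ridge residual interpolation (Gaussian radial basis
  # on the scaled design coordinates): the log-ratio surface has
  # regime structure a global polynomial cannot track; a smooth
  # interpolator through the designed FE points captures it. The
  # bandwidth is the median pairwise squared distance of the design;
  # the ridge (lambda = 1e-2) absorbs the ~1-2% solver/discretization
  # noise rather than chasing it.
  Cf <- correction_coords(fit_tbl$SR, fit_tbl$cap_thk, fit_tbl$E_core,
                          fit_tbl$E_plaque)
  D2 <- as.matrix(stats::dist(Cf))^2
  ell2 <- stats::median(D2[upper.tri(D2)])
  lambda <- 1e-2
  K <- exp(-D2 / (2 * ell2))
  trend <- list(); alphas <- list()
  for (f in feats) {
    y <- log(abs(fit_tbl[[paste0("fe_", f)]]) / abs(fit_tbl[[paste0("cyl_", f)]]))
    bt <- stats::lm.fit(Xf, y)$coefficients
    r <- y - drop(Xf %*% bt)
    trend[[f]] <- as.list(bt)
    alphas[[f]] <- as.numeric(solve(K + lambda * diag(nrow(K)), r))
  }

  calib <- structure(list(
    coefficients = trend,
    rbf = list(centers = unname(as.matrix(Cf)), ell2 = ell2,
               lambda = lambda, alphas = alphas),
    features = feats,
    protocol = list(end_kPa = protocol$end_kPa, n_inc = protocol$n_inc),
    mesh_h = h, seed = seed,
    n_fit = nrow(fit_tbl), n_holdout = nrow(hold_tbl)
  ), class = "surrogate_calibration")

  # holdout agreement
  pred <- purrr::map_dfr(seq_len(nrow(hold_tbl)), function(i)
    surrogate_forward_params(hold_tbl$SR[i], hold_tbl$cap_thk[i],
                             hold_tbl$E_core[i], hold_tbl$E_plaque[i],
                             calibration = calib, protocol = protocol))
  rel <- purrr::map_dbl(feats, function(f)
    stats::median(abs(pred[[f]] - hold_tbl[[paste0("fe_", f)]]) /
                    abs(hold_tbl[[paste0("fe_", f)]])))
  calib$holdout_rel_err <- setNames(rel, feats)
  calib
}

# one FE solve -> features, for calibration and validation
fe_case_features <- function(SR, cap_thk, core_thk, E_core, E_plaque,
                             h = 0.2, protocol = load_protocol(),
                             geom = NULL) {
  geom <- geom %||% build_idealized(geometry_params(SR = SR, cap_thk = cap_thk,
                                                    core_thk = core_thk))
  mesh <- mesh_geometry(geom, h = h)
  mats <- c(list(core = neo_hookean(E_core), plaque = neo_hookean(E_plaque)),
            table2_materials())
  sol <- solve_inflation(mesh, mats, protocol)
  extract_features(sol, geom)[, c("eps1", "eps2", "eps_core", "eps_cap",
                                  "eps_theta", "SR")]
}

#' Store and load surrogate calibrations
#'
#' @param calib A `surrogate_calibration`.
#' @param path JSON file path. `load_surrogate_calibration()` defaults
#'   to the calibration shipped with the package.
#' @return The calibration object (read) or `path` invisibly (write).
#' @export
write_surrogate_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_surrogate_calibration
#' @export
load_surrogate_calibration <- function(path = NULL) {
  path <- path %||% system.file("extdata", "surrogate_calibration.json",
                                package = "atheromech", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$holdout_rel_err <- unlist(raw$holdout_rel_err)
  if (!is.null(raw$rbf)) {
    raw$rbf$centers <- as.matrix(raw$rbf$centers)
    raw$rbf$alphas <- lapply(raw$rbf$alphas, as.numeric)
  }
  structure(raw, class = "surrogate_calibration")
}

# scaled design coordinates used by the kernel part of the correction
correction_coords <- function(SR, cap_thk, E_core, E_plaque) {
  cbind(s = (SR - 60) / 20,
        c = log(cap_thk / 140) / log(300 / 140),
        e = (log(E_core) - log(10)) / log(10),
        p = (E_plaque - 795) / 405)
}

# correction factor h_i for one feature (trend + kernel residual)
surrogate_correction <- function(calib, feature, SR, cap_thk, E_core, E_plaque) {
  b <- unlist(calib$coefficients[[feature]])
  X <- correction_terms(SR, cap_thk, E_core, E_plaque)
  out <- drop(X[, names(b), drop = FALSE] %*% b)
  if (!is.null(calib$rbf)) {
    ctr <- calib$rbf$centers
    q <- correction_coords(SR, cap_thk, E_core, E_plaque)
    d2 <- outer(rowSums(q^2), rowSums(ctr^2), "+") - 2 * (q %*% t(ctr))
    Kq <- exp(-d2 / (2 * calib$rbf$ell2))
    out <- out + drop(Kq %*% calib$rbf$alphas[[feature]])
  }
  exp(out)
}

# surrogate features for scalar parameter combinations
surrogate_forward_params <- function(SR, cap_thk, E_core, E_plaque,
                                     calibration, protocol = load_protocol(),
                                     shape_mod = NULL) {
  raw <- surrogate_raw_features(SR, cap_thk, E_core, E_plaque,
                                protocol = protocol)
  out <- as.list(raw)
  X <- correction_terms(SR, cap_thk, E_core, E_plaque)
  Kq <- NULL
  if (!is.null(calibration$rbf)) {
    ctr <- calibration$rbf$centers
    q <- correction_coords(SR, cap_thk, E_core, E_plaque)
    d2 <- outer(rowSums(q^2), rowSums(ctr^2), "+") - 2 * (q %*% t(ctr))
    Kq <- exp(-d2 / (2 * calibration$rbf$ell2))
  }
  for (f in calibration$features) {
    b <- unlist(calibration$coefficients[[f]])
    lg <- drop(X[, names(b), drop = FALSE] %*% b)
    if (!is.null(Kq)) lg <- lg + drop(Kq %*% calibration$rbf$alphas[[f]])
    out[[f]] <- raw[[f]] * exp(lg)
  }
  if (!is.null(shape_mod)) {
    out$eps_cap <- out$eps_cap * shape_mod$m_cap
    out$eps_core <- out$eps_core * shape_mod$m_core
    out$eps_theta <- out$eps_theta * shape_mod$m_theta
    out$eps1 <- out$eps1 * shape_mod$m_cap
    out$eps2 <- out$eps2 * shape_mod$m_cap
  }
  out$eps_core_sq <- out$eps_core^2
  out$eps_cap_sq <- out$eps_cap^2
  out$eps_theta_sq <- out$eps_theta^2
  tibble::as_tibble(out)
}

#' Surrogate feature prediction
#'
#' Evaluates the calibrated surrogate feature map for an idealized
#' parameter combination or a built geometry. For perturbed
#' (realistic-family) geometries, deterministic shape-modulation
#' factors derived from the lumen contour's local curvature scale the
#' strain features: a locally flatter (larger curvature radius) cap
#' carries a proportionally larger membrane strain, which is what
#' distinguishes a non-circular lesion from its equivalent cylinder.
#'
#' @param x A [geometry_params()], a `plaque_geometry`, or a data
#'   frame with columns `SR`, `cap_thk` (and optionally `core_thk`).
#' @param E_core,E_plaque Moduli in kPa (vectorized, recycled against
#'   the rows of `x`).
#' @param calibration A `surrogate_calibration`; defaults to the one
#'   shipped with the package.
#' @param protocol Load protocol (must match the calibration's).
#' @return A tibble of features, one row per case.
#' @export
surrogate_forward <- function(x, E_core, E_plaque, calibration = NULL,
                              protocol = load_protocol()) {
  calibration <- calibration %||% load_surrogate_calibration()
  if (inherits(x, "geometry_params")) {
    x <- tibble::tibble(SR = x$SR, cap_thk = x$cap_thk)
  } else if (inherits(x, "plaque_geometry")) {
    x <- tibble::tibble(SR = x$SR, cap_thk = mm_to_um(x$shape$cap),
                        shape_mod = list(shape_modulation(x)))
  }
  n <- max(nrow(x), length(E_core), length(E_plaque))
  tbl <- tibble::tibble(row = seq_len(n))
  SRv <- rep_len(x$SR, n); capv <- rep_len(x$cap_thk, n)
  Ecv <- rep_len(E_core, n); Epv <- rep_len(E_plaque, n)
  mods <- if ("shape_mod" %in% names(x)) rep_len(x$shape_mod, n) else NULL
  if (any(SRv < 40 | SRv > 80) || any(capv < 65 | capv > 300) ||
      any(Ecv < 1 | Ecv > 100) || any(Epv < 390 | Epv > 1200)) {
    rlang::warn("surrogate queried outside its calibrated ranges; extrapolating",
                class = "atheromech_extrapolation")
  }
  purrr::map_dfr(seq_len(n), function(i)
    surrogate_forward_params(SRv[i], capv[i], Ecv[i], Epv[i],
                             calibration = calibration, protocol = protocol,
                             shape_mod = if (is.null(mods)) NULL else mods[[i]]))
}

#' Shape-modulation factors of a perturbed geometry
#'
#' Deterministic factors comparing the local lumen curvature radius at
#' the cap midpoint (and at the opposite axis point) with the radius
#' of the area-equivalent circular lumen; they equal 1 for idealized
#' (circular-lumen) geometries.
#'
#' @param geom A `plaque_geometry`.
#' @return A list with `m_cap`, `m_core`, `m_theta`.
#' @export
shape_modulation <- function(geom) {
  shape <- geom$shape
  r_eq <- sqrt(geom$A_lumen / pi)
  curv_radius <- function(theta0) {
    # polar curve about the lumen center: R = r0/(1 - r''/r0) at an
    # extremum of r(theta) (r' = 0 on the symmetry axis)
    r0 <- shape_radius(shape, "lumen", theta0)
    if (is.null(shape$inner_harm)) return(r0)
    ks <- as.integer(names(shape$inner_harm))
    rpp <- -shape$inner_amp *
      sum(shape$inner_harm * ks^2 * cos(ks * theta0))
    r0 / max(1 - rpp / r0, 0.2)
  }
  Rc0 <- curv_radius(0)
  Rcpi <- curv_radius(pi)
  r0 <- shape_radius(shape, "lumen", 0)
  rpi <- shape_radius(shape, "lumen", pi)
  m_cap <- Rc0 / r0
  list(m_cap = m_cap,
       m_core = sqrt(m_cap),
       m_theta = (Rc0 + Rcpi) / (r0 + rpi))
}

#' @export
print.surrogate_calibration <- function(x, ...) {
  cat("<surrogate_calibration>", x$n_fit, "fit /", x$n_holdout, "holdout FE cases, mesh h =",
      x$mesh_h, "\n")
  if (!is.null(x$holdout_rel_err)) {
    cat("  holdout median relative error:\n")
    print(round(x$holdout_rel_err, 4))
  }
  invisible(x)
}
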
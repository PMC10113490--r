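#' Stenosis ratio from plaque and lumen areas
#'
#' The stenosis ratio quantifies lumen narrowing as the plaque
#' cross-sectional area over the combined plaque-plus-lumen area,
#' \deqn{SR = \frac{A_{plaque}}{A_{plaque} + A_{lumen}} \cdot 100,}
#' where the plaque is the diseased intima (fibrotic tissue plus
#' lipid core).
#'
#' @param A_plaque Plaque cross-sectional area (mm^2), non-negative.
#' @param A_lumen Lumen cross-sectional area (mm^2), strictly positive.
#' @return Stenosis ratio in percent, in `[0, 100)`.
#' @examples
#' compute_stenosis_ratio(7, 3) # 70
#' @export
compute_stenosis_ratio <- function(A_plaque, A_lumen) {
  if (any(A_lumen <= 0)) {
    ath_abort("`A_lumen` must be strictly positive.", "atheromech_invalid_geometry")
  }
  if (any(A_plaque < 0)) {
    ath_abort("`A_plaque` must be non-negative.", "atheromech_invalid_geometry")
  }
  A_plaque / (A_plaque + A_lumen) * 100
}

#' Geometry parameters for an idealized plaque cross-section
#'
#' Bundles and validates the geometric degrees of freedom of the
#' idealized eccentric-plaque model: outer layer diameters, fibrous cap
#' thickness, lipid-core thickness and angular extent, and the target
#' stenosis ratio. The lumen diameter is not free: it is solved from the
#' stenosis ratio during construction (the outer wall stays fixed and
#' the lumen shrinks and shifts away from the core).
#'
#' @param SR Target stenosis ratio (percent), in `[40, 80]`.
#' @param cap_thk Fibrous cap thickness (micrometres), in `[65, 300]`.
#' @param core_thk Lipid-core radial thickness (micrometres), in `[300, 800]`.
#' @param alpha_lipid Angular extent of the lipid core (degrees).
#' @param phi_int,phi_med,phi_adv Outer diameters of the intima, media
#'   and adventitia boundaries (mm).
#' @param phi_lum Nominal (healthy reference) lumen diameter (mm); kept
#'   for provenance, the effective lumen diameter follows from `SR`.
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(SR = 70, cap_thk = 65, core_thk = 500,
                            alpha_lipid = 60,
                            phi_lum = 3.6, phi_int = 5.596,
                            phi_med = 6.05, phi_adv = 6.5) {
  if (!(phi_lum < phi_int && phi_int < phi_med && phi_med < phi_adv)) {
    ath_abort("Layer diameters must be strictly nested: phi_lum < phi_int < phi_med < phi_adv.",
              "atheromech_invalid_geometry")
  }
  if (cap_thk < 65 || cap_thk > 300) {
    ath_abort("`cap_thk` must lie in [65, 300] micrometres.", "atheromech_invalid_geometry")
  }
  if (core_thk < 300 || core_thk > 800) {
    ath_abort("`core_thk` must lie in [300, 800] micrometres.", "atheromech_invalid_geometry")
  }
  if (SR < 0 || SR >= 100) {
    ath_abort("`SR` must lie in [0, 100).", "atheromech_invalid_geometry")
  }
  structure(
    list(SR = SR, cap_thk = cap_thk, core_thk = core_thk,
         alpha_lipid = alpha_lipid, phi_lum = phi_lum, phi_int = phi_int,
         phi_med = phi_med, phi_adv = phi_adv),
    class = "geometry_params"
  )
}

# --- internal shape machinery -----------------------------------------------
#
# Every region boundary is parameterized as a radius-from-lumen-center
# function rho_b(theta), theta in [-pi, pi], symmetric about the x axis.
# The lipid core sits on the +x side; its inner boundary is concentric
# with the lumen at distance cap_thk, its thickness tapers smoothly
# (cosine rolloff) to zero at +/- alpha_lipid/2, giving rounded ends.

# smooth thickness profile of the core band, s(theta) in [0, 1]
core_taper <- function(theta, alpha_rad, taper_frac = 0.35) {
  th_end <- alpha_rad / 2
  th_full <- th_end * (1 - taper_frac)
  a <- abs(theta)
  s <- numeric(length(theta))
  s[a <= th_full] <- 1
  mid <- a > th_full & a < th_end
  s[mid] <- 0.5 * (1 + cos(pi * (a[mid] - th_full) / (th_end - th_full)))
  s
}

# harmonic perturbation profile: sum_k c_k cos(k theta), normalized so
# that max |.| = 1 (cos-only keeps the shape mirror-symmetric so the
# half-model analysis remains valid)
harmonic_profile <- function(theta, coefs) {
  if (is.null(coefs) || length(coefs) == 0) return(numeric(length(theta)))
  ks <- as.integer(names(coefs) %||% seq(2, length.out = length(coefs)))
  v <- numeric(length(theta))
  for (i in seq_along(coefs)) v <- v + coefs[i] * cos(ks[i] * theta)
  v
}

# distance from the (offset) lumen center to a circle of radius R
# centered at the origin, along the ray at angle theta
ray_to_circle <- function(theta, xc, R) {
  -xc * cos(theta) + sqrt(R^2 - (xc * sin(theta))^2)
}

# Radius functions for every boundary of a plaque shape.
# shape: list(xc, r_lum, R_int, R_med, R_adv, cap, core, alpha_rad,
#             taper_frac, inner_harm, inner_amp, outer_harm, outer_amp)
# inner_amp / outer_amp are absolute radial amplitudes in mm.
shape_radius <- function(shape, boundary, theta) {
  di <- if (is.null(shape$inner_harm)) 0 else
    shape$inner_amp * harmonic_profile(theta, shape$inner_harm)
  do <- if (is.null(shape$outer_harm)) 0 else
    shape$outer_amp * harmonic_profile(theta, shape$outer_harm)
  switch(boundary,
    lumen   = shape$r_lum + di,
    core_in = shape$r_lum + di + shape$cap,
    core_out = shape$r_lum + di + shape$cap +
      shape$core * core_taper(theta, shape$alpha_rad, shape$taper_frac),
    intima  = ray_to_circle(theta, shape$xc, shape$R_int) + do,
    media   = ray_to_circle(theta, shape$xc, shape$R_med) + do,
    adventitia = ray_to_circle(theta, shape$xc, shape$R_adv) + do,
    ath_abort(paste0("unknown boundary '", boundary, "'"), "atheromech_internal")
  )
}

# polygon contour of one boundary in global coordinates
shape_contour <- function(shape, boundary, n = 256) {
  if (boundary == "core") {
    th_end <- shape$alpha_rad / 2
    th <- seq(-th_end, th_end, length.out = n)
    ro <- shape_radius(shape, "core_out", th)
    ri <- shape_radius(shape, "core_in", rev(th))
    tibble::tibble(
      region = "core",
      x = shape$xc + c(ro * cos(th), ri * cos(rev(th))),
      y = c(ro * sin(th), ri * sin(rev(th)))
    )
  } else {
    th <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
    r <- shape_radius(shape, boundary, th)
    tibble::tibble(region = boundary,
                   x = shape$xc + r * cos(th), y = r * sin(th))
  }
}

# areas of lumen and plaque (intima region minus lumen) for a shape
shape_areas <- function(shape, n = 720) {
  lum <- shape_contour(shape, "lumen", n)
  int <- shape_contour(shape, "intima", n)
  A_lumen <- abs(polygon_area(lum$x, lum$y))
  A_int <- abs(polygon_area(int$x, int$y))
  list(A_lumen = A_lumen, A_plaque = A_int - A_lumen)
}

# Eccentric placement rule: keep a healthy thin-side wall of t_thin
# (0.25 mm when space allows, floor 0.08 mm) and put the core-side
# bulk on +x. The wall reservation uses the study's core-thickness
# ceiling (0.8 mm), not the actual core, so the lumen layout — and
# with it every deformation feature — depends only on the stenosis
# ratio and cap thickness, never on the core thickness; the actual
# core always fits inside the reserved space. Fails constructively
# when cap + reserved core + clearance cannot fit.
CORE_THK_CEILING <- 0.8 # mm, upper end of the study's core range

place_lumen <- function(r_lum, R_int, cap, core) {
  g_needed <- cap + CORE_THK_CEILING + 0.05
  t_thin <- min(0.25, 2 * (R_int - r_lum) - g_needed)
  if (t_thin < 0.08) {
    ath_abort(sprintf(paste0(
      "infeasible geometry: cap (%.3f mm) + reserved core (%.3f mm) + clearance do not fit ",
      "in the wall at this stenosis ratio (available %.3f mm, healthy-side floor 0.08 mm)"),
      cap, CORE_THK_CEILING, 2 * (R_int - r_lum)), "atheromech_constructive_failure")
  }
  r_lum + t_thin - R_int # lumen center x offset (toward -x)
}

# healthy-side wall thickness implied by the placement rule, as a
# function of stenosis ratio and cap thickness only (used by the
# surrogate's correction model)
thin_wall_of <- function(SR, cap_thk, phi_int = 5.596) {
  R_int <- phi_int / 2
  r <- R_int * sqrt(1 - SR / 100)
  pmin(0.25, 2 * (R_int - r) - (um_to_mm(cap_thk) + CORE_THK_CEILING + 0.05))
}

#' Build an idealized 2D plaque cross-section
#'
#' Constructs the five nested region boundaries (lumen, lipid core,
#' intima, media, adventitia) of an eccentric idealized plaque. The
#' outer wall stays at the prescribed diameters; the lumen diameter and
#' offset are solved by bisection so that the polygon-recomputed
#' stenosis ratio matches the request to within 0.5 percentage points.
#' The lipid core is a circumferential band concentric with the lumen
#' at distance `cap_thk`, with cosine-rounded angular ends.
#'
#' @param params A [geometry_params()] object.
#' @param n_contour Number of vertices per emitted boundary contour.
#' @return An object of class `plaque_geometry`: contours (tibble with
#'   `region`, `x`, `y`), derived areas `A_plaque`/`A_lumen`, the
#'   achieved `SR`, and the internal shape description used for meshing.
#' @examples
#' geom <- build_idealized(geometry_params(SR = 70, cap_thk = 65, core_thk = 500))
#' geom$SR
#' @export
build_idealized <- function(params, n_contour = 256) {
  stopifnot(inherits(params, "geometry_params"))
  R_int <- params$phi_int / 2
  cap <- um_to_mm(params$cap_thk)
  core <- um_to_mm(params$core_thk)

  make_shape <- function(r_lum) {
    list(
      kind = "idealized", r_lum = r_lum,
      xc = place_lumen(r_lum, R_int, cap, core),
      R_int = R_int, R_med = params$phi_med / 2, R_adv = params$phi_adv / 2,
      cap = cap, core = core, alpha_rad = params$alpha_lipid * pi / 180,
      taper_frac = 0.35,
      inner_harm = NULL, inner_amp = 0, outer_harm = NULL, outer_amp = 0
    )
  }
  sr_of <- function(r_lum) {
    a <- shape_areas(make_shape(r_lum))
    compute_stenosis_ratio(a$A_plaque, a$A_lumen)
  }
  # SR decreases monotonically in lumen radius; bracket and bisect
  # inside the feasible radius range of the eccentric placement rule
  r_lum <- solve_lumen_radius(sr_of, params$SR, R_int, cap, core)
  shape <- make_shape(r_lum)
  finalize_geometry(shape, params, n_contour)
}

# invert SR(r_lum) over the feasible lumen-radius range
solve_lumen_radius <- function(sr_of, SR_target, R_int, cap, core) {
  r_max <- R_int - (cap + CORE_THK_CEILING + 0.05 + 0.08) / 2 - 1e-6
  r_min <- 0.3
  if (r_max <= r_min) {
    ath_abort(sprintf(
      "infeasible geometry: cap (%.3f mm) + core (%.3f mm) leave no feasible lumen radius",
      cap, core), "atheromech_constructive_failure")
  }
  sr_lo <- sr_of(r_max) # smallest achievable SR
  sr_hi <- sr_of(r_min)
  if (SR_target < sr_lo || SR_target > sr_hi) {
    ath_abort(sprintf(
      "infeasible geometry: requested SR %.1f%% outside achievable range [%.1f, %.1f]%% for cap %.3f mm + core %.3f mm",
      SR_target, sr_lo, sr_hi, cap, core), "atheromech_constructive_failure")
  }
  uniroot(function(r) sr_of(r) - SR_target, c(r_min, r_max), tol = 1e-6)$root
}

# assemble, validate, and class a plaque_geometry from a shape
finalize_geometry <- function(shape, params, n_contour = 256) {
  areas <- shape_areas(shape)
  SR <- compute_stenosis_ratio(areas$A_plaque, areas$A_lumen)

  boundaries <- c("lumen", "core", "intima", "media", "adventitia")
  contours <- dplyr::bind_rows(lapply(boundaries, function(b)
    shape_contour(shape, b, n_contour)))

  geom <- structure(
    list(params = params, shape = shape, contours = contours,
         A_lumen = areas$A_lumen, A_plaque = areas$A_plaque, SR = SR,
         half_model = TRUE),
    class = "plaque_geometry"
  )
  validate_geometry(geom)
  geom
}

#' Validate a plaque geometry
#'
#' Checks boundary nesting and positivity along rays, the
#' lumen-to-core distance against the requested cap thickness, and the
#' recomputed stenosis ratio against the request (0.5 percentage
#' points). Called by the builders; exported for use on user-supplied
#' geometries.
#'
#' @param geom A `plaque_geometry`.
#' @param sr_tol Allowed deviation of recomputed SR from the requested
#'   target, percentage points.
#' @return `geom`, invisibly.
#' @export
validate_geometry <- function(geom, sr_tol = 0.5) {
  stopifnot(inherits(geom, "plaque_geometry"))
  shape <- geom$shape
  th <- seq(-pi, pi, length.out = 361)
  rl <- shape_radius(shape, "lumen", th)
  ri <- shape_radius(shape, "intima", th)
  rm <- shape_radius(shape, "media", th)
  ra <- shape_radius(shape, "adventitia", th)
  if (any(rl <= 0)) {
    ath_abort("lumen boundary radius must stay positive", "atheromech_invalid_geometry")
  }
  if (any(rl >= ri) || any(ri >= rm) || any(rm >= ra)) {
    ath_abort("boundaries must be strictly nested (lumen < intima < media < adventitia)",
              "atheromech_invalid_geometry")
  }
  # core containment only matters over the core's angular extent
  in_core <- abs(th) <= shape$alpha_rad / 2
  rco <- shape_radius(shape, "core_out", th[in_core])
  if (any(rco >= ri[in_core])) {
    ath_abort("lipid core must stay inside the intima boundary",
              "atheromech_invalid_geometry")
  }
  # cap check: min distance between lumen and core contours
  lum <- shape_contour(shape, "lumen", 256)
  cor <- shape_contour(shape, "core", 256)
  dmin <- min_polyline_distance(lum$x, lum$y, cor$x, cor$y)
  if (abs(dmin - shape$cap) > max(0.05 * shape$cap, 5e-4)) {
    ath_abort(sprintf("minimum lumen-core distance %.4f mm does not match cap thickness %.4f mm",
                      dmin, shape$cap), "atheromech_invalid_geometry")
  }
  if (!is.null(geom$params$SR) && abs(geom$SR - geom$params$SR) > sr_tol) {
    ath_abort(sprintf("recomputed SR %.2f%% deviates from requested %.2f%% by more than %.1f pp",
                      geom$SR, geom$params$SR, sr_tol), "atheromech_invalid_geometry")
  }
  invisible(geom)
}

#' Enumerate the idealized geometry grid
#'
#' Full factorial grid over stenosis ratio (40-80%, step 5), fibrous
#' cap thickness (10 log-spaced values on 65-300 um, denser in the
#' vulnerable thin-cap regime) and lipid-core thickness (6 equally
#' spaced values on 300-800 um): 540 parameter combinations.
#'
#' @return A tibble with columns `SR`, `cap_thk`, `core_thk`, one row
#'   per geometry.
#' @export
enumerate_idealized_grid <- function() {
  tidyr::expand_grid(
    SR = seq(40, 80, by = 5),
    cap_thk = log_seq(65, 300, 10),
    core_thk = seq(300, 800, length.out = 6)
  )
}

#' Enumerate the material grid
#'
#' Young's moduli of the lipid core are log-spaced on 1-100 kPa
#' (denser near the soft end); moduli of the fibrotic tissue are
#' arithmetic on 390-1200 kPa (step 90 at the default count).
#'
#' @param n_core Number of core modulus values (default 300).
#' @param n_plaque Number of fibrotic tissue modulus values (default 10).
#' @return A list of class `material_grid` with numeric vectors
#'   `E_core` and `E_plaque` (kPa).
#' @export
enumerate_material_grid <- function(n_core = 300, n_plaque = 10) {
  stopifnot(n_core >= 2, n_plaque >= 2)
  structure(
    list(E_core = log_seq(1, 100, n_core),
         E_plaque = seq(390, 1200, length.out = n_plaque)),
    class = "material_grid"
  )
}

#' Generate a synthetic realistic plaque family
#'
#' Stands in for patient-derived (IVUS-segmented) cross-sections, which
#' are not distributed with the package: starting from an idealized
#' base, all boundaries receive smooth low-order cosine-harmonic
#' perturbations (seeded; amplitude bounded by 15% of the local wall
#' thickness) producing non-circular lumen and wall contours. The
#' perturbed base is replicated at `n_cap` cap thicknesses spanning
#' 65-300 um and crossed with a material grid.
#'
#' @param base_params [geometry_params()] of the underlying idealized
#'   base (default: the 70% stenosis base with a 500 um core).
#' @param n_cap Number of cap-thickness variants (default 20).
#' @param material_grid A [enumerate_material_grid()] object; default
#'   50 log-spaced core moduli x 10 fibrotic moduli (500 combinations).
#' @param seed Integer seed controlling the harmonic perturbation.
#' @param amp_frac Peak perturbation amplitude as a fraction of the
#'   local wall thickness (default 0.15).
#' @param max_retries Resampling attempts when a draw violates nesting.
#' @return A list of class `realistic_family`: `geometries` (list of
#'   `plaque_geometry`, one per cap variant), and `cases`, a tibble
#'   crossing the variants with the material grid (`case_id`,
#'   `geometry_id`, `cap_thk`, `SR`, `E_core`, `E_plaque`).
#' @export
generate_realistic_family <- function(base_params = NULL, n_cap = 20,
                                      material_grid = NULL, seed = 1L,
                                      amp_frac = 0.15, max_retries = 20) {
  stopifnot(n_cap >= 1)
  base_params <- base_params %||% geometry_params(SR = 70, core_thk = 500)
  material_grid <- material_grid %||% enumerate_material_grid(n_core = 50, n_plaque = 10)

  cap_grid <- if (n_cap == 1) 65 else log_seq(65, 300, n_cap)
  set.seed(seed)
  draw_harm <- function() {
    c_in <- runif(3, -1, 1); c_out <- runif(3, -1, 1)
    list(inner = setNames(c_in / sum(abs(c_in)), 2:4),
         outer = setNames(c_out / sum(abs(c_out)), 2:4))
  }

  geometries <- vector("list", n_cap)
  harm <- NULL # found with the first variant, shared by the rest
  for (j in seq_len(n_cap)) {
    params <- geometry_params(SR = base_params$SR, cap_thk = cap_grid[j],
                              core_thk = base_params$core_thk,
                              alpha_lipid = base_params$alpha_lipid,
                              phi_lum = base_params$phi_lum,
                              phi_int = base_params$phi_int,
                              phi_med = base_params$phi_med,
                              phi_adv = base_params$phi_adv)
    built <- build_realistic_one(params, draw_harm, amp_frac, max_retries,
                                 reuse_harm = harm)
    harm <- built$harm
    geometries[[j]] <- built$geom
  }

  cases <- tidyr::expand_grid(
    geometry_id = seq_len(n_cap),
    E_core = material_grid$E_core,
    E_plaque = material_grid$E_plaque
  ) |>
    dplyr::mutate(
      cap_thk = cap_grid[.data$geometry_id],
      SR = purrr::map_dbl(.data$geometry_id, function(i) geometries[[i]]$SR),
      case_id = sprintf("R%05d", dplyr::row_number())
    ) |>
    dplyr::select("case_id", "geometry_id", "cap_thk", "SR", "E_core", "E_plaque")

  structure(list(geometries = geometries, cases = cases,
                 seed = seed, amp_frac = amp_frac, cap_grid = cap_grid),
            class = "realistic_family")
}

# Build one perturbed geometry; all cap variants share the harmonic
# draw found for the first so the family is one "patient" at many cap
# states. The perturbation amplitude is anchored to the unperturbed
# solution: 15% of the thin-side (healthy) wall for the inner
# boundaries, 15% of the media layer thickness for the outer ones.
build_realistic_one <- function(params, draw_harm, amp_frac, max_retries, reuse_harm) {
  R_int <- params$phi_int / 2
  cap <- um_to_mm(params$cap_thk)
  core <- um_to_mm(params$core_thk)

  # unperturbed lumen radius for this cap variant anchors the amplitude
  base <- build_idealized(params)
  t_thin <- R_int - (base$shape$r_lum - base$shape$xc)
  inner_amp <- amp_frac * t_thin
  outer_amp <- amp_frac * (params$phi_med - params$phi_int) / 2

  make_shape <- function(r_lum, h) {
    list(kind = "realistic", r_lum = r_lum,
         xc = place_lumen(r_lum, R_int, cap, core),
         R_int = R_int, R_med = params$phi_med / 2, R_adv = params$phi_adv / 2,
         cap = cap, core = core, alpha_rad = params$alpha_lipid * pi / 180,
         taper_frac = 0.35,
         inner_harm = h$inner, inner_amp = inner_amp,
         outer_harm = h$outer, outer_amp = outer_amp)
  }

  for (attempt in seq_len(max_retries)) {
    h <- reuse_harm %||% draw_harm()
    sr_of <- function(r) {
      a <- shape_areas(make_shape(r, h))
      compute_stenosis_ratio(a$A_plaque, a$A_lumen)
    }
    geom <- tryCatch({
      r_lum <- solve_lumen_radius(sr_of, params$SR, R_int, cap, core)
      finalize_geometry(make_shape(r_lum, h), params)
    }, atheromech_invalid_geometry = function(e) NULL,
       atheromech_constructive_failure = function(e) NULL)
    if (!is.null(geom)) return(list(geom = geom, harm = h))
    if (!is.null(reuse_harm)) break # a shared shape cannot be resampled
  }
  ath_abort(sprintf("could not generate a valid perturbed geometry after %d attempts",
                    max_retries), "atheromech_constructive_failure")
}

#' Read and write geometry contours as CSV polylines
#'
#' Contours are exchanged as plain CSV with columns `region`, `x`, `y`
#' (mm), one closed polyline per region in row order.
#'
#' @param geom A `plaque_geometry`.
#' @param path File path.
#' @return `write_contours()` returns `path` invisibly;
#'   `read_contours()` returns a tibble.
#' @export
write_contours <- function(geom, path) {
  stopifnot(inherits(geom, "plaque_geometry"))
  readr::write_csv(geom$contours, path)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    x = readr::col_double(), y = readr::col_double()
  ))
}

#' @export
print.plaque_geometry <- function(x, ...) {
  cat("<plaque_geometry>", x$shape$kind, "\n")
  cat(sprintf("  SR %.1f%%  cap %.0f um  core %.0f um  lumen r %.3f mm (offset %.3f mm)\n",
              x$SR, mm_to_um(x$shape$cap), mm_to_um(x$shape$core),
              x$shape$r_lum, x$shape$xc))
  cat(sprintf("  A_lumen %.3f mm^2  A_plaque %.3f mm^2\n", x$A_lumen, x$A_plaque))
  invisible(x)
}
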
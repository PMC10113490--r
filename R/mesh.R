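#' Mesh a plaque cross-section
#'
#' Boundary-conforming structured triangulation of the half-model
#' (y >= 0). Nodes lie on rays from the lumen center at `n_theta + 1`
#' angles covering `[0, pi]` (theta = 0 is the +x axis through the cap
#' midpoint) and on radial stations subdividing five bands: an inner
#' fibrotic band whose outer interface coincides with the cap/core
#' interface over the core's angular extent, the core band, the outer
#' fibrotic band, the media and the adventitia. Quads are split into
#' triangle pairs with alternating diagonals; each pair is recorded as
#' a patch for selective (patch-averaged) volumetric integration.
#'
#' Outside the lipid core's angular extent the core band degenerates;
#' there it is kept open as a thin fibrotic-tissue sliver (labelled
#' `plaque`) so the grid stays structured. The cap is always resolved
#' by at least two element rows through its thickness.
#'
#' @param geom A `plaque_geometry` from [build_idealized()] or
#'   [generate_realistic_family()].
#' @param h Target element edge length (mm).
#' @return An object of class `ath_mesh`: `nodes` (n x 2 reference
#'   coordinates, mm), `tri` (ne x 3 counter-clockwise connectivity),
#'   `region` (per-element label), `quad` (volumetric patch id),
#'   boundary node sets, and the feature-measurement node indices.
#' @export
mesh_geometry <- function(geom, h = 0.2) {
  stopifnot(inherits(geom, "plaque_geometry"), h > 0)
  shape <- geom$shape
  th_end <- shape$alpha_rad / 2
  th_blend <- min(th_end + pi / 6, pi)

  # cap-interface blending weight: 1 inside the core extent, cosine
  # rolloff to 0 beyond it (interface becomes a fixed wall fraction)
  wfun <- function(th) {
    a <- abs(th)
    w <- numeric(length(th))
    w[a <= th_end] <- 1
    mid <- a > th_end & a < th_blend
    w[mid] <- 0.5 * (1 + cos(pi * (a[mid] - th_end) / (th_blend - th_end)))
    w
  }

  interfaces <- function(th) {
    r1 <- shape_radius(shape, "lumen", th)
    ri <- shape_radius(shape, "intima", th)
    rm <- shape_radius(shape, "media", th)
    ra <- shape_radius(shape, "adventitia", th)
    w <- wfun(th)
    r2 <- r1 + w * shape$cap + (1 - w) * 0.35 * (ri - r1)
    t_core <- shape$core * core_taper(th, shape$alpha_rad, shape$taper_frac)
    t_floor <- 0.10 * (ri - r2)
    r3 <- r2 + pmax(t_core, t_floor)
    cbind(r1, r2, r3, ri, rm, ra)
  }

  # Graded ray distribution: the core sector (plus margin) carries a
  # denser share of rays than its angular fraction (soft-inclusion
  # response, cap/core feature nodes), and the outer sector clusters
  # toward the far axis point where the opposite lumen-diameter node
  # sits; both axis ends are therefore well resolved.
  n_theta <- max(40L, min(240L, as.integer(ceiling(pi * 2.6 / h))))
  th_b <- min(th_end + pi / 12, pi / 2)
  n_in <- max(10L, as.integer(ceiling(0.35 * n_theta)))
  n_out <- n_theta - n_in
  s <- seq(0, 1, length.out = n_out + 1)[-1]
  th <- c(seq(0, th_b, length.out = n_in + 1),
          th_b + (pi - th_b) * sin(s * pi / 2))
  th[length(th)] <- pi
  R <- interfaces(th) # (n_theta+1) x 6

  # Ring counts per band are fixed relative to the reference edge
  # length (0.2 mm) rather than derived from each geometry's band
  # thicknesses: every cross-section of a family then shares one mesh
  # topology, so discretization bias varies smoothly with the
  # geometry parameters instead of jumping whenever a band gains a
  # ring. The cap and core bands carry higher ring counts because the
  # thickness-change features are measured across them.
  scale <- 0.2 / h
  nb <- pmax(c(3L, 5L, 10L, 3L, 3L),
             as.integer(ceiling(c(3, 5, 10, 3, 3) * scale)))
  band_region <- c("plaque", "core", "plaque", "media", "adventitia")

  # radial stations (fractions within each band, interfaces shared)
  stations <- list()
  for (b in 1:5) {
    fr <- seq(0, 1, length.out = nb[b] + 1)
    if (b > 1) fr <- fr[-1]
    stations[[b]] <- cbind(band = b, frac = fr)
  }
  st <- do.call(rbind, stations)
  K <- nrow(st) # stations per ray

  # node coordinates
  nn <- (n_theta + 1) * K
  node_id <- function(j, k) (j - 1L) * K + k # j in 1..n_theta+1
  xs <- numeric(nn); ys <- numeric(nn)
  for (j in seq_len(n_theta + 1)) {
    rin <- R[j, st[, "band"]]
    rout <- R[j, st[, "band"] + 1]
    r <- rin + st[, "frac"] * (rout - rin)
    xs[node_id(j, 1:K)] <- shape$xc + r * cos(th[j])
    ys[node_id(j, 1:K)] <- r * sin(th[j])
  }
  # exact symmetry plane
  ys[node_id(1, 1:K)] <- 0
  ys[node_id(n_theta + 1, 1:K)] <- 0

  # elements: quads (j, k)-(j+1, k)-(j+1, k+1)-(j, k+1), CCW in theta
  tri <- matrix(0L, nrow = 2 * n_theta * (K - 1), ncol = 3)
  region <- character(nrow(tri))
  quad <- integer(nrow(tri))
  th_mid <- (th[-1] + th[-(n_theta + 1)]) / 2
  t_core_mid <- shape$core * core_taper(th_mid, shape$alpha_rad, shape$taper_frac)
  Rmid <- interfaces(th_mid)
  core_ok <- t_core_mid >= 0.10 * (Rmid[, 4] - Rmid[, 2]) # sliver test

  e <- 0L; q <- 0L
  for (j in seq_len(n_theta)) {
    for (k in seq_len(K - 1)) {
      q <- q + 1L
      a <- node_id(j, k); b <- node_id(j + 1, k)
      cc <- node_id(j + 1, k + 1); d <- node_id(j, k + 1)
      if ((j + k) %% 2 == 0) {
        tri[e + 1L, ] <- c(a, b, cc); tri[e + 2L, ] <- c(a, cc, d)
      } else {
        tri[e + 1L, ] <- c(a, b, d); tri[e + 2L, ] <- c(b, cc, d)
      }
      bnd <- st[k + 1, "band"]
      reg <- band_region[bnd]
      if (reg == "core" && !core_ok[j]) reg <- "plaque"
      region[e + 1:2] <- reg
      quad[e + 1:2] <- q
      e <- e + 2L
    }
  }

  nodes <- cbind(x = xs, y = ys)
  # orientation check (theta increases CCW, radius outward: triangles CCW)
  a1 <- tri_areas(nodes, tri)
  if (any(a1 <= 0)) {
    tri[a1 <= 0, c(2, 3)] <- tri[a1 <= 0, c(3, 2)]
  }

  structure(list(
    nodes = nodes, tri = tri, region = region, quad = quad,
    lumen_chain = node_id(seq_len(n_theta + 1), 1L),
    symmetry_nodes = c(node_id(1, 1:K), node_id(n_theta + 1, 1:K)),
    outer_nodes = node_id(seq_len(n_theta + 1), K),
    anchor_node = node_id(n_theta + 1, K), # outer wall on the -x axis
    feature_nodes = list(
      lumen_cap = node_id(1, 1L),                    # lumen wall at cap midpoint
      lumen_opp = node_id(n_theta + 1, 1L),          # lumen wall opposite
      core_in = node_id(1, 1L + nb[1]),              # cap/core interface on axis
      core_out = node_id(1, 1L + nb[1] + nb[2])      # core outer on axis
    ),
    n_theta = n_theta, rings = nb, h = h, geom_kind = shape$kind
  ), class = "ath_mesh")
}

#' Mesh a concentric layered ring
#'
#' Convenience mesher for verification against the closed-form
#' cylinder: concentric annular layers, no core, half-model.
#'
#' @param layers Data frame with `r_in`, `r_out` and a `region` name
#'   column (regions index into the material assignment).
#' @param h Target element edge length (mm).
#' @return An `ath_mesh`; feature nodes refer to the innermost ring.
#' @export
mesh_ring <- function(layers, h = 0.2) {
  layers <- as.data.frame(layers)
  stopifnot(all(c("r_in", "r_out") %in% names(layers)))
  if (is.null(layers$region)) layers$region <- paste0("layer", seq_len(nrow(layers)))
  n_theta <- max(16L, min(200L, as.integer(ceiling(pi * mean(layers$r_in[1]) / h))))
  th <- seq(0, pi, length.out = n_theta + 1)
  nb <- pmax(2L, pmin(30L, as.integer(ceiling((layers$r_out - layers$r_in) / h))))

  stations <- list()
  for (b in seq_len(nrow(layers))) {
    fr <- seq(0, 1, length.out = nb[b] + 1)
    if (b > 1) fr <- fr[-1]
    stations[[b]] <- cbind(band = b, frac = fr)
  }
  st <- do.call(rbind, stations)
  K <- nrow(st)
  node_id <- function(j, k) (j - 1L) * K + k
  nn <- (n_theta + 1) * K
  r <- layers$r_in[st[, "band"]] + st[, "frac"] *
    (layers$r_out[st[, "band"]] - layers$r_in[st[, "band"]])
  xs <- numeric(nn); ys <- numeric(nn)
  for (j in seq_len(n_theta + 1)) {
    xs[node_id(j, 1:K)] <- r * cos(th[j])
    ys[node_id(j, 1:K)] <- r * sin(th[j])
  }
  ys[node_id(1, 1:K)] <- 0
  ys[node_id(n_theta + 1, 1:K)] <- 0

  tri <- matrix(0L, nrow = 2 * n_theta * (K - 1), ncol = 3)
  region <- character(nrow(tri))
  quad <- integer(nrow(tri))
  e <- 0L; q <- 0L
  for (j in seq_len(n_theta)) {
    for (k in seq_len(K - 1)) {
      q <- q + 1L
      a <- node_id(j, k); b <- node_id(j + 1, k)
      cc <- node_id(j + 1, k + 1); d <- node_id(j, k + 1)
      if ((j + k) %% 2 == 0) {
        tri[e + 1L, ] <- c(a, b, cc); tri[e + 2L, ] <- c(a, cc, d)
      } else {
        tri[e + 1L, ] <- c(a, b, d); tri[e + 2L, ] <- c(b, cc, d)
      }
      region[e + 1:2] <- layers$region[st[k + 1, "band"]]
      quad[e + 1:2] <- q
      e <- e + 2L
    }
  }
  nodes <- cbind(x = xs, y = ys)
  a1 <- tri_areas(nodes, tri)
  if (any(a1 <= 0)) tri[a1 <= 0, c(2, 3)] <- tri[a1 <= 0, c(3, 2)]

  structure(list(
    nodes = nodes, tri = tri, region = region, quad = quad,
    lumen_chain = node_id(seq_len(n_theta + 1), 1L),
    symmetry_nodes = c(node_id(1, 1:K), node_id(n_theta + 1, 1:K)),
    outer_nodes = node_id(seq_len(n_theta + 1), K),
    anchor_node = node_id(n_theta + 1, K),
    feature_nodes = list(lumen_cap = node_id(1, 1L),
                         lumen_opp = node_id(n_theta + 1, 1L),
                         core_in = NA_integer_, core_out = NA_integer_),
    n_theta = n_theta, rings = nb, h = h, geom_kind = "ring"
  ), class = "ath_mesh")
}

# signed areas of all triangles
tri_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' @export
print.ath_mesh <- function(x, ...) {
  cat("<ath_mesh>", nrow(x$nodes), "nodes,", nrow(x$tri), "triangles;",
      "regions:", paste(names(table(x$region)), table(x$region), collapse = ", "), "\n")
  invisible(x)
}

#' Export a mesh (and optional nodal field) as legacy VTK
#'
#' @param mesh An `ath_mesh`.
#' @param path Output file (`.vtk`, ASCII legacy format).
#' @param displacement Optional n x 2 nodal displacement to attach as
#'   a point vector field.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atheromech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 4 * ne), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("5", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (!is.null(displacement)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.9g %.9g 0", displacement[, 1], displacement[, 2]), con)
  }
  invisible(path)
}
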
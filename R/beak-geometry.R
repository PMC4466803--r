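#' @importFrom stats quantile sd cor.test pt runif rnorm
#' @importFrom utils read.csv write.csv
NULL

# Internal constants of the parametric beak idealization. The upper beak is a
# superelliptical cross-section lofted along a curved axis with power-law
# taper; the section is split into a dorsal and a ventral half so that the
# thick ventral (palatal) keratin of crushing beaks fits inside the section.
.beak_const <- list(
  dorsal_frac  = 0.4,   # dorsal share of total section depth
  ventral_frac = 0.6,   # ventral share (palatal keratin lives here)
  profile_min  = 0.08,  # taper profile floor: keeps a small open tip, no slivers
  ker_cap      = 0.75,  # keratin thickness cap as fraction of local radius
  wall_cap     = 0.50,  # bone wall cap as fraction of radius under the keratin
  hinge_band   = c(0.05, 0.15), # axial extent of the nasal-hinge thinning
  hinge_relief = 0.55,  # fractional bone-wall reduction at the hinge crest
  core_end     = 0.88   # axial fraction where the bony core ends (tip is keratin)
)

# Functional-group shape defaults: per-group means and SDs of the four
# published ratios (keratin thickness and beak dimensions relative to beak
# length), plus a curvature default (tip drop / length; tip biters carry the
# strongest decurvature, probers intermediate).
.shape_groups <- data.frame(
  group      = c("crush", "probe_and_base", "probe", "tip"),
  n          = c(3, 3, 2, 5),
  ker_bottom = c(0.095, 0.067, 0.029, 0.08),
  ker_bottom_sd = c(0.015, 0.007, 0.005, 0.03),
  ker_top    = c(0.023, 0.0205, 0.018, 0.035),
  ker_top_sd = c(0.005, 0.0013, 0.007, 0.011),
  depth      = c(0.22, 0.161, 0.120, 0.22),
  depth_sd   = c(0.03, 0.013, 0.006, 0.05),
  width      = c(0.406, 0.35, 0.304, 0.44),
  width_sd   = c(0.010, 0.02, 0.003, 0.07),
  curvature  = c(0.10, 0.14, 0.18, 0.22),
  stringsAsFactors = FALSE
)

# Species membership of the four functional groups.
.group_species <- list(
  crush          = c("G_fortis", "G_fuliginosa", "G_magnirostris"),
  probe_and_base = c("G_scandens", "G_difficilis", "G_conirostris"),
  probe          = c("C_olivacea", "P_inornata"),
  tip            = c("C_parvulus", "C_pauper", "C_psittacula", "C_pallida",
                     "P_crassirostris")
)

#' Functional beak groups
#'
#' @return Character vector of the four functional beak types, in the
#'   conventional order: crushing beaks, probe-and-base beaks, probing beaks,
#'   tip-biting beaks.
#' @export
beak_groups <- function() .shape_groups$group

#' Species-to-group assignment
#'
#' @return Named character vector mapping each of the 13 finch species to its
#'   functional beak group.
#' @export
species_groups <- function() {
  out <- rep(names(.group_species), lengths(.group_species))
  names(out) <- unlist(.group_species, use.names = FALSE)
  out
}

#' Construct beak shape parameters for a functional group
#'
#' Returns the group's mean shape ratios as defaults, overridable field by
#' field. All linear dimensions are ratios to total beak length except
#' `length` itself (mm).
#'
#' @param group One of `beak_groups()`.
#' @param overrides Named list of fields to replace (e.g.
#'   `list(depth_ratio = 0.30)`).
#' @return An object of class `beak_shape_params` with fields `length` (mm),
#'   `depth_ratio`, `width_ratio`, `ker_bottom_ratio`, `ker_top_ratio`,
#'   `bone_wall_ratio`, `curvature`, `taper_exponent`, `section_exponent`,
#'   `group`.
#' @export
make_shape_params <- function(group, overrides = list()) {
  row <- .shape_groups[.shape_groups$group == group, ]
  if (nrow(row) != 1L)
    stop("unknown functional group: ", group,
         " (expected one of ", paste(beak_groups(), collapse = ", "), ")")
  p <- list(
    length           = 15,
    depth_ratio      = row$depth,
    width_ratio      = row$width,
    ker_bottom_ratio = row$ker_bottom,
    ker_top_ratio    = row$ker_top,
    bone_wall_ratio  = 0.02,
    curvature        = row$curvature,
    taper_exponent   = 0.8,
    section_exponent = 2.5,
    group            = group
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown shape parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  class(p) <- "beak_shape_params"
  validate_shape_params(p)
  p
}

#' Validate beak shape parameters
#'
#' @param p A `beak_shape_params` object.
#' @return `p`, invisibly, or an error describing the violated invariant.
#' @export
validate_shape_params <- function(p) {
  stopifnot(inherits(p, "beak_shape_params"))
  num <- c("length", "depth_ratio", "width_ratio", "ker_bottom_ratio",
           "ker_top_ratio", "bone_wall_ratio", "taper_exponent",
           "section_exponent")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop("shape parameter '", f, "' must be a positive scalar")
  if (p$ker_bottom_ratio + p$ker_top_ratio >= p$depth_ratio)
    stop("keratin thicknesses must sum to less than the beak depth: ",
         "ker_bottom_ratio + ker_top_ratio = ",
         p$ker_bottom_ratio + p$ker_top_ratio,
         " >= depth_ratio = ", p$depth_ratio)
  if (!is.numeric(p$curvature) || p$curvature < 0 || p$curvature >= 1)
    stop("curvature (tip drop / length) must lie in [0, 1)")
  if (!p$group %in% beak_groups())
    stop("unknown functional group: ", p$group)
  invisible(p)
}

#' @export
print.beak_shape_params <- function(x, ...) {
  cat("Beak shape parameters [", x$group, "]\n", sep = "")
  cat(sprintf("  length          %.3g mm\n", x$length))
  for (f in c("depth_ratio", "width_ratio", "ker_bottom_ratio",
              "ker_top_ratio", "bone_wall_ratio", "curvature",
              "taper_exponent", "section_exponent"))
    cat(sprintf("  %-15s %.4g\n", f, x[[f]]))
  invisible(x)
}

# taper profile: local section scale at axial fraction t in [0, 1]
.profile <- function(t, taper_exponent) {
  pmax((1 - t)^taper_exponent, .beak_const$profile_min)
}

# axis centre-line drop at axial fraction t
.axis_drop <- function(t, curvature, length) -curvature * length * t^2

# superellipse boundary point for parameter angle theta: returns cbind(y, dz)
# where dz is the offset from the section centre; a = half width, b_d/b_v the
# dorsal and ventral semi-depths, p the section exponent
.superellipse <- function(theta, a, b_d, b_v, p) {
  e <- 2 / p
  s <- sin(theta); c <- cos(theta)
  b <- ifelse(s >= 0, b_d, b_v)
  cbind(y = a * sign(c) * abs(c)^e, dz = b * sign(s) * abs(s)^e)
}

# discretization sizes for a target element count
.grid_dims <- function(resolution, radial_layers = NULL) {
  n_r <- if (!is.null(radial_layers)) as.integer(radial_layers)
         else if (resolution < 20000) 2L else 4L
  if (n_r %% 2L != 0L || n_r < 2L)
    stop("radial_layers must be an even count >= 2 (split bone/keratin)")
  q <- ceiling(resolution / (6 * n_r))
  n_th <- max(12L, 4L * as.integer(round(sqrt(q / 2.5) / 4)))
  n_ax <- max(12L, 4L * as.integer(ceiling(q / n_th / 4)))
  list(n_ax = n_ax, n_th = n_th, n_r_bone = n_r %/% 2L, n_r_ker = n_r %/% 2L)
}

# Freudenthal (Kuhn) subdivision of a structured hex into 6 tets; conforming
# across a structured grid when all cells use the same local axis order.
# Vertices are indexed by bits (di, dj, dk) -> 1 + di + 2*dj + 4*dk.
.kuhn_paths <- rbind(
  c(0L, 1L, 3L, 7L),  # x, y, z
  c(0L, 1L, 5L, 7L),  # x, z, y
  c(0L, 2L, 3L, 7L),  # y, x, z
  c(0L, 2L, 6L, 7L),  # y, z, x
  c(0L, 4L, 5L, 7L),  # z, x, y
  c(0L, 4L, 6L, 7L)   # z, y, x
) + 1L

#' Generate a parametric two-layer tetrahedral beak mesh
#'
#' Builds a tapered, downward-curved upper-beak mesh: a superelliptical
#' section lofted along a curved axis, with an outer keratin sheath of the
#' prescribed dorsal/ventral thicknesses over a thin-walled bony shell that
#' encloses an open internal cavity. The bony core ends short of the beak tip
#' (the distal piece is solid keratin) and a dorsal-basal band of reduced
#' bone wall realizes the nasal hinge that lets the upper beak flex. All node
#' sets and element regions needed by the downstream load cases and stress
#' reports are tagged on the mesh.
#'
#' Meshing is fully structured and deterministic; `seed` only feeds optional
#' node jitter (`jitter > 0`) and is recorded in the mesh metadata either way.
#'
#' @param params A `beak_shape_params` object.
#' @param resolution Target element count (>= 500). The emitted mesh has at
#'   least this many tetrahedra.
#' @param seed Integer seed recorded with the mesh; used only when
#'   `jitter > 0`.
#' @param jitter Optional interior node jitter as a fraction of local element
#'   size (default 0: fully deterministic structured mesh).
#' @param bite_side Side of the unilateral base bite, `"left"` or `"right"`.
#' @param radial_layers Optional even count of radial element layers (half
#'   bone, half keratin), overriding the resolution-based default (2 below
#'   20000 elements, 4 above). Convergence studies pin this so refinement
#'   acts on the surface directions only.
#' @return A `tet_mesh`: list with `nodes` (n x 3, mm), `tets` (m x 4 node
#'   indices), `material` (per element, `"bone"` or `"keratin"`),
#'   `node_sets`, `element_regions`, and `meta` (axis metadata and the
#'   generating parameters).
#' @export
generate_beak_mesh <- function(params, resolution = 5000, seed = 1,
                               jitter = 0, bite_side = "left",
                               radial_layers = NULL) {
  validate_shape_params(params)
  if (resolution < 500) stop("resolution must be at least 500 elements")
  k <- .beak_const
  g <- .grid_dims(resolution, radial_layers)
  n_ax <- g$n_ax; n_th <- g$n_th
  n_rb <- g$n_r_bone; n_rk <- g$n_r_ker
  n_r <- n_rb + n_rk
  L <- params$length

  t_ax  <- seq(0, 1, length.out = n_ax + 1)
  theta <- -pi / 2 + 2 * pi * seq(0, n_th - 1) / n_th

  # per (station, angle): outer radius and the two interface radii
  f <- .profile(t_ax, params$taper_exponent)                 # (n_ax+1)
  a   <- 0.5 * params$width_ratio * L * f                    # half width
  b_d <- k$dorsal_frac  * params$depth_ratio * L * f
  b_v <- k$ventral_frac * params$depth_ratio * L * f

  w_top <- (1 + sin(theta)) / 2
  ker_nom <- w_top * params$ker_top_ratio + (1 - w_top) * params$ker_bottom_ratio

  hinge <- function(t) {
    h <- k$hinge_band
    ifelse(t > h[1] & t < h[2], sin(pi * (t - h[1]) / (h[2] - h[1]))^2, 0)
  }

  n_nodes <- (n_ax + 1) * n_th * (n_r + 1)
  nodes <- matrix(0, n_nodes, 3)
  node_t <- numeric(n_nodes); node_theta <- numeric(n_nodes)
  node_layer <- integer(n_nodes)
  idx <- function(i, j, kk) ((i * n_th) + (j %% n_th)) * (n_r + 1L) + kk + 1L

  for (i in 0:n_ax) {
    ti <- t_ax[i + 1]
    se <- .superellipse(theta, a[i + 1], b_d[i + 1], b_v[i + 1],
                        params$section_exponent)
    R <- sqrt(se[, "y"]^2 + se[, "dz"]^2)
    u_y <- se[, "y"] / R; u_z <- se[, "dz"] / R
    tk  <- pmin(ker_nom * L * f[i + 1], k$ker_cap * R)
    R1  <- R - tk
    wall <- params$bone_wall_ratio * L * f[i + 1] *
      (1 - k$hinge_relief * hinge(ti) * pmax(sin(theta), 0)^2)
    wall <- pmin(wall, k$wall_cap * R1)
    R2 <- R1 - wall
    zc <- .axis_drop(ti, params$curvature, L)
    for (kk in 0:n_r) {
      r <- if (kk <= n_rb) R2 + (R1 - R2) * kk / n_rb
           else            R1 + (R - R1) * (kk - n_rb) / n_rk
      ii <- idx(i, 0:(n_th - 1), kk)
      nodes[ii, 1] <- ti * L
      nodes[ii, 2] <- u_y * r
      nodes[ii, 3] <- zc + u_z * r
      node_t[ii] <- ti; node_theta[ii] <- theta; node_layer[ii] <- kk
    }
  }

  if (jitter > 0) {
    set.seed(seed)
    interior <- node_layer > 0 & node_layer < n_r & node_t > 0 & node_t < 1
    h <- L / n_ax
    nodes[interior, ] <- nodes[interior, ] +
      matrix(runif(3 * sum(interior), -1, 1), ncol = 3) * 0.1 * jitter * h
  }

  # hex cells -> 6 tets each (Freudenthal, conforming on the structured grid)
  n_hex <- n_ax * n_th * n_r
  hex <- matrix(0L, n_hex, 8)
  hex_t <- numeric(n_hex); hex_theta <- numeric(n_hex); hex_k <- integer(n_hex)
  h <- 0L
  for (i in 0:(n_ax - 1)) for (j in 0:(n_th - 1)) for (kk in 0:(n_r - 1)) {
    h <- h + 1L
    corner <- integer(8)
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1)
      corner[1L + di + 2L * dj + 4L * dk] <- idx(i + di, j + dj, kk + dk)
    hex[h, ] <- corner
    hex_t[h] <- (t_ax[i + 1] + t_ax[i + 2]) / 2
    hex_theta[h] <- theta[j + 1] + pi / n_th
    hex_k[h] <- kk
  }
  tets <- matrix(0L, 6L * n_hex, 4)
  for (p in 1:6)
    tets[seq(p, by = 6L, length.out = n_hex), ] <- hex[, .kuhn_paths[p, ]]
  el_t     <- rep(hex_t,     each = 6)
  el_theta <- rep(hex_theta, each = 6)
  el_k     <- rep(hex_k,     each = 6)

  # orient for positive signed volume
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  v <- abs(v)
  if (any(v <= .Machine$double.eps * L^3))
    stop("degenerate elements produced for parameter combination: group=",
         params$group, " depth_ratio=", params$depth_ratio,
         " width_ratio=", params$width_ratio)

  material <- ifelse(el_k < n_rb & el_t <= k$core_end, "bone", "keratin")

  s_th <- sin(el_theta)
  outer_bone <- el_k == (n_rb - 1L)
  element_regions <- list(
    bending_area      = which(material == "bone" & el_t > 0.05 & el_t < 0.15 &
                                s_th > 0.3),
    region_nasal_hinge = which(material == "bone" & outer_bone &
                                 el_t > 0.05 & el_t < 0.18 & s_th > 0.5),
    region_nasal_left  = which(material == "bone" & outer_bone &
                                 el_t > 0.12 & el_t < 0.32 &
                                 s_th > -0.1 & s_th < 0.75 & cos(el_theta) < 0),
    region_nasal_right = which(material == "bone" & outer_bone &
                                 el_t > 0.12 & el_t < 0.32 &
                                 s_th > -0.1 & s_th < 0.75 & cos(el_theta) > 0),
    region_bite_tip    = which(material == "bone" & outer_bone &
                                 el_t > k$core_end - 0.10 & el_t <= k$core_end &
                                 s_th > 0.2),
    region_bite_base   = which(material == "bone" & outer_bone &
                                 el_t > 0.17 & el_t < 0.33 & s_th > 0.2)
  )

  mesh <- structure(list(
    nodes = nodes, tets = tets, material = material,
    node_sets = list(), element_regions = element_regions,
    meta = list(length = L, curvature = params$curvature,
                taper_exponent = params$taper_exponent,
                core_end = k$core_end, n_ax = n_ax, n_th = n_th,
                n_r_bone = n_rb, n_r_ker = n_rk,
                node_t = node_t, node_theta = node_theta,
                node_layer = node_layer,
                params = unclass(params), resolution = resolution,
                seed = seed, bite_side = bite_side)
  ), class = "tet_mesh")

  # Load attachments sit on the ventro-lateral beak base distal to the nasal
  # hinge, so muscle action rotates the upper beak about the hinge onto the
  # bite support (the band ends proximal of the base-bite patch).
  outer <- node_layer == n_r
  y <- nodes[, 2]
  attach_band <- outer & node_t > 0.15 & node_t <= 0.22
  mesh$node_sets <- list(
    back_fixed = which(node_t == 0),
    bite_tip = locate_bite_nodes(mesh, "tip"),
    bite_base_unilateral = locate_bite_nodes(mesh, "base", side = bite_side),
    jugal_attach_left  = which(attach_band & abs(sin(node_theta)) <= 0.35 &
                                 y < 0),
    jugal_attach_right = which(attach_band & abs(sin(node_theta)) <= 0.35 &
                                 y > 0),
    palatine_attach = which(attach_band & sin(node_theta) <= -0.8)
  )
  validate_tet_mesh(mesh)
  mesh
}

#' Validate a tetrahedral mesh
#'
#' Checks the structural invariants: positive element volumes, named sets
#' non-empty and within bounds, and the bone/keratin labels partitioning the
#' elements.
#'
#' @param mesh A `tet_mesh`.
#' @return `mesh`, invisibly; errors on the first violated invariant.
#' @export
validate_tet_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  if (any(mesh$tets < 1L) || any(mesh$tets > n))
    stop("tet node indices out of bounds")
  if (!all(mesh$material %in% c("bone", "keratin")) ||
      length(mesh$material) != m)
    stop("material labels must partition elements into bone and keratin")
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) stop(sum(v <= 0), " non-positive element volume(s)")
  for (s in names(mesh$node_sets)) {
    ns <- mesh$node_sets[[s]]
    if (length(ns) == 0L) stop("node set '", s, "' is empty")
    if (any(ns < 1L | ns > n)) stop("node set '", s, "' out of bounds")
  }
  for (s in names(mesh$element_regions)) {
    er <- mesh$element_regions[[s]]
    if (length(er) == 0L) stop("element region '", s, "' is empty")
    if (any(er < 1L | er > m)) stop("element region '", s, "' out of bounds")
  }
  invisible(mesh)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$tets),
      "tets (", sum(x$material == "bone"), "bone /",
      sum(x$material == "keratin"), "keratin )\n")
  if (!is.null(x$meta$length))
    cat(sprintf("  length %.3g mm, grid %d x %d x %d\n", x$meta$length,
                x$meta$n_ax, x$meta$n_th, x$meta$n_r_bone + x$meta$n_r_ker))
  cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  cat("  regions:  ", paste(names(x$element_regions), collapse = ", "), "\n")
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 node coordinate matrix (mm).
#' @param tets m x 4 matrix of node indices.
#' @return Numeric vector of signed volumes (mm^3), positive for
#'   right-handed node ordering.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c_ <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# All element faces with owning element; faces keyed by sorted node triple.
.tet_faces <- function(tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  owner <- rep.int(seq_len(m), 4L)
  key <- t(apply(faces, 1, sort))
  list(faces = faces, owner = owner, key = key)
}

# Boundary faces (appearing exactly once) with owning element index.
boundary_faces <- function(mesh) {
  ff <- .tet_faces(mesh$tets)
  id <- paste(ff$key[, 1], ff$key[, 2], ff$key[, 3])
  cnt <- table(id)
  once <- id %in% names(cnt)[cnt == 1L]
  list(faces = ff$faces[once, , drop = FALSE], owner = ff$owner[once])
}

# Faces on the bone/keratin interface (shared by one bone and one keratin
# element).
interface_faces <- function(mesh) {
  ff <- .tet_faces(mesh$tets)
  id <- paste(ff$key[, 1], ff$key[, 2], ff$key[, 3])
  o <- order(id)
  id <- id[o]; owner <- ff$owner[o]; faces <- ff$faces[o, , drop = FALSE]
  dup <- which(id[-1] == id[-length(id)])
  mixed <- mesh$material[owner[dup]] != mesh$material[owner[dup + 1L]]
  faces[dup[mixed], , drop = FALSE]
}

.tri_areas <- function(nodes, faces) {
  a <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Surface area of a mesh boundary
#'
#' Sums the areas of the boundary triangles (faces owned by exactly one
#' element). With `material = "keratin"` only boundary faces of keratin
#' elements are counted, which for generated beaks is the outer skin — the
#' area the size-scaling scenario normalizes.
#'
#' @param mesh A `tet_mesh`.
#' @param material Optional material label restricting the boundary faces to
#'   those owned by elements of that material.
#' @return Total boundary area in mm^2.
#' @export
surface_area <- function(mesh, material = NULL) {
  bf <- boundary_faces(mesh)
  if (nrow(bf$faces) == 0L) stop("mesh has no boundary")
  keep <- if (is.null(material)) TRUE else mesh$material[bf$owner] == material
  faces <- bf$faces[keep, , drop = FALSE]
  if (nrow(faces) == 0L) stop("no boundary faces with material ", material)
  sum(.tri_areas(mesh$nodes, faces))
}

#' Mesh quality report
#'
#' Aspect ratio metric: longest edge divided by the smallest altitude,
#' normalized by sqrt(3/2) so a regular tetrahedron scores exactly 1.
#'
#' @param mesh A `tet_mesh`.
#' @param aspect_threshold Elements above this aspect ratio are counted as
#'   poorly shaped (reporting only).
#' @return List with `min_signed_volume`, `max_aspect`, `n_inverted`,
#'   `n_above_threshold`, and the per-element `aspect` vector.
#' @export
mesh_quality <- function(mesh, aspect_threshold = 25) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  tets <- mesh$tets; nodes <- mesh$nodes
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e2 <- vapply(seq_len(6), function(p) {
    d <- nodes[tets[, pairs[p, 1]], , drop = FALSE] -
      nodes[tets[, pairs[p, 2]], , drop = FALSE]
    rowSums(d^2)
  }, numeric(nrow(tets)))
  e2 <- matrix(e2, nrow = nrow(tets))
  max_edge <- sqrt(apply(e2, 1, max))
  # smallest altitude = 3V / largest face area
  fa <- vapply(1:4, function(f) {
    face <- tets[, setdiff(1:4, f), drop = FALSE]
    .tri_areas(nodes, face)
  }, numeric(nrow(tets)))
  fa <- matrix(fa, nrow = nrow(tets))
  max_face <- apply(fa, 1, max)
  min_alt <- 3 * abs(v) / max_face
  aspect <- (max_edge / min_alt) / sqrt(3 / 2)
  list(min_signed_volume = min(v),
       max_aspect = max(aspect),
       n_inverted = sum(v <= 0),
       n_above_threshold = sum(aspect > aspect_threshold),
       aspect = aspect)
}

# Moller-Trumbore ray/triangle intersection; returns hit distances along the
# (unit) direction for all intersected triangles.
.ray_hits <- function(nodes, faces, origin, dir) {
  eps <- 1e-12
  v0 <- nodes[faces[, 1], , drop = FALSE]
  e1 <- nodes[faces[, 2], , drop = FALSE] - v0
  e2 <- nodes[faces[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > eps
  s <- matrix(origin, nrow(v0), 3, byrow = TRUE) - v0
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q %*% dir)[, 1] / det
  tt <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9
  tt[hit]
}

#' Measure a generated beak by ray casting
#'
#' Casts vertical and horizontal rays through the mesh near the beak base and
#' reports the realized shape ratios: section depth and width over length, and
#' the dorsal/ventral keratin thicknesses over length (distance from the outer
#' surface to the bone interface along the vertical ray).
#'
#' @param mesh A generated `tet_mesh` (needs axis metadata).
#' @param station Axial fraction at which to measure (default 0.03, just
#'   inside the base where the taper profile is still near 1).
#' @return Named list: `depth_ratio`, `width_ratio`, `ker_bottom_ratio`,
#'   `ker_top_ratio`.
#' @export
measure_beak <- function(mesh, station = 0.03) {
  meta <- mesh$meta
  if (is.null(meta$length)) stop("mesh lacks axis metadata")
  L <- meta$length
  x0 <- station * L
  zc <- .axis_drop(station, meta$curvature, L)
  off <- 1e-6 * L
  bf <- boundary_faces(mesh)
  outer <- bf$faces[mesh$material[bf$owner] == "keratin", , drop = FALSE]
  inter <- interface_faces(mesh)

  up <- c(0, 0, 1)
  zo <- .ray_hits(mesh$nodes, outer, c(x0, off, zc - 10 * L), up)
  if (length(zo) < 2) stop("ray cast failed to cross the outer surface")
  depth <- max(zo) - min(zo)
  zi <- .ray_hits(mesh$nodes, inter, c(x0, off, zc - 10 * L), up)
  ker_bottom <- min(zi) - min(zo)
  ker_top <- max(zo) - max(zi)

  side <- c(0, 1, 0)
  yo <- .ray_hits(mesh$nodes, outer, c(x0, -10 * L, zc + off), side)
  width <- max(yo) - min(yo)

  list(depth_ratio = depth / L, width_ratio = width / L,
       ker_bottom_ratio = ker_bottom / L, ker_top_ratio = ker_top / L)
}

#' Per-material mesh volumes
#'
#' @param mesh A `tet_mesh`.
#' @return Named numeric vector of total element volume (mm^3) per material.
#' @export
material_volumes <- function(mesh) {
  v <- abs(tet_volumes(mesh$nodes, mesh$tets))
  vapply(split(v, mesh$material), sum, numeric(1))
}
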
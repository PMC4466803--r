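# Scenario construction: physiological vs size-scaled models, tip vs base
# biting. Bite placement follows the homologous-bite-point convention: the
# central tip bite sits close to the tip of the bony core (birds do not bite
# at the very tip), and the unilateral base bite at one quarter of the total
# rhamphotheca length, near the lateral edge of the bony core. The quarter
# point is measured as a straight axial fraction (not along the curved
# tomial edge); the convention is recorded in the case metadata.

#' Locate bite constraint nodes on a generated beak
#'
#' Selects a small patch of nodes on the ventral keratin surface: for the
#' tip bite a central patch at the axial station of the bony-core tip; for
#' the base bite a unilateral patch at axial fraction 0.25 of beak length,
#' on the configured side. The patch has a fixed physical axial half-width
#' (default 2.4% of beak length) so its extent does not shrink under mesh
#' refinement.
#'
#' @param mesh A generated `tet_mesh` (requires axis metadata).
#' @param mode `"tip"` or `"base"`.
#' @param side Side of the unilateral base bite (`"left"` = negative y).
#' @param axial_halfwidth Patch half-width as a fraction of beak length.
#' @return Integer vector of node indices on the outer (keratin) surface.
#' @export
locate_bite_nodes <- function(mesh, mode = c("tip", "base"), side = "left",
                              axial_halfwidth = 0.024) {
  mode <- match.arg(mode)
  meta <- mesh$meta
  if (is.null(meta$node_t)) stop("mesh lacks axis metadata")
  n_r <- meta$n_r_bone + meta$n_r_ker
  outer <- meta$node_layer == n_r
  s <- sin(meta$node_theta)
  y <- mesh$nodes[, 2]
  t_target <- if (mode == "tip") meta$core_end - 0.02 else 0.25
  # snap to the nearest axial station so the patch is grid-aligned
  stations <- sort(unique(meta$node_t))
  t_target <- stations[which.min(abs(stations - t_target))]
  in_band <- abs(meta$node_t - t_target) <= axial_halfwidth + 1e-12
  sel <- if (mode == "tip") {
    ventral <- s <= -0.6
    half_w <- max(abs(y[outer & in_band])) + 1e-12
    outer & in_band & ventral & abs(y) <= 0.35 * half_w
  } else {
    sgn <- if (side == "left") -1 else 1
    outer & in_band & s <= -0.35 & sgn * y >
      0.2 * max(abs(y[outer & in_band]))
  }
  nodes <- which(sel)
  if (length(nodes) == 0L)
    stop("empty bite patch: mesh resolution too coarse for mode ", mode)
  nodes
}

#' Scale a mesh to a reference surface area
#'
#' Uniformly scales coordinates by `s = sqrt(reference_area / area)` so the
#' outer keratin surface area matches the reference (the size-scaled models
#' share the surface area of the reference species, eliminating size
#' effects).
#'
#' @param mesh A `tet_mesh`.
#' @param reference_area Target outer surface area, mm^2.
#' @param material Surface used for normalization (default the outer keratin
#'   skin; set `"bone"` to normalize on the bone surface instead).
#' @return List with the scaled `mesh` and the scale factor `s`.
#' @export
scale_to_reference <- function(mesh, reference_area, material = "keratin") {
  if (reference_area <= 0) stop("reference area must be positive")
  a <- surface_area(mesh, material = material)
  if (a <= 0) stop("degenerate mesh surface area")
  s <- sqrt(reference_area / a)
  mesh$nodes <- mesh$nodes * s
  mesh$meta$length <- mesh$meta$length * s
  list(mesh = mesh, s = s)
}

#' Scenario specification
#'
#' @param scenario `"physiological"` (species' own loads on its own-size
#'   mesh) or `"scaled"` (all meshes normalized to a reference surface area
#'   and loaded with the reference input forces).
#' @param bite_mode `"tip"` or `"base"`.
#' @param reference_area Reference outer surface area, mm^2 (scaled only).
#' @param reference_loads A `beak_loads` object (scaled only; conventionally
#'   the G. fortis input forces, Fj = 11.9 N, Fp = 10.9 N).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(scenario = c("physiological", "scaled"),
                          bite_mode = c("tip", "base"),
                          reference_area = NULL, reference_loads = NULL) {
  scenario <- match.arg(scenario)
  bite_mode <- match.arg(bite_mode)
  if (scenario == "scaled" &&
      (is.null(reference_area) || is.null(reference_loads)))
    stop("scaled scenario requires reference_area and reference_loads")
  structure(list(scenario = scenario, bite_mode = bite_mode,
                 reference_area = reference_area,
                 reference_loads = reference_loads),
            class = "scenario_spec")
}

#' Build the load case for a scenario
#'
#' Applies the scenario's loads to the mesh's attachment sets: the jugal
#' force split equally between the left and right jugal attachments, the
#' palatine force on the palatine attachment; the back rim is always fully
#' constrained and the bite patch for the requested mode is fully
#' constrained. For the scaled scenario the caller scales the mesh first
#' (see [scale_to_reference()]); `build_case` then applies the reference
#' loads regardless of species.
#'
#' @param mesh A generated (and, for scaled scenarios, already scaled)
#'   `tet_mesh`.
#' @param spec A [scenario_spec()].
#' @param species_loads A `beak_loads` object (used for physiological
#'   scenarios; ignored for scaled ones).
#' @return A [load_case()].
#' @export
build_case <- function(mesh, spec, species_loads = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  loads <- if (spec$scenario == "scaled") spec$reference_loads
           else species_loads
  if (is.null(loads))
    stop("missing loads for ", spec$scenario, " scenario")
  stopifnot(inherits(loads, "beak_loads"))
  bite_nodes <- if (spec$bite_mode == "tip") mesh$node_sets$bite_tip
                else mesh$node_sets$bite_base_unilateral
  load_case(
    fixed_nodes = mesh$node_sets$back_fixed,
    bite_nodes = bite_nodes,
    point_loads = list(
      list(nodes = mesh$node_sets$jugal_attach_left,
           force = loads$jugal_dir * loads$Fj / 2),
      list(nodes = mesh$node_sets$jugal_attach_right,
           force = loads$jugal_dir * loads$Fj / 2),
      list(nodes = mesh$node_sets$palatine_attach,
           force = loads$palatine_dir * loads$Fp)
    ),
    bite_mode = spec$bite_mode
  )
}
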
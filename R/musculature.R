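# Jaw-muscle architecture: PCSA, bundle forces, and the two load pathways
# acting on the upper beak. The external adductor and pseudotemporalis
# bundles act on the upper mandible only indirectly, through the jugal bar
# (force projected by an effective angle relative to the jugal); the
# pterygoid/palatine bundles act on it directly. The depressor (MDM, jaw
# opener) never contributes to closing loads.

.pathways <- c("indirect_jugal", "direct_palatine", "none")

#' Load the packaged finch jaw-muscle dissection table
#'
#' Per-bundle muscle mass (g) and fiber length (mm) for the eight Darwin's
#' finch species with dissection data, with each bundle assigned to its load
#' pathway: the external adductor + pseudotemporalis complex acts on the
#' upper beak indirectly via the jugal; the pterygoid/palatine complex acts
#' directly; the jaw opener (MDM) and, by default, the protractor (MPPtQ)
#' are excluded from closing loads.
#'
#' @param species Optional species id (e.g. `"G_fortis"`) to filter to.
#' @return A data.frame with columns `species`, `muscle`, `mass_g`,
#'   `fiber_length_mm`, `pathway`.
#' @export
finch_muscles <- function(species = NULL) {
  path <- system.file("extdata", "finch_muscles.csv", package = "beakfem",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(species)) {
    tab <- tab[tab$species %in% species, , drop = FALSE]
    if (nrow(tab) == 0L) stop("no muscle data for species: ",
                              paste(species, collapse = ", "))
  }
  tab
}

#' Assemble a species muscle set
#'
#' @param species Species id.
#' @param bundles Data.frame with columns `muscle`, `mass_g`,
#'   `fiber_length_mm`, `pathway` (defaults to the packaged dissection table
#'   for that species).
#' @param density Muscle density, kg/m^3.
#' @param specific_tension Muscle stress, N/cm^2.
#' @return A `species_muscles` object.
#' @export
species_muscles <- function(species, bundles = finch_muscles(species),
                            density = 1036, specific_tension = 30) {
  stopifnot(density > 0, specific_tension > 0)
  need <- c("muscle", "mass_g", "fiber_length_mm", "pathway")
  if (!all(need %in% names(bundles)))
    stop("bundles must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(bundles$muscle))
    stop("bundle names must be unique within a species")
  if (any(bundles$mass_g <= 0) || any(bundles$fiber_length_mm <= 0))
    stop("muscle mass and fiber length must be positive")
  if (!all(bundles$pathway %in% .pathways))
    stop("pathway must be one of ", paste(.pathways, collapse = ", "))
  structure(list(species = species, bundles = bundles, density = density,
                 specific_tension = specific_tension),
            class = "species_muscles")
}

#' @export
print.species_muscles <- function(x, ...) {
  cat("Jaw muscles for", x$species, "-", nrow(x$bundles), "bundles\n")
  cat(sprintf("  density %.0f kg/m^3, specific tension %.0f N/cm^2\n",
              x$density, x$specific_tension))
  cat(sprintf("  indirect (jugal) sum %.2f N, direct (palatine) sum %.2f N\n",
              pathway_force(x, "indirect_jugal"),
              pathway_force(x, "direct_palatine")))
  invisible(x)
}

#' Physiological cross-sectional area of a muscle bundle
#'
#' PCSA = mass / (density x fiber length), with unit conversions so mass in
#' grams and fiber length in mm yield cm^2. No pennation correction is
#' applied: pennate muscles enter as separate bundles.
#'
#' @param mass_g Bundle mass, g.
#' @param fiber_length_mm Mean fiber length, mm.
#' @param density Muscle density, kg/m^3.
#' @return PCSA in cm^2.
#' @export
pcsa <- function(mass_g, fiber_length_mm, density = 1036) {
  if (any(mass_g <= 0) || any(fiber_length_mm <= 0) || density <= 0)
    stop("mass, fiber length and density must be positive")
  # g -> kg (1e-3), mm -> m (1e-3), m^2 -> cm^2 (1e4)
  (mass_g * 1e-3) / (density * fiber_length_mm * 1e-3) * 1e4
}

#' Maximal isometric force of a muscle bundle
#'
#' @inheritParams pcsa
#' @param specific_tension Muscle stress, N/cm^2.
#' @return Force in N.
#' @export
bundle_force <- function(mass_g, fiber_length_mm, density = 1036,
                         specific_tension = 30) {
  if (specific_tension < 0) stop("specific tension must be non-negative")
  specific_tension * pcsa(mass_g, fiber_length_mm, density)
}

#' Summed bundle force along one pathway
#'
#' @param muscles A `species_muscles` object.
#' @param pathway `"indirect_jugal"` or `"direct_palatine"`.
#' @return Summed maximal force, N. Bundles absent from the dissection table
#'   simply do not contribute.
#' @export
pathway_force <- function(muscles, pathway) {
  stopifnot(inherits(muscles, "species_muscles"))
  b <- muscles$bundles[muscles$bundles$pathway == pathway, , drop = FALSE]
  if (nrow(b) == 0L) return(0)
  sum(bundle_force(b$mass_g, b$fiber_length_mm, muscles$density,
                   muscles$specific_tension))
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("direction vector must be non-zero")
  v / n
}

# Default load directions in the mesh frame (x tip-ward, z up): both pathways
# pull the upper beak downward and backward during jaw closing.
default_jugal_dir    <- function() .unit(c(-0.3, 0, -0.95))
default_palatine_dir <- function() .unit(c(-0.2, 0, -0.98))

#' Resolve muscle bundles into the two beak load vectors
#'
#' The indirect pathway (external adductor + pseudotemporalis) is projected
#' onto the jugal axis by an effective angle; the direct pathway
#' (pterygoid/palatine) transmits along the palatine direction, optionally
#' scaled by an effective transfer coefficient. The jugal load is applied
#' bilaterally, half at each jugal attachment.
#'
#' @param muscles A `species_muscles` object.
#' @param jugal_angle Effective angle (degrees, in `[0, 90]`) between the
#'   indirect-muscle resultant and the jugal axis.
#' @param jugal_dir,palatine_dir Unit direction vectors of the two load paths
#'   in mesh coordinates.
#' @param palatine_scale Effective transfer coefficient of the direct
#'   pathway (1 = full transmission). Values above 1 indicate a calibration
#'   target exceeding the raw force sum and are flagged in the result.
#' @return A `beak_loads` object: magnitudes `Fj`, `Fp` (N), unit directions,
#'   and the angle used.
#' @export
resolve_beak_loads <- function(muscles, jugal_angle,
                               jugal_dir = default_jugal_dir(),
                               palatine_dir = default_palatine_dir(),
                               palatine_scale = 1) {
  stopifnot(inherits(muscles, "species_muscles"))
  if (jugal_angle < 0 || jugal_angle > 90)
    stop("jugal_angle must lie in [0, 90] degrees")
  Fj <- cos(jugal_angle * pi / 180) * pathway_force(muscles, "indirect_jugal")
  Fp <- palatine_scale * pathway_force(muscles, "direct_palatine")
  structure(list(species = muscles$species,
                 Fj = Fj, Fp = Fp,
                 jugal_dir = .unit(jugal_dir),
                 palatine_dir = .unit(palatine_dir),
                 jugal_angle = jugal_angle,
                 palatine_scale = palatine_scale,
                 exceeds_raw_sum = palatine_scale > 1),
            class = "beak_loads")
}

#' Construct beak loads from explicit magnitudes
#'
#' Convenience constructor for scenario references (e.g. the G. fortis input
#' forces used by the size-scaled models).
#'
#' @param Fj,Fp Jugal and palatine load magnitudes, N.
#' @inheritParams resolve_beak_loads
#' @param species Optional label.
#' @return A `beak_loads` object.
#' @export
beak_loads <- function(Fj, Fp, jugal_dir = default_jugal_dir(),
                       palatine_dir = default_palatine_dir(),
                       species = NA_character_) {
  stopifnot(Fj >= 0, Fp >= 0)
  structure(list(species = species, Fj = Fj, Fp = Fp,
                 jugal_dir = .unit(jugal_dir),
                 palatine_dir = .unit(palatine_dir),
                 jugal_angle = NA_real_, palatine_scale = NA_real_,
                 exceeds_raw_sum = FALSE),
            class = "beak_loads")
}

#' @export
print.beak_loads <- function(x, ...) {
  cat(sprintf("Beak loads%s: |Fj| = %.3g N (bilateral), |Fp| = %.3g N\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              x$Fj, x$Fp))
  if (!is.na(x$jugal_angle))
    cat(sprintf("  jugal projection angle %.1f deg, palatine scale %.3f%s\n",
                x$jugal_angle, x$palatine_scale,
                if (isTRUE(x$exceeds_raw_sum))
                  " (exceeds raw pathway sum)" else ""))
  invisible(x)
}

#' Calibrate the effective jugal angle and palatine transfer coefficient
#'
#' The dissection geometry behind the per-species muscle orientations is not
#' available, so the two-pathway model is calibrated against target input
#' forces: `jugal_angle = acos(target_Fj / sum of indirect forces)` and
#' `palatine_scale = target_Fp / sum of direct forces`. Applying the result
#' through [resolve_beak_loads()] reproduces the targets exactly (to
#' round-off). A palatine target exceeding the raw direct sum yields a scale
#' above 1 (flagged downstream); a jugal target exceeding the indirect sum is
#' an error since no projection angle can produce it.
#'
#' @param muscles A `species_muscles` object.
#' @param target_Fj,target_Fp Target jugal and palatine input forces, N.
#' @return List with `jugal_angle` (degrees) and `palatine_scale`.
#' @export
calibrate_angles <- function(muscles, target_Fj, target_Fp) {
  Fi <- pathway_force(muscles, "indirect_jugal")
  Fd <- pathway_force(muscles, "direct_palatine")
  if (target_Fj < 0 || target_Fp < 0) stop("targets must be non-negative")
  if (target_Fj > Fi)
    stop(sprintf(paste0("jugal target %.3g N exceeds the summed indirect ",
                        "muscle force %.3g N (acos out of domain)"),
                 target_Fj, Fi))
  if (Fd <= 0 && target_Fp > 0) stop("no direct-pathway bundles available")
  list(jugal_angle = acos(target_Fj / Fi) * 180 / pi,
       palatine_scale = if (target_Fp == 0 && Fd == 0) 1 else target_Fp / Fd)
}

#' Calibrated physiological loads for one species
#'
#' Looks up the species' published model input forces (jugal and palatine)
#' and returns the loads that reproduce them through the two-pathway model.
#'
#' @param species Species id with both dissection data and published input
#'   forces.
#' @param ... Passed to [species_muscles()] (e.g. `density`,
#'   `specific_tension`).
#' @return A `beak_loads` object.
#' @export
physiological_loads <- function(species, ...) {
  targets <- reference_input_forces()
  if (!species %in% rownames(targets))
    stop("no published input forces for ", species)
  m <- species_muscles(species, ...)
  cal <- calibrate_angles(m, targets[species, "Fj"], targets[species, "Fp"])
  resolve_beak_loads(m, cal$jugal_angle, palatine_scale = cal$palatine_scale)
}

#' Published model input forces per species
#'
#' @return Matrix (rownames = species) with columns `Fj`, `Fp`: the jugal and
#'   palatine input forces (N) of the physiological models.
#' @export
reference_input_forces <- function() {
  tab <- finch_model_stresses()
  phys <- tab[tab$lc == "PB", c("species", "Fj", "Fp")]
  out <- as.matrix(phys[, c("Fj", "Fp")])
  rownames(out) <- phys$species
  out
}
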
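# Accessors for the packaged reference tables from the published FE study of
# Darwin's finch beaks: per-model input forces and regional stresses, the
# safety factors, and the functional-group shape ratios.

.extdata <- function(file) {
  read.csv(system.file("extdata", file, package = "beakfem",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Published per-model stresses and forces
#'
#' One row per FE model of the source study: load case (`PB`/`PT` =
#' physiological base/tip biting, `FB`/`FT` = base/tip biting size-scaled to
#' G. fortis), input forces `Fj`/`Fp` (N), regional 98th-percentile von
#' Mises stresses `vM1`-`vM3` (MPa), normalized CT gray values at the same
#' locations, model bite force `F` (N) and material volumes (mm^3).
#'
#' @return A data.frame of 40 model rows.
#' @export
finch_model_stresses <- function() .extdata("finch_model_stresses.csv")

#' Published model safety factors
#'
#' Model bite forces and 1-decimal safety factors for the eight species with
#' physiological models, together with the feeding behavior class.
#'
#' @return A data.frame of 8 species rows.
#' @export
finch_safety_factors <- function() .extdata("finch_safety_factors.csv")

#' Published functional-group shape ratios
#'
#' Group means and standard deviations of bottom/top keratin thickness, beak
#' depth and beak width, all relative to beak length.
#'
#' @return A data.frame of 4 group rows.
#' @export
finch_shape_groups <- function() .extdata("finch_shape_groups.csv")
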
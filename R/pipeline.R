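# Pipeline orchestration: one deterministic run from shape parameters to the
# comparative tables. Stages: generate -> loads -> cases -> solve ->
# summarize -> correlate.

#' Synthetic 13-species beak cohort
#'
#' One parameter set per finch species: the species' functional-group mean
#' ratios perturbed by seeded Gaussian jitter with the group's published
#' standard deviations (clamped to two SDs and to the shape invariants), so
#' the cohort spans the observed parameter ranges while staying valid.
#'
#' @param seed Integer seed (all cohort randomness derives from it).
#' @param length Beak length given to every synthetic beak, mm (the source
#'   geometries' absolute lengths are not published; size effects are removed
#'   by the scaled scenario anyway).
#' @return Named list of `beak_shape_params`, one per species.
#' @export
finch_cohort <- function(seed = 0, length = 15) {
  set.seed(seed)
  sg <- species_groups()
  out <- lapply(names(sg), function(sp) {
    g <- .shape_groups[.shape_groups$group == sg[[sp]], ]
    jit <- function(mean, sd) {
      x <- mean + stats::rnorm(1, 0, sd)
      min(max(x, mean - 2 * sd, 0.25 * mean), mean + 2 * sd)
    }
    ov <- list(length = length,
               depth_ratio = jit(g$depth, g$depth_sd),
               width_ratio = jit(g$width, g$width_sd),
               ker_bottom_ratio = jit(g$ker_bottom, g$ker_bottom_sd),
               ker_top_ratio = jit(g$ker_top, g$ker_top_sd))
    if (ov$ker_bottom_ratio + ov$ker_top_ratio >= 0.95 * ov$depth_ratio) {
      shrink <- 0.95 * ov$depth_ratio /
        (ov$ker_bottom_ratio + ov$ker_top_ratio)
      ov$ker_bottom_ratio <- ov$ker_bottom_ratio * shrink
      ov$ker_top_ratio <- ov$ker_top_ratio * shrink
    }
    make_shape_params(sg[[sp]], ov)
  })
  names(out) <- names(sg)
  out
}

#' Pipeline configuration
#'
#' @param cohort Named list of `beak_shape_params` (default the seeded
#'   13-species cohort).
#' @param scenario `"scaled"` or `"physiological"`.
#' @param resolution Target element count per mesh.
#' @param seed Master seed; the cohort and all meshing derive from it.
#' @param materials Material set (see [beak_materials()]).
#' @param pct Percentile for regional stresses.
#' @param strength Bone strength for safety factors, MPa.
#' @param reference_loads Loads for the scaled scenario (default the
#'   G. fortis input forces, 11.9 N jugal / 10.9 N palatine).
#' @param reference_group Functional group whose default-parameter beak
#'   provides the reference surface area for scaling (default `"crush"`, the
#'   G. fortis group).
#' @param species_loads Named list of `beak_loads` for physiological runs.
#' @param out_dir Optional directory for CSV artifacts.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = NULL, scenario = "scaled",
                            resolution = 3000, seed = 0,
                            materials = beak_materials(), pct = 0.98,
                            strength = reported_strength(7300),
                            reference_loads = beak_loads(11.9, 10.9,
                                                         species = "G_fortis"),
                            reference_group = "crush",
                            species_loads = NULL, out_dir = NULL) {
  if (is.null(cohort)) cohort <- finch_cohort(seed)
  stopifnot(scenario %in% c("scaled", "physiological"))
  if (scenario == "physiological" && is.null(species_loads))
    stop("physiological scenario requires species_loads")
  cfg <- list(cohort = cohort, scenario = scenario, resolution = resolution,
              seed = seed, materials = materials, pct = pct,
              strength = strength, reference_loads = reference_loads,
              reference_group = reference_group,
              species_loads = species_loads, out_dir = out_dir)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Hash a configuration for provenance
#'
#' @param config Any R object.
#' @return MD5 hex digest of the serialized object (version-2 serialization,
#'   stable across sessions).
#' @export
config_hash <- function(config) {
  config$hash <- NULL
  config$out_dir <- NULL   # artifact destination is not scientific content
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(config, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full beak-loading pipeline
#'
#' Generates every cohort beak, applies the scenario (size-scaling to the
#' reference surface area for `"scaled"`), solves tip and base biting,
#' summarizes stresses/bite forces/safety factors, and computes the
#' functional-group shape summaries and shape-versus-safety correlations.
#' Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_result`: `summaries` (one row per model x bite mode),
#'   `shape_table` (per model ratios + SFs), `correlations`, `group_stats`,
#'   `reference_area`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  ref_area <- NULL
  spec_list <- list()
  if (config$scenario == "scaled") {
    ref_mesh <- generate_beak_mesh(make_shape_params(config$reference_group),
                                   resolution = config$resolution,
                                   seed = config$seed)
    ref_area <- surface_area(ref_mesh, material = "keratin")
    say("reference area ", signif(ref_area, 4), " mm^2")
  }
  summaries <- list(); shapes <- list()
  for (id in names(config$cohort)) {
    params <- config$cohort[[id]]
    stage <- paste0("generate[", id, "]")
    mesh <- tryCatch(
      generate_beak_mesh(params, resolution = config$resolution,
                         seed = config$seed),
      error = function(e) stop("stage ", stage, " failed: ",
                               conditionMessage(e)))
    if (config$scenario == "scaled")
      mesh <- scale_to_reference(mesh, ref_area)$mesh
    for (mode in c("base", "tip")) {
      spec <- if (config$scenario == "scaled")
        scenario_spec("scaled", mode, reference_area = ref_area,
                      reference_loads = config$reference_loads)
      else scenario_spec("physiological", mode)
      case <- build_case(mesh, spec, config$species_loads[[id]])
      stage <- paste0("solve[", id, ", ", mode, "]")
      sol <- tryCatch(solve_static(mesh, config$materials, case),
                      error = function(e) stop("stage ", stage, " failed: ",
                                               conditionMessage(e)))
      summaries[[paste(id, mode)]] <- summarize_solution(
        sol, mesh, scenario = config$scenario, bite_mode = mode,
        pct = config$pct, strength = config$strength, model = id)
      say(stage, ": peak ", signif(summaries[[paste(id, mode)]]$peak_vm, 3),
          " MPa, bite ",
          signif(summaries[[paste(id, mode)]]$bite_force, 3), " N")
    }
    shapes[[id]] <- data.frame(
      model = id, group = params$group,
      ker_bottom_ratio = params$ker_bottom_ratio,
      ker_top_ratio = params$ker_top_ratio,
      depth_ratio = params$depth_ratio, width_ratio = params$width_ratio,
      stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  shape_table <- do.call(rbind, shapes)
  sf_of <- function(mode) {
    s <- summaries[summaries$bite_mode == mode, ]
    s$sf[match(shape_table$model, s$model)]
  }
  shape_table$SF_base <- sf_of("base")
  shape_table$SF_tip <- sf_of("tip")
  rownames(shape_table) <- NULL

  correlations <- if (nrow(shape_table) >= 4)
    shape_safety_correlations(shape_table) else NULL
  group_stats <- do.call(rbind, lapply(
    c("ker_bottom_ratio", "ker_top_ratio", "depth_ratio", "width_ratio"),
    function(f) cbind(field = f, group_summary(shape_table, f))))

  res <- structure(list(summaries = summaries, shape_table = shape_table,
                        correlations = correlations,
                        group_stats = group_stats,
                        reference_area = ref_area, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Beak-loading pipeline:", nrow(x$shape_table), "models,",
      x$config$scenario, "scenario\n")
  cat(sprintf("  SF range base %.2f-%.2f, tip %.2f-%.2f\n",
              min(x$shape_table$SF_base), max(x$shape_table$SF_base),
              min(x$shape_table$SF_tip), max(x$shape_table$SF_tip)))
  invisible(x)
}

#' Write pipeline artifacts as CSV
#'
#' Emits the stress-summary table, the shape/safety table, the group
#' summaries and the correlation table, each carrying the configuration hash
#' and seed, plus a plain-text run log.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    df$config_hash <- result$config$hash
    df$seed <- result$config$seed
    df
  }
  write.csv(stamp(result$summaries), file.path(dir, "stress_summaries.csv"),
            row.names = FALSE)
  write.csv(stamp(result$shape_table), file.path(dir, "shape_safety.csv"),
            row.names = FALSE)
  write.csv(stamp(result$group_stats), file.path(dir, "group_summaries.csv"),
            row.names = FALSE)
  if (!is.null(result$correlations))
    write.csv(stamp(result$correlations),
              file.path(dir, "shape_safety_correlations.csv"),
              row.names = FALSE)
  writeLines(c(
    paste("beakfem", as.character(utils::packageVersion("beakfem"))),
    paste("R", getRversion()),
    paste("seed", result$config$seed),
    paste("config", result$config$hash),
    paste("scenario", result$config$scenario),
    paste("resolution", result$config$resolution),
    paste("percentile", result$config$pct),
    paste("strength_MPa", result$config$strength)
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Replay a stress table into safety factors
#'
#' Applies peak = max(vM1, vM2, vM3), then strength / peak, to each row of a
#' model-stress table (no FE solve involved), and pivots the base/tip pairs
#' into a safety-factor table.
#'
#' @param stresses Data.frame with columns `species`, `lc` (PB/PT/FB/FT),
#'   `vM1`, `vM2`, `vM3` and optionally `F`, or a path to such a CSV.
#' @param strength Bone strength, MPa (default the reported 45 MPa).
#' @return Data.frame with one row per species x scenario family: model
#'   forces (if present) and full-precision plus 1-decimal safety factors
#'   for both bite modes.
#' @export
replay_tables <- function(stresses, strength = reported_strength(7300)) {
  if (is.character(stresses)) stresses <- read.csv(stresses,
                                                   stringsAsFactors = FALSE)
  empty <- data.frame(species = character(), scenario = character(),
                      model_force_base = numeric(),
                      model_force_tip = numeric(),
                      sf_base = numeric(), sf_tip = numeric(),
                      sf_base_rounded = numeric(),
                      sf_tip_rounded = numeric(), stringsAsFactors = FALSE)
  if (nrow(stresses) == 0L) return(empty)
  need <- c("species", "lc", "vM1", "vM2", "vM3")
  if (!all(need %in% names(stresses)))
    stop("stress table needs columns ", paste(need, collapse = ", "))
  stresses$peak <- pmax(stresses$vM1, stresses$vM2, stresses$vM3)
  stresses$sf <- safety_factor(strength, stresses$peak)
  fam <- ifelse(stresses$lc %in% c("PB", "PT"), "physiological", "scaled")
  mode <- ifelse(stresses$lc %in% c("PB", "FB"), "base", "tip")
  keys <- unique(data.frame(species = stresses$species, scenario = fam,
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- stresses$species == keys$species[i] & fam == keys$scenario[i]
    pick <- function(m, col) {
      v <- stresses[[col]][sel & mode == m]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(species = keys$species[i], scenario = keys$scenario[i],
               model_force_base = if ("F" %in% names(stresses))
                 pick("base", "F") else NA_real_,
               model_force_tip = if ("F" %in% names(stresses))
                 pick("tip", "F") else NA_real_,
               sf_base = pick("base", "sf"), sf_tip = pick("tip", "sf"),
               sf_base_rounded = round_sf(pick("base", "sf")),
               sf_tip_rounded = round_sf(pick("tip", "sf")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
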
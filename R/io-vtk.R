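# Mesh file I/O. Meshes are written as legacy ASCII VTK unstructured grids
# (readable by ParaView/VTK and by meshio-based tools): material labels and
# element regions as CELL_DATA, node sets and the generator's parametric
# node coordinates as POINT_DATA, and the scalar axis metadata packed into
# the VTK title line. Coordinates are printed at full double precision so a
# write/read round trip is exact. The outer surface can also be exported as
# ASCII STL.

.meta_scalars <- c("length", "curvature", "taper_exponent", "core_end",
                   "n_ax", "n_th", "n_r_bone", "n_r_ker", "resolution",
                   "seed")

#' Write a mesh as legacy ASCII VTK
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- mesh$meta
  title <- paste("beakfem", paste(
    vapply(.meta_scalars, function(f)
      if (is.null(meta[[f]])) "" else
        paste0(f, "=", format(meta[[f]], digits = 17)),
      character(1)), collapse = " "))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(format(mesh$nodes, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste("CELLS", m, 5 * m), con)
  writeLines(paste(4, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(10L, m)), con)

  writeLines(paste("CELL_DATA", m), con)
  writeLines(c("SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(mesh$material == "bone", 1L, 2L)), con)
  for (r in names(mesh$element_regions)) {
    flag <- integer(m); flag[mesh$element_regions[[r]]] <- 1L
    writeLines(c(paste("SCALARS", paste0("region_tag_", r), "int 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(flag), con)
  }

  writeLines(paste("POINT_DATA", n), con)
  for (s in names(mesh$node_sets)) {
    flag <- integer(n); flag[mesh$node_sets[[s]]] <- 1L
    writeLines(c(paste("SCALARS", paste0("set_tag_", s), "int 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(flag), con)
  }
  for (f in c("node_t", "node_theta", "node_layer")) {
    if (is.null(meta[[f]])) next
    writeLines(c(paste("SCALARS", f, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(meta[[f]], digits = 17, scientific = TRUE,
                      trim = TRUE), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' @param path Path to a legacy ASCII VTK file written by this package.
#' @return A `tet_mesh` with node sets, element regions and axis metadata
#'   restored.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  title <- lines[2]
  meta <- list()
  if (startsWith(title, "beakfem")) {
    kv <- regmatches(title, gregexpr("[a-z_]+=[-0-9.e+]+", title))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- as.numeric(p[2])
    }
    for (f in c("n_ax", "n_th", "n_r_bone", "n_r_ker", "resolution", "seed"))
      if (!is.null(meta[[f]])) meta[[f]] <- as.integer(meta[[f]])
  }
  i_pts <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i_pts], " +")[[1]][2])
  nodes <- matrix(scan(text = lines[(i_pts + 1):(i_pts + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  i_cells <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[i_cells], " +")[[1]][2])
  cells <- matrix(scan(text = lines[(i_cells + 1):(i_cells + m)],
                       quiet = TRUE),
                  ncol = 5, byrow = TRUE)
  tets <- matrix(as.integer(cells[, 2:5] + 1L), ncol = 4)

  read_scalar_blocks <- function(from, to, count) {
    idx <- grep("^SCALARS ", lines)
    idx <- idx[idx > from & idx <= to]
    out <- list()
    for (i in idx) {
      name <- strsplit(lines[i], " +")[[1]][2]
      vals <- scan(text = lines[(i + 2):(i + 1 + count)], quiet = TRUE)
      out[[name]] <- vals
    }
    out
  }
  i_cd <- grep("^CELL_DATA", lines)[1]
  i_pd <- grep("^POINT_DATA", lines)[1]
  cd <- read_scalar_blocks(i_cd, i_pd, m)
  pd <- read_scalar_blocks(i_pd, length(lines), n)

  material <- ifelse(cd$material == 1, "bone", "keratin")
  element_regions <- lapply(cd[grep("^region_tag_", names(cd))],
                            function(v) which(v == 1))
  names(element_regions) <- sub("^region_tag_", "",
                                names(cd)[grep("^region_tag_", names(cd))])
  node_sets <- lapply(pd[grep("^set_tag_", names(pd))],
                      function(v) which(v == 1))
  names(node_sets) <- sub("^set_tag_", "",
                          names(pd)[grep("^set_tag_", names(pd))])
  for (f in c("node_t", "node_theta", "node_layer"))
    if (!is.null(pd[[f]]))
      meta[[f]] <- if (f == "node_layer") as.integer(pd[[f]]) else pd[[f]]

  structure(list(nodes = nodes, tets = tets, material = material,
                 node_sets = node_sets, element_regions = element_regions,
                 meta = meta),
            class = "tet_mesh")
}

#' Export the outer surface as ASCII STL
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path.
#' @param material Material whose boundary faces form the surface (default
#'   the keratin skin; `NULL` for the full boundary).
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(mesh, path, material = "keratin") {
  bf <- boundary_faces(mesh)
  keep <- if (is.null(material)) rep(TRUE, nrow(bf$faces))
          else mesh$material[bf$owner] == material
  faces <- bf$faces[keep, , drop = FALSE]
  if (nrow(faces) == 0L) stop("no boundary faces to export")
  v1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  v2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  v3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  fmt <- function(v) paste(format(v[, 1]), format(v[, 2]), format(v[, 3]))
  body <- paste0("facet normal ", fmt(nrm), "\n outer loop\n  vertex ",
                 fmt(v1), "\n  vertex ", fmt(v2), "\n  vertex ", fmt(v3),
                 "\n endloop\nendfacet")
  writeLines(c("solid beakfem", body, "endsolid beakfem"), path)
  invisible(path)
}
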
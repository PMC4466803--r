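# Structured box meshes for solver verification (patch tests, cantilever
# benchmarks, dense-solve cross-checks).

#' Structured tetrahedral box mesh
#'
#' Meshes the box `[0, lx] x [0, ly] x [0, lz]` on a regular grid, each cell
#' split into six tetrahedra (Freudenthal subdivision, conforming). Face node
#' sets `x0`, `x1`, `y0`, `y1`, `z0`, `z1` are tagged.
#'
#' @param lx,ly,lz Box dimensions, mm.
#' @param nx,ny,nz Cells per direction.
#' @param material Material label for every element.
#' @return A `tet_mesh` (no beak axis metadata).
#' @export
make_box_mesh <- function(lx, ly, lz, nx = 4, ny = 4, nz = 4,
                          material = "bone") {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  idx <- function(i, j, k) (k * (ny + 1L) + j) * (nx + 1L) + i + 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL

  n_hex <- nx * ny * nz
  hex <- matrix(0L, n_hex, 8)
  h <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    h <- h + 1L
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1)
      hex[h, 1L + di + 2L * dj + 4L * dk] <- idx(i + di, j + dj, k + dk)
  }
  tets <- matrix(0L, 6L * n_hex, 4)
  for (p in 1:6)
    tets[seq(p, by = 6L, length.out = n_hex), ] <- hex[, .kuhn_paths[p, ]]
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  eps <- 1e-9 * max(lx, ly, lz)
  structure(list(
    nodes = nodes, tets = tets,
    material = rep(material, nrow(tets)),
    node_sets = list(
      x0 = which(nodes[, 1] < eps), x1 = which(nodes[, 1] > lx - eps),
      y0 = which(nodes[, 2] < eps), y1 = which(nodes[, 2] > ly - eps),
      z0 = which(nodes[, 3] < eps), z1 = which(nodes[, 3] > lz - eps)),
    element_regions = list(all = seq_len(nrow(tets))),
    meta = list(lx = lx, ly = ly, lz = lz, nx = nx, ny = ny, nz = nz)
  ), class = "tet_mesh")
}
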
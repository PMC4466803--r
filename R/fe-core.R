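# Small-strain linear-elastic solver for 4-node (constant-strain)
# tetrahedra with isotropic materials. Consistent N-mm-MPa unit system:
# coordinates mm, forces N, moduli and stresses MPa.

#' Isotropic linear-elastic material
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return A `material` object.
#' @export
material <- function(E, nu) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must lie in [0, 0.5)")
  structure(list(E = E, nu = nu), class = "material")
}

#' Default beak material set
#'
#' Bone and keratin moduli from nanoindentation work on finch beaks
#' (E_bone = 7.3 GPa, E_keratin = 1.7 GPa), entered in MPa. Poisson ratios
#' are not reported with those measurements; the defaults (0.30 for cortical
#' bone, 0.40 for beta-keratin) are the values conventionally used in avian
#' beak FE modelling, and are recorded in every stress summary.
#'
#' @param E_bone,E_keratin Young's moduli, MPa.
#' @param nu_bone,nu_keratin Poisson ratios.
#' @return Named list of `material` objects (`bone`, `keratin`).
#' @export
beak_materials <- function(E_bone = 7300, nu_bone = 0.30,
                           E_keratin = 1700, nu_keratin = 0.40) {
  list(bone = material(E_bone, nu_bone),
       keratin = material(E_keratin, nu_keratin))
}

# 6x6 isotropic elasticity matrix (engineering shear strains),
# component order xx, yy, zz, xy, yz, zx
.dmatrix <- function(mat) {
  E <- mat$E; nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# shape-function gradients and volume of one tet; coords 4x3
.tet_gradients <- function(coords) {
  J <- coords[2:4, , drop = FALSE] -
    matrix(coords[1, ], 3, 3, byrow = TRUE)
  detJ <- det(J)
  V <- detJ / 6
  if (V <= 0) stop("degenerate tetrahedron (non-positive volume)")
  g <- t(solve(J))                # columns: grad lambda_2..4? rows below
  grads <- rbind(-colSums(g), g)  # 4x3: grad N_i
  list(grads = grads, V = V)
}

# 6x12 strain-displacement matrix from 4x3 shape gradients
.bmatrix <- function(grads) {
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    b <- grads[i, 1]; c_ <- grads[i, 2]; d <- grads[i, 3]
    col <- 3 * (i - 1)
    B[1, col + 1] <- b
    B[2, col + 2] <- c_
    B[3, col + 3] <- d
    B[4, col + 1] <- c_; B[4, col + 2] <- b
    B[5, col + 2] <- d;  B[5, col + 3] <- c_
    B[6, col + 1] <- d;  B[6, col + 3] <- b
  }
  B
}

#' Element stiffness matrix of a 4-node tetrahedron
#'
#' `K = V * B' D B` for the constant-strain tetrahedron: symmetric positive
#' semi-definite with exactly six rigid-body zero-energy modes.
#'
#' @param coords 4 x 3 matrix of node coordinates (mm), right-handed
#'   (positive volume) ordering.
#' @param mat A [material()].
#' @return 12 x 12 stiffness matrix (N/mm), DOFs ordered
#'   (u1,v1,w1, ..., u4,v4,w4).
#' @export
element_stiffness <- function(coords, mat) {
  tg <- .tet_gradients(coords)
  B <- .bmatrix(tg$grads)
  tg$V * crossprod(B, .dmatrix(mat) %*% B)
}

#' Assemble the global sparse stiffness matrix
#'
#' @param mesh A `tet_mesh`.
#' @param materials Named list of [material()] objects covering every label
#'   in `mesh$material`.
#' @return Sparse symmetric stiffness matrix (3n x 3n, `Matrix` package),
#'   DOFs ordered (x1, y1, z1, x2, ...).
#' @export
assemble <- function(mesh, materials) {
  labs <- unique(mesh$material)
  missing <- setdiff(labs, names(materials))
  if (length(missing))
    stop("no material supplied for label(s): ", paste(missing, collapse = ", "))
  m <- nrow(mesh$tets); n <- nrow(mesh$nodes)
  D <- lapply(materials, .dmatrix)
  ii <- integer(144 * m); jj <- integer(144 * m); xx <- numeric(144 * m)
  pos <- 0L
  for (e in seq_len(m)) {
    tg <- .tet_gradients(mesh$nodes[mesh$tets[e, ], , drop = FALSE])
    B <- .bmatrix(tg$grads)
    Ke <- tg$V * crossprod(B, D[[mesh$material[e]]] %*% B)
    dofs <- rep(3L * (mesh$tets[e, ] - 1L), each = 3L) + rep(1:3, 4)
    rng <- pos + seq_len(144L)
    ii[rng] <- rep(dofs, times = 12L)
    jj[rng] <- rep(dofs, each = 12L)
    xx[rng] <- Ke
    pos <- pos + 144L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n, 3 * n))
}

#' Define a load case
#'
#' @param fixed_nodes Node indices with all translations constrained (back of
#'   the beak at the neurocranium).
#' @param bite_nodes Node indices with all translations constrained at the
#'   bite point; their reaction is the model bite force. May be empty for
#'   verification problems without a bite support.
#' @param point_loads List of loads, each either `list(nodes =, force =)`
#'   where `force` is the total force vector (N) distributed as statically
#'   equivalent equal nodal forces over the node set, or
#'   `list(nodes =, forces =)` with an explicit per-node force matrix
#'   (|nodes| x 3) as produced by [consistent_face_loads()].
#' @param bite_mode `"tip"` or `"base"`.
#' @return A `load_case` object.
#' @export
load_case <- function(fixed_nodes, bite_nodes = integer(0), point_loads,
                      bite_mode = c("tip", "base")) {
  bite_mode <- match.arg(bite_mode)
  fixed_nodes <- as.integer(fixed_nodes); bite_nodes <- as.integer(bite_nodes)
  if (length(intersect(fixed_nodes, bite_nodes)))
    stop("fixed and bite node sets must be disjoint")
  constrained <- c(fixed_nodes, bite_nodes)
  for (pl in point_loads) {
    ok <- "nodes" %in% names(pl) &&
      ((!is.null(pl$force) && length(pl$force) == 3) ||
         (!is.null(pl$forces) && is.matrix(pl$forces) &&
            nrow(pl$forces) == length(pl$nodes) && ncol(pl$forces) == 3))
    if (!ok)
      stop("each point load needs nodes plus force (length-3 total) or ",
           "forces (per-node matrix)")
    if (length(intersect(pl$nodes, constrained)))
      stop("loaded nodes must not be constrained")
  }
  structure(list(fixed_nodes = fixed_nodes, bite_nodes = bite_nodes,
                 point_loads = point_loads, bite_mode = bite_mode),
            class = "load_case")
}

#' Solve the static elasticity problem
#'
#' Direct sparse Cholesky solve of `K u = f` on the free DOFs, with element
#' stresses from constant-strain kinematics (evaluated at element centroids,
#' no nodal averaging) and reactions `K u - f` on constrained DOFs.
#'
#' @param mesh A `tet_mesh`.
#' @param materials Named list of [material()] objects.
#' @param case A [load_case()].
#' @param residual_tol Maximum accepted relative residual on the free DOFs.
#' @return An `fe_solution`: `displacement` (n x 3, mm), `stress` (m x 6,
#'   MPa, order xx,yy,zz,xy,yz,zx), `von_mises` (per element, MPa),
#'   `reactions` (per constrained node, N), `residual`, and the inputs'
#'   metadata.
#' @export
solve_static <- function(mesh, materials, case, residual_tol = 1e-8) {
  n <- nrow(mesh$nodes)
  K <- assemble(mesh, materials)
  f <- numeric(3 * n)
  for (pl in case$point_loads) {
    nodes <- as.integer(pl$nodes)
    if (!is.null(pl$forces)) {
      for (d in 1:3) f[3 * (nodes - 1) + d] <- f[3 * (nodes - 1) + d] +
          pl$forces[, d]
    } else {
      per <- pl$force / length(nodes)
      for (d in 1:3) f[3 * (nodes - 1) + d] <- f[3 * (nodes - 1) + d] + per[d]
    }
  }
  con_nodes <- c(case$fixed_nodes, case$bite_nodes)
  con <- rep(3L * (con_nodes - 1L), each = 3L) + rep(1:3, length(con_nodes))
  free <- setdiff(seq_len(3 * n), con)
  if (length(free) == 0L) stop("all DOFs constrained")

  u <- numeric(3 * n)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)), ff),
    error = function(e)
      stop("linear solve failed (singular system? insufficient constraints): ",
           conditionMessage(e)))
  u[free] <- as.numeric(sol)

  r <- as.numeric(K %*% u - f)
  res <- sqrt(sum(r[free]^2)) / max(1, sqrt(sum(ff^2)))
  if (res > residual_tol)
    stop(sprintf("solver residual %.3g exceeds tolerance %.3g", res,
                 residual_tol))

  m <- nrow(mesh$tets)
  stress <- matrix(0, m, 6,
                   dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  D <- lapply(materials, .dmatrix)
  for (e in seq_len(m)) {
    tg <- .tet_gradients(mesh$nodes[mesh$tets[e, ], , drop = FALSE])
    B <- .bmatrix(tg$grads)
    dofs <- rep(3L * (mesh$tets[e, ] - 1L), each = 3L) + rep(1:3, 4)
    stress[e, ] <- D[[mesh$material[e]]] %*% (B %*% u[dofs])
  }

  reactions <- matrix(r[rep(3L * (con_nodes - 1L), each = 3L) + rep(1:3,
                        length(con_nodes))],
                      ncol = 3, byrow = TRUE,
                      dimnames = list(NULL, c("x", "y", "z")))
  structure(list(
    displacement = matrix(u, ncol = 3, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y", "z"))),
    stress = stress,
    von_mises = von_mises(stress),
    reaction_nodes = con_nodes,
    reactions = reactions,
    residual = res,
    case = case, n_dof_free = length(free)
  ), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat("FE solution:", nrow(x$displacement), "nodes,", nrow(x$stress),
      "elements\n")
  cat(sprintf("  residual %.2e, max |u| %.3g mm, max vM %.3g MPa\n",
              x$residual, max(abs(x$displacement)), max(x$von_mises)))
  cat(sprintf("  bite force %.3g N (%s bite)\n",
              reaction_force(x, x$case$bite_nodes)$magnitude,
              x$case$bite_mode))
  invisible(x)
}

#' Von Mises equivalent stress
#'
#' @param stress Length-6 vector or m x 6 matrix of stress components in the
#'   order (xx, yy, zz, xy, yz, zx), MPa.
#' @return Von Mises stress(es), MPa.
#' @export
von_mises <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, 1)
  sx <- stress[, 1]; sy <- stress[, 2]; sz <- stress[, 3]
  txy <- stress[, 4]; tyz <- stress[, 5]; tzx <- stress[, 6]
  sqrt(0.5 * ((sx - sy)^2 + (sy - sz)^2 + (sz - sx)^2) +
         3 * (txy^2 + tyz^2 + tzx^2))
}

#' Net reaction force over a constrained node set
#'
#' The magnitude over the bite node set is the model bite force: equal in
#' magnitude and opposite in sign to the force on the food item.
#'
#' @param solution An `fe_solution`.
#' @param nodes Node indices; must all be constrained in the solved case.
#' @return List with `force` (length-3 vector, N) and `magnitude` (N).
#' @export
reaction_force <- function(solution, nodes) {
  idx <- match(as.integer(nodes), solution$reaction_nodes)
  if (anyNA(idx))
    stop("reaction requested at unconstrained node(s)")
  force <- colSums(solution$reactions[idx, , drop = FALSE])
  list(force = force, magnitude = sqrt(sum(force^2)))
}

#' Mesh-refinement convergence check
#'
#' Re-meshes and re-solves a beak model at increasing target resolutions and
#' reports the relative change in peak regional von Mises stress and model
#' bite force at each refinement, flagging a pass when the final doubling
#' changes both by less than the stated fraction.
#'
#' @param params A `beak_shape_params`.
#' @param loads A `beak_loads` object applied at every level.
#' @param resolutions Increasing vector (length >= 2) of target element
#'   counts.
#' @param bite_mode `"tip"` or `"base"`.
#' @param materials Material set.
#' @param pct Percentile used for the regional peak stress.
#' @param tol Pass threshold on the final refinement (default 0.05 = 5%).
#' @param seed Mesh generator seed.
#' @param radial_layers Through-wall layer count pinned across levels
#'   (default 4: two element layers per material) so refinement acts on the
#'   surface directions at fixed through-wall resolution.
#' @return A `convergence_report`: data.frame of levels plus a `pass` flag.
#' @export
convergence_check <- function(params, loads, resolutions,
                              bite_mode = "base",
                              materials = beak_materials(), pct = 0.98,
                              tol = 0.05, seed = 1, radial_layers = 4) {
  if (length(resolutions) < 2) stop("need at least two resolutions")
  rows <- lapply(resolutions, function(res) {
    mesh <- generate_beak_mesh(params, resolution = res, seed = seed,
                               radial_layers = radial_layers)
    case <- build_case(mesh, scenario_spec("physiological", bite_mode), loads)
    sol <- solve_static(mesh, materials, case)
    sm <- summarize_solution(sol, mesh, scenario = "physiological",
                             bite_mode = bite_mode, pct = pct)
    data.frame(resolution = res, n_elements = nrow(mesh$tets),
               peak_vm = sm$peak_vm, bite_force = sm$bite_force)
  })
  out <- do.call(rbind, rows)
  rel_change <- function(x) c(NA, abs(diff(x)) / abs(x[-length(x)]))
  out$peak_vm_change <- rel_change(out$peak_vm)
  out$bite_force_change <- rel_change(out$bite_force)
  last <- nrow(out)
  structure(list(table = out,
                 pass = out$peak_vm_change[last] < tol &&
                   out$bite_force_change[last] < tol,
                 tol = tol),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("final refinement: %s (threshold %.0f%%)\n",
              if (x$pass) "PASS" else "not converged", 100 * x$tol))
  invisible(x)
}

#' Consistent nodal loads for a uniform surface traction
#'
#' Integrates a constant traction over the boundary triangles whose three
#' nodes all belong to the given node set (each triangle contributing a third
#' of its area to each node) — the statically consistent load vector for
#' linear triangles, which reproduces uniform stress states exactly in patch
#' tests.
#'
#' @param mesh A `tet_mesh`.
#' @param nodes Node set spanning the loaded surface patch.
#' @param traction Traction vector, N/mm^2 (MPa).
#' @return A point-load entry `list(nodes =, forces =)` for [load_case()].
#' @export
consistent_face_loads <- function(mesh, nodes, traction) {
  stopifnot(length(traction) == 3)
  bf <- boundary_faces(mesh)
  onpatch <- matrix(bf$faces %in% nodes, ncol = 3)
  faces <- bf$faces[rowSums(onpatch) == 3L, , drop = FALSE]
  if (nrow(faces) == 0L) stop("no boundary triangles span the node set")
  areas <- .tri_areas(mesh$nodes, faces)
  nodal <- numeric(max(nodes))
  for (c_ in 1:3) {
    agg <- tapply(areas / 3, faces[, c_], sum)
    idx <- as.integer(names(agg))
    nodal[idx] <- nodal[idx] + as.numeric(agg)
  }
  used <- sort(unique(as.integer(faces)))
  list(nodes = used, forces = outer(nodal[used], traction))
}
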
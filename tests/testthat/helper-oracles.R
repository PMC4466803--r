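# Independent oracles, written from scratch against textbook formulas and
# kept free of the package's internal code paths.

# Element stiffness by direct hand assembly of the constant-strain-tet
# B matrix from explicit shape-function gradients.
oracle_element_K <- function(coords, E, nu) {
  M <- cbind(1, coords)                  # rows: [1 x y z]
  V <- det(M) / 6
  grads <- solve(M)[2:4, ]               # column i: grad N_i
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    gx <- grads[1, i]; gy <- grads[2, i]; gz <- grads[3, i]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- gx
    B[2, c0 + 2] <- gy
    B[3, c0 + 3] <- gz
    B[4, c0 + 1] <- gy; B[4, c0 + 2] <- gx
    B[5, c0 + 2] <- gz; B[5, c0 + 3] <- gy
    B[6, c0 + 1] <- gz; B[6, c0 + 3] <- gx
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  V * t(B) %*% D %*% B
}

# Dense global stiffness by brute-force scatter of oracle element matrices.
oracle_dense_K <- function(mesh, materials) {
  n <- nrow(mesh$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(mesh$tets))) {
    mat <- materials[[mesh$material[e]]]
    Ke <- oracle_element_K(mesh$nodes[mesh$tets[e, ], ], mat$E, mat$nu)
    dofs <- as.vector(t(outer(mesh$tets[e, ], 1:3,
                              function(a, b) 3 * (a - 1) + b)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# Dense direct solve with constraint elimination via base::solve.
oracle_dense_solve <- function(mesh, materials, fixed_nodes, f) {
  n <- nrow(mesh$nodes)
  K <- oracle_dense_K(mesh, materials)
  con <- as.vector(t(outer(fixed_nodes, 1:3, function(a, b) 3 * (a - 1) + b)))
  free <- setdiff(seq_len(3 * n), con)
  u <- numeric(3 * n)
  u[free] <- solve(K[free, free], f[free])
  matrix(u, ncol = 3, byrow = TRUE)
}

# Boundary area by a brute-force face walk: hash every face of every tet in
# a named counter and sum areas of faces seen exactly once.
oracle_boundary_area <- function(mesh) {
  counter <- new.env(hash = TRUE)
  store <- new.env(hash = TRUE)
  combs <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (e in seq_len(nrow(mesh$tets))) {
    for (cmb in combs) {
      tri <- sort(mesh$tets[e, cmb])
      key <- paste(tri, collapse = "_")
      counter[[key]] <- if (is.null(counter[[key]])) 1L else
        counter[[key]] + 1L
      store[[key]] <- tri
    }
  }
  area <- 0
  for (key in ls(counter)) {
    if (counter[[key]] == 1L) {
      tri <- store[[key]]
      a <- mesh$nodes[tri[2], ] - mesh$nodes[tri[1], ]
      b <- mesh$nodes[tri[3], ] - mesh$nodes[tri[1], ]
      area <- area + sqrt(sum(crossprod_vec(a, b)^2)) / 2
    }
  }
  area
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Product-moment correlation straight from the defining sums.
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# A regular tetrahedron with unit edge, wrapped as a minimal tet_mesh.
regular_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  structure(list(nodes = nodes, tets = matrix(1:4, 1),
                 material = "bone", node_sets = list(all = 1:4),
                 element_regions = list(all = 1L), meta = list()),
            class = "tet_mesh")
}

# Four near-coplanar points: a sliver element.
sliver_tet_mesh <- function(height = 1e-4) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                 c(0.5, 0.5, height))
  structure(list(nodes = nodes, tets = matrix(1:4, 1),
                 material = "bone", node_sets = list(all = 1:4),
                 element_regions = list(all = 1L), meta = list()),
            class = "tet_mesh")
}

# Fabricated solution/mesh pair for percentile-convention checks.
fake_solution <- function(vm) list(von_mises = vm)
fake_bone_mesh <- function(m) list(material = rep("bone", m))
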
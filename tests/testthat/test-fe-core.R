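test_that("element stiffness is symmetric with rigid-body null modes", {
  set.seed(42)
  for (i in 1:5) {
    coords <- matrix(rnorm(12), 4, 3)
    if (det(cbind(1, coords)) < 0) coords <- coords[c(1, 2, 4, 3), ]
    K <- element_stiffness(coords, material(2000, 0.3))
    expect_equal(K, t(K), tolerance = 1e-12)
    for (d in 1:3) {
      u <- rep(0, 12); u[seq(d, 12, by = 3)] <- 1   # rigid translation
      expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
    }
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9 * max(abs(K)))
  }
  expect_error(element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                       c(1, 1, 0)), material(1, 0)),
               "degenerate")
})

test_that("element stiffness matches the hand-assembled B-matrix oracle", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(element_stiffness(ref, material(1, 0)),
               oracle_element_K(ref, 1, 0), tolerance = 1e-12)
  set.seed(1)
  coords <- ref + 0.2 * matrix(rnorm(12), 4, 3)
  expect_equal(element_stiffness(coords, material(7300, 0.3)),
               oracle_element_K(coords, 7300, 0.3), tolerance = 1e-10)
})

test_that("assembly equals brute-force dense scatter and is linear in E", {
  mesh <- make_box_mesh(1, 1, 1, 1, 1, 1)   # 6 tets, 8 nodes
  mats <- list(bone = material(1000, 0.25))
  K <- as.matrix(assemble(mesh, mats))
  expect_equal(K, oracle_dense_K(mesh, mats), tolerance = 1e-10)

  K2 <- as.matrix(assemble(mesh, list(bone = material(2000, 0.25))))
  expect_equal(K2, 2 * K, tolerance = 1e-12)

  expect_error(assemble(mesh, list(keratin = material(1, 0))), "no material")

  # a node belonging to no element gives a zero row/column
  mesh$nodes <- rbind(mesh$nodes, c(5, 5, 5))
  Kd <- as.matrix(assemble(mesh, mats))
  expect_equal(dim(Kd), c(27L, 27L))
  expect_true(all(Kd[25:27, ] == 0) && all(Kd[, 25:27] == 0))
})

test_that("zero loads give identically zero response", {
  mesh <- make_box_mesh(2, 1, 1, 2, 1, 1)
  case <- load_case(fixed_nodes = mesh$node_sets$x0,
                    point_loads = list(list(nodes = mesh$node_sets$x1,
                                            force = c(0, 0, 0))))
  sol <- solve_static(mesh, list(bone = material(100, 0.3)), case)
  expect_equal(max(abs(sol$displacement)), 0)
  expect_equal(max(sol$von_mises), 0)
  expect_equal(max(abs(sol$reactions)), 0)
})

test_that("uniform-bar patch test is exact", {
  mesh <- make_box_mesh(10, 2, 2, nx = 5, ny = 2, nz = 2)
  mats <- list(bone = material(1000, 0))
  traction <- c(2, 0, 0)   # MPa over the 4 mm^2 end face
  case <- load_case(fixed_nodes = mesh$node_sets$x0,
                    point_loads = list(consistent_face_loads(
                      mesh, mesh$node_sets$x1, traction)))
  sol <- solve_static(mesh, mats, case)
  expect_lt(max(abs(sol$stress[, 1] - 2)), 1e-10)
  expect_lt(max(abs(sol$stress[, 2:6])), 1e-10)
  expect_lt(max(abs(sol$von_mises - 2)), 1e-10)
  # reaction equals the applied load with opposite sign
  rf <- reaction_force(sol, mesh$node_sets$x0)
  expect_equal(unname(rf$force), c(-8, 0, 0), tolerance = 1e-10)
  expect_equal(rf$magnitude, 8, tolerance = 1e-10)
})

test_that("solution matches a dense brute-force solve on a small mesh", {
  mesh <- make_box_mesh(2, 1, 1, 2, 2, 2)   # 27 nodes = 81 DOF
  mats <- list(bone = material(500, 0.3))
  case <- load_case(fixed_nodes = mesh$node_sets$x0,
                    point_loads = list(list(nodes = mesh$node_sets$x1,
                                            force = c(1, 0.5, -2))))
  sol <- solve_static(mesh, mats, case)
  f <- numeric(3 * nrow(mesh$nodes))
  per <- c(1, 0.5, -2) / length(mesh$node_sets$x1)
  for (nd in mesh$node_sets$x1) f[3 * (nd - 1) + 1:3] <- per
  u_oracle <- oracle_dense_solve(mesh, mats, mesh$node_sets$x0, f)
  scale <- max(abs(u_oracle))
  expect_lt(max(abs(sol$displacement - u_oracle)) / scale, 1e-10)
})

test_that("response is linear in the load and reactions balance loads", {
  mesh <- generate_beak_mesh(make_shape_params("crush"), 1000, seed = 1)
  mats <- beak_materials()
  mk <- function(scale) build_case(
    mesh, scenario_spec("physiological", "base"),
    beak_loads(11.9 * scale, 10.9 * scale))
  s1 <- solve_static(mesh, mats, mk(1))
  s2 <- solve_static(mesh, mats, mk(2))
  expect_equal(s2$displacement, 2 * s1$displacement, tolerance = 1e-9)
  expect_equal(reaction_force(s2, s2$case$bite_nodes)$magnitude,
               2 * reaction_force(s1, s1$case$bite_nodes)$magnitude,
               tolerance = 1e-9)
  # global equilibrium: reactions + applied loads cancel
  total_applied <- (11.9 + 10.9)  # both loads have unit direction vectors
  resultant <- colSums(s1$reactions) +
    11.9 * beak_loads(11.9, 10.9)$jugal_dir +
    10.9 * beak_loads(11.9, 10.9)$palatine_dir
  expect_lt(max(abs(resultant)) / total_applied, 1e-8)
})

test_that("stresses scale as 1/s^2 under uniform geometric scaling", {
  mesh <- generate_beak_mesh(make_shape_params("probe"), 1000, seed = 1)
  mats <- beak_materials()
  case <- build_case(mesh, scenario_spec("physiological", "base"),
                     beak_loads(5, 5))
  s1 <- solve_static(mesh, mats, case)
  big <- mesh; big$nodes <- big$nodes * 2; big$meta$length <- big$meta$length * 2
  s2 <- solve_static(big, mats, case)
  expect_equal(s2$von_mises, s1$von_mises / 4, tolerance = 1e-8)
  expect_equal(s2$displacement, s1$displacement / 2, tolerance = 1e-8)
})

test_that("von Mises stress is frame-invariant under rigid rotation", {
  mesh <- generate_beak_mesh(make_shape_params("crush"), 1000, seed = 1)
  mats <- beak_materials()
  loads <- beak_loads(11.9, 10.9)
  case <- build_case(mesh, scenario_spec("physiological", "base"), loads)
  s1 <- solve_static(mesh, mats, case)
  ang <- c(0.4, -0.3, 1.1)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  rot <- mesh; rot$nodes <- mesh$nodes %*% t(R)
  case_rot <- case
  case_rot$point_loads <- lapply(case$point_loads, function(pl) {
    pl$force <- as.numeric(R %*% pl$force); pl
  })
  s2 <- solve_static(rot, mats, case_rot)
  expect_equal(s2$von_mises, s1$von_mises,
               tolerance = 1e-8 * max(s1$von_mises))
})

test_that("von Mises closed forms hold", {
  expect_equal(von_mises(c(50, 0, 0, 0, 0, 0)), 50)
  expect_equal(von_mises(c(0, 0, 0, 7, 0, 0)), sqrt(3) * 7)
  expect_equal(von_mises(c(-3, -3, -3, 0, 0, 0)), 0)
  m <- rbind(c(50, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 7, 0))
  expect_equal(von_mises(m), c(50, sqrt(3) * 7))
})

test_that("reaction queries reject unconstrained nodes", {
  mesh <- make_box_mesh(2, 1, 1, 2, 1, 1)
  case <- load_case(fixed_nodes = mesh$node_sets$x0,
                    point_loads = list(list(nodes = mesh$node_sets$x1,
                                            force = c(1, 0, 0))))
  sol <- solve_static(mesh, list(bone = material(100, 0.3)), case)
  expect_error(reaction_force(sol, mesh$node_sets$x1), "unconstrained")
})

test_that("under-constrained systems are reported, not silently solved", {
  mesh <- make_box_mesh(2, 1, 1, 2, 1, 1)
  case <- load_case(fixed_nodes = integer(0),
                    point_loads = list(list(nodes = mesh$node_sets$x1,
                                            force = c(1, 0, 0))))
  expect_error(solve_static(mesh, list(bone = material(100, 0.3)), case),
               "singular|failed|residual")
})

test_that("repeating a resolution yields zero convergence change", {
  p <- make_shape_params("crush")
  cv <- convergence_check(p, beak_loads(11.9, 10.9), c(1500, 1500),
                          radial_layers = 2)
  expect_equal(cv$table$peak_vm_change[2], 0)
  expect_equal(cv$table$bite_force_change[2], 0)
  expect_true(cv$pass)
})

test_that("slender cantilever approaches the Euler-Bernoulli deflection", {
  E <- 1000; P <- 1
  I <- 2 * 2^3 / 12
  delta <- P * 20^3 / (3 * E * I)   # beam-theory tip deflection, L/h = 10
  tip_def <- function(nx, ny, nz) {
    mesh <- make_box_mesh(20, 2, 2, nx = nx, ny = ny, nz = nz)
    case <- load_case(fixed_nodes = mesh$node_sets$x0,
                      point_loads = list(list(nodes = mesh$node_sets$x1,
                                              force = c(0, 0, -P))))
    sol <- solve_static(mesh, list(bone = material(E, 0)), case)
    -mean(sol$displacement[mesh$node_sets$x1, 3])
  }
  coarse <- tip_def(40, 4, 4)
  ref <- tip_def(60, 6, 6)        # documented reference resolution
  expect_lt(abs(ref - delta) / delta, 0.10)
  expect_lt(abs(ref - delta), abs(coarse - delta))  # improves on refinement
})
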
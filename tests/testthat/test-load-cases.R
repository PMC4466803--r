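test_that("base bite nodes sit at the quarter point on one side", {
  mesh <- generate_beak_mesh(make_shape_params("crush"), 3000, seed = 1)
  L <- mesh$meta$length
  nodes <- locate_bite_nodes(mesh, "base", side = "left")
  x <- mesh$nodes[nodes, 1]; y <- mesh$nodes[nodes, 2]
  expect_true(all(abs(x / L - 0.25) <= 0.025))
  expect_true(all(y < 0))          # unilateral, left of the midline
  right <- locate_bite_nodes(mesh, "base", side = "right")
  expect_true(all(mesh$nodes[right, 2] > 0))
  # ventral keratin surface only
  n_r <- mesh$meta$n_r_bone + mesh$meta$n_r_ker
  expect_true(all(mesh$meta$node_layer[nodes] == n_r))
  expect_true(all(sin(mesh$meta$node_theta[nodes]) < 0))
})

test_that("tip bite nodes straddle the midline near the bony-core tip", {
  mesh <- generate_beak_mesh(make_shape_params("tip"), 3000, seed = 1)
  nodes <- locate_bite_nodes(mesh, "tip")
  y <- mesh$nodes[nodes, 2]
  expect_equal(sort(y), sort(-y), tolerance = 1e-9)   # symmetric patch
  t <- mesh$meta$node_t[nodes]
  expect_true(all(t <= mesh$meta$core_end))
  expect_true(all(t > mesh$meta$core_end - 0.08))
})

test_that("bite patch node count grows but physical extent stays capped", {
  p <- make_shape_params("crush")
  counts <- c(); diam <- c()
  for (res in c(1500, 10000, 40000)) {
    mesh <- generate_beak_mesh(p, res, seed = 1)
    nodes <- locate_bite_nodes(mesh, "base")
    pts <- mesh$nodes[nodes, , drop = FALSE]
    counts <- c(counts, length(nodes))
    diam <- c(diam, max(dist(pts)))
  }
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
  expect_true(all(diam <= 0.35 * p$length))
})

test_that("surface-area scaling is exact and reversible", {
  mesh <- generate_beak_mesh(make_shape_params("probe"), 1500, seed = 1)
  a <- surface_area(mesh, "keratin")
  same <- scale_to_reference(mesh, a)
  expect_equal(same$s, 1, tolerance = 1e-12)
  expect_equal(same$mesh$nodes, mesh$nodes, tolerance = 1e-12)

  q <- scale_to_reference(mesh, 4 * a)
  expect_equal(q$s, 2, tolerance = 1e-12)
  expect_equal(surface_area(q$mesh, "keratin"), 4 * a,
               tolerance = 1e-3 * 4 * a)

  back <- scale_to_reference(q$mesh, a)
  expect_equal(back$mesh$nodes, mesh$nodes,
               tolerance = 1e-10 * max(abs(mesh$nodes)))
  expect_error(scale_to_reference(mesh, -1), "positive")
})

test_that("scaled cases carry the reference loads for every species", {
  ref <- beak_loads(11.9, 10.9, species = "G_fortis")
  for (g in c("crush", "probe")) {
    mesh <- generate_beak_mesh(make_shape_params(g), 1500, seed = 1)
    spec <- scenario_spec("scaled", "tip", reference_area = 100,
                          reference_loads = ref)
    case <- build_case(mesh, spec)
    mags <- vapply(case$point_loads,
                   function(pl) sqrt(sum(pl$force^2)), numeric(1))
    expect_equal(sort(mags), sort(c(11.9 / 2, 11.9 / 2, 10.9)),
                 tolerance = 1e-12)
  }
  expect_error(scenario_spec("scaled", "tip"), "requires reference")
})

test_that("physiological cases use the species' own loads and sets", {
  mesh <- generate_beak_mesh(make_shape_params("crush"), 1500, seed = 1)
  loads <- beak_loads(11.9, 10.9)
  case <- build_case(mesh, scenario_spec("physiological", "base"), loads)
  expect_identical(case$bite_nodes,
                   as.integer(mesh$node_sets$bite_base_unilateral))
  expect_identical(case$fixed_nodes, as.integer(mesh$node_sets$back_fixed))
  expect_length(intersect(case$fixed_nodes, case$bite_nodes), 0)
  loaded <- unlist(lapply(case$point_loads, `[[`, "nodes"))
  expect_length(intersect(loaded, c(case$fixed_nodes, case$bite_nodes)), 0)
  expect_error(build_case(mesh, scenario_spec("physiological", "base")),
               "missing loads")
})

test_that("a mesh already at reference size degenerates to physiological", {
  mesh <- generate_beak_mesh(make_shape_params("crush"), 1500, seed = 1)
  a <- surface_area(mesh, "keratin")
  ref <- beak_loads(11.9, 10.9)
  scaled_mesh <- scale_to_reference(mesh, a)$mesh
  c_scaled <- build_case(scaled_mesh,
                         scenario_spec("scaled", "base", reference_area = a,
                                       reference_loads = ref))
  c_phys <- build_case(mesh, scenario_spec("physiological", "base"), ref)
  expect_equal(c_scaled$point_loads, c_phys$point_loads, tolerance = 1e-12)
  expect_identical(c_scaled$bite_nodes, c_phys$bite_nodes)
})

test_that("geometrically similar meshes give identical stresses once scaled", {
  p <- make_shape_params("probe_and_base")
  small <- generate_beak_mesh(p, 1000, seed = 1)
  big <- generate_beak_mesh(make_shape_params("probe_and_base",
                                              list(length = 24)),
                            1000, seed = 1)
  ref <- surface_area(small, "keratin")
  loads <- beak_loads(11.9, 10.9)
  sols <- lapply(list(small, big), function(mesh) {
    m2 <- scale_to_reference(mesh, ref)$mesh
    case <- build_case(m2, scenario_spec("scaled", "base",
                                         reference_area = ref,
                                         reference_loads = loads))
    solve_static(m2, beak_materials(), case)
  })
  expect_equal(sols[[1]]$von_mises, sols[[2]]$von_mises,
               tolerance = 1e-6 * max(sols[[1]]$von_mises))
})
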
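# One coarse reference solution shared across the checks in this file.
base_model <- fem_test_model(substrate_modulus = 0.9)
base_mesh <- build_mesh(base_model)
base_sol <- solve_contraction(base_model, base_mesh)

test_that("model validation rejects degenerate configurations", {
  expect_error(contraction_model(cell_length = 2, cell_radius = 4),
               class = "podomech_validation_error")
  expect_error(contraction_model(mesh_resolution = 2),
               class = "podomech_validation_error")
  expect_error(contraction_model(cell_poisson = 0.5),
               class = "podomech_validation_error")
  expect_error(contraction_model(substrate_modulus = -1),
               class = "podomech_validation_error")
  expect_error(contraction_model(eigenstrain_base = c(-0.6, 0, 0)),
               class = "podomech_validation_error")
})

test_that("the mesh is conforming with a shared cell-substrate interface", {
  q <- mesh_quality(base_mesh)
  expect_true(q$interface_conforming)
  expect_gt(q$n_interface_nodes, 0)
  expect_gt(q$min_volume, 0)
  # no duplicated node coordinates (mismatched face diagonals would create
  # coincident but distinct nodes)
  expect_false(any(duplicated(round(base_mesh$nodes, 9))))
  # tetrahedra tile the kept hexahedra exactly: total volume is a whole
  # number of substrate slab plus voxelised cell volume
  expect_equal(q$n_elements, q$n_cell_elements + q$n_substrate_elements)
  sub_vol <- prod(base_model$substrate_size) * base_model$substrate_thickness
  vols <- podomech:::tet_signed_volume(base_mesh$nodes, base_mesh$elems[, 1:4])
  expect_equal(sum(vols[base_mesh$region == "substrate"]), sub_vol,
               tolerance = 1e-9)
})

test_that("the solved state is in equilibrium with self-balanced reactions", {
  expect_lt(base_sol$equilibrium_residual, 1e-10)
  # eigenstrain is self-equilibrated: net reaction on the fixed base ~ 0
  scale <- max(abs(base_sol$stress)) * base_model$cell_radius^2
  expect_lt(max(abs(base_sol$reaction_sum)) / scale, 1e-8)
})

test_that("the solution is mirror-symmetric in y and sigma_zy is odd", {
  nodes <- base_mesh$nodes
  key <- paste(round(nodes[, 1], 8), round(-nodes[, 2], 8),
               round(nodes[, 3], 8))
  own <- paste(round(nodes[, 1], 8), round(nodes[, 2], 8),
               round(nodes[, 3], 8))
  mirror <- match(key, own)
  expect_false(anyNA(mirror)) # grid built symmetric in y
  u <- base_sol$u
  uref <- max(abs(u))
  expect_lt(max(abs(u[, 1] - u[mirror, 1])) / uref, 1e-9)
  expect_lt(max(abs(u[, 3] - u[mirror, 3])) / uref, 1e-9)
  expect_lt(max(abs(u[, 2] + u[mirror, 2])) / uref, 1e-9)
  prof <- interface_shear_profile(base_sol)
  rev_idx <- match(round(-prof$y_um, 8), round(prof$y_um, 8))
  sref <- max(abs(prof$sigma_zx_kPa))
  expect_lt(max(abs(prof$sigma_zx_kPa - prof$sigma_zx_kPa[rev_idx])) / sref,
            1e-8)
  szyref <- max(abs(prof$sigma_zy_kPa))
  expect_lt(max(abs(prof$sigma_zy_kPa + prof$sigma_zy_kPa[rev_idx])) / szyref,
            1e-8)
})

test_that("interface shear extrema sit at the footprint periphery", {
  prof <- interface_shear_profile(base_sol)
  r <- base_model$cell_radius
  peak_y <- prof$y_um[which.max(abs(prof$sigma_zx_kPa))]
  expect_gt(abs(peak_y), 2 * r / 3) # outer third of the half-width
  edge <- max(abs(prof$sigma_zx_kPa[abs(abs(prof$y_um) - r) < 1e-6]))
  center <- abs(prof$sigma_zx_kPa[which.min(abs(prof$y_um))])
  expect_gt(edge, center)
  expect_error(interface_shear_profile(base_sol, x_position = 50),
               class = "podomech_bounds_error")
})

test_that("a free-floating cell under uniform eigenstrain is stress free", {
  m <- fem_test_model(substrate_modulus = "none")
  sol <- solve_contraction(m)
  expect_lt(max(abs(sol$stress)), 1e-10)
  # displacement field is the homogeneous contraction (linear in x)
  mesh <- sol$mesh
  exp_u <- sweep(mesh$nodes, 2, mesh$nodes[1, ]) # relative to first node
  exp_u <- sweep(exp_u, 2, m$contraction_level * m$eigenstrain_base, "*")
  rel <- sweep(sol$u, 2, sol$u[1, ])
  expect_lt(max(abs(rel - exp_u)), 1e-9)
})

test_that("zero contraction gives the zero solution", {
  m0 <- base_model
  m0$contraction_level <- 0
  s0 <- solve_contraction(m0, base_mesh)
  expect_equal(max(abs(s0$u)), 0)
  expect_equal(max(abs(s0$stress)), 0)
  prof0 <- interface_shear_profile(s0)
  expect_equal(max(abs(prof0$sigma_zx_kPa)), 0)
  expect_equal(cell_width_change(s0), 0)
})

test_that("all outputs scale exactly with the contraction level", {
  mh <- base_model
  mh$contraction_level <- 0.5
  sh <- solve_contraction(mh, base_mesh)
  expect_lt(max(abs(sh$u - 0.5 * base_sol$u)) / max(abs(base_sol$u)), 1e-8)
  expect_lt(max(abs(sh$stress - 0.5 * base_sol$stress)) /
              max(abs(base_sol$stress)), 1e-8)
  expect_equal(cell_width_change(sh), 0.5 * cell_width_change(base_sol),
               tolerance = 1e-8)
})

test_that("a very stiff substrate approaches the rigid-interface limit", {
  mr <- fem_test_model(substrate_modulus = "rigid")
  sr <- solve_contraction(mr)
  # substrate-side interface displacement is exactly zero by constraint
  iface <- which(abs(sr$mesh$nodes[, 3]) < 1e-9)
  expect_equal(max(abs(sr$u[iface, ])), 0)
  me <- fem_test_model(substrate_modulus = 1e4)
  se <- solve_contraction(me)
  pr <- interface_shear_profile(sr)
  pe <- interface_shear_profile(se)
  peak_r <- max(abs(pr$sigma_zx_kPa))
  peak_e <- max(abs(pe$sigma_zx_kPa))
  expect_lt(abs(peak_e - peak_r) / peak_r, 0.01)
  # emulated-rigid interface barely moves
  iface_e <- which(abs(se$mesh$nodes[, 3]) < 1e-9)
  expect_lt(max(abs(se$u[iface_e, ])) / max(abs(se$u)), 1e-3)
})

test_that("sweeps report per-combination summaries with monotonicity flags", {
  sw <- stiffness_sweep(c(0.9), levels = c(1.0), model = base_model)
  expect_equal(nrow(sw), 1)
  expect_true(all(c("max_abs_sigma_zx_kPa", "max_principal_cauchy_kPa",
                    "width_change_um") %in% names(sw)))
  expect_error(stiffness_sweep(numeric(), 1),
               class = "podomech_validation_error")
})
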
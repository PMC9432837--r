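test_that("Green-Lagrange kernel matches closed forms", {
  expect_equal(max(abs(green_lagrange(diag(2)))), 0)
  E <- green_lagrange(diag(c(1.1, 1)))
  expect_equal(E[1, 1], 0.105, tolerance = 1e-12)
  expect_equal(E[c(2, 3, 4)], rep(0, 3))
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(green_lagrange(R))), 1e-12)
  Esh <- green_lagrange(matrix(c(1, 0, 0.2, 1), 2, 2))
  expect_equal(Esh, matrix(c(0, 0.1, 0.1, 0.02), 2, 2), tolerance = 1e-12)
  expect_error(green_lagrange(diag(c(-1, 1))),
               class = "podomech_inverted_element_error")
})

test_that("principal strains come from the eigen-decomposition", {
  p <- principal_strain(diag(c(0.1, 0.02)))
  expect_equal(p$e1, 0.1)
  expect_equal(abs(p$direction), c(1, 0))
  p45 <- principal_strain(matrix(c(0, 0.1, 0.1, 0), 2, 2))
  expect_equal(p45$e1, 0.1)
  expect_equal(abs(p45$direction), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  for (seed in 1:20) {
    E <- withr::with_seed(seed, {
      a <- matrix(rnorm(4, sd = 0.1), 2, 2); (a + t(a)) / 2
    })
    p <- principal_strain(E)
    expect_lt(abs(p$e1 + p$e2 - sum(diag(E))), 1e-12)
    expect_gte(p$e1, p$e2)
  }
  expect_error(principal_strain(matrix(c(0, 0.1, 0.2, 0), 2, 2)),
               class = "podomech_validation_error")
})

test_that("bead matching is mutual-nearest-neighbor without double assignment", {
  pts <- withr::with_seed(4, cbind(runif(30, 0, 20), runif(30, 0, 20)))
  ident <- match_beads(pts, pts, max_disp = 1)
  expect_equal(ident$match_indices[, 1], ident$match_indices[, 2])
  expect_equal(nrow(ident$match_indices), 30)

  dom <- c(0, 30, 0, 30)
  tr <- generate_bead_field(deformation_spec("translation",
                                             list(tx = 0.3, ty = 0), dom),
                            density = 0.05, seed = 2)
  mb <- match_beads(tr$ref, tr$def, max_disp = 1)
  expect_equal(nrow(mb$match_indices), nrow(tr$ref))
  u <- mb$def[mb$match_indices[, 2], ] - mb$ref[mb$match_indices[, 1], ]
  expect_equal(u[, 1], rep(0.3, nrow(u)), tolerance = 1e-12)

  # ambiguous close pair: brute-force check on <= 10 beads
  ref <- rbind(c(5, 5), c(5.1, 5), c(10, 10), c(15, 5))
  def <- rbind(c(5.05, 5.3), c(10, 10.1), c(15.05, 5))
  amb <- match_beads(ref, def, max_disp = 0.5)
  expect_lte(max(table(amb$match_indices[, 1])), 1)
  expect_lte(max(table(amb$match_indices[, 2])), 1)
  d2 <- outer(ref[, 1], def[, 1], "-")^2 + outer(ref[, 2], def[, 2], "-")^2
  for (k in seq_len(nrow(amb$match_indices))) {
    i <- amb$match_indices[k, 1]; j <- amb$match_indices[k, 2]
    expect_equal(which.min(d2[i, ]), j) # mutual nearest neighbours
    expect_equal(which.min(d2[, j]), i)
  }
  expect_error(match_beads(rbind(c(0, 0)), rbind(c(10, 10)), max_disp = 1),
               class = "podomech_empty_field_error")
})

test_that("affine bead fields are recovered exactly at every grid point", {
  dom <- c(0, 40, 0, 40)
  def <- deformation_spec("imported_field", list(fun = function(pts) {
    F <- matrix(c(1.1, 0, 0, 0.95), 2, 2)
    list(pos = pts %*% t(F) + 0.5,
         F = matrix(rep(c(1.1, 0, 0, 0.95), each = nrow(pts)), ncol = 4))
  }), dom)
  bf <- generate_bead_field(def, density = 0.3, seed = 6)
  sf <- fit_deformation_gradient(bf, grid = 2, window_radius = 5)
  ok <- !is.na(sf$F11)
  expect_true(any(ok))
  err <- max(abs(cbind(sf$F11[ok] - 1.1, sf$F12[ok], sf$F21[ok],
                       sf$F22[ok] - 0.95)))
  expect_lt(err, 1e-8)
})

test_that("collinear bead neighborhoods are flagged undefined", {
  ref <- cbind(seq(0, 10, by = 0.5), 5) # all beads on a line
  field <- new_bead_field <- podomech:::new_bead_field(
    ref, ref, cbind(seq_len(nrow(ref)), seq_len(nrow(ref))))
  sf <- suppressWarnings(tryCatch(
    fit_deformation_gradient(field, grid = rbind(c(5, 5), c(5, 20)),
                             window_radius = 3),
    podomech_coverage_error = function(e) NULL))
  if (!is.null(sf)) expect_true(all(is.na(sf$F11)))
  else succeed() # every point undefined raises the coverage error
})

test_that("superposed rigid motion leaves the strain field unchanged", {
  dom <- c(0, 40, 0, 40)
  stretch <- deformation_spec("uniform_stretch",
                              list(lambda_x = 1.05, lambda_y = 0.98), dom)
  rigid_after <- compose_deformations(list(
    stretch,
    deformation_spec("rotation", list(theta = 0.35), dom),
    deformation_spec("translation", list(tx = 2, ty = -1), dom)))
  b1 <- generate_bead_field(stretch, density = 0.3, seed = 8)
  b2 <- generate_bead_field(rigid_after, density = 0.3, seed = 8)
  s1 <- add_strain_columns(fit_deformation_gradient(b1, grid = 4, window_radius = 5))
  s2 <- add_strain_columns(fit_deformation_gradient(b2, grid = 4, window_radius = 5))
  ok <- !is.na(s1$e1) & !is.na(s2$e1)
  expect_lt(max(abs(s1$E11[ok] - s2$E11[ok])), 1e-10)
  expect_lt(max(abs(s1$E12[ok] - s2$E12[ok])), 1e-10)
  expect_lt(max(abs(s1$e1[ok] - s2$e1[ok])), 1e-10)
})

test_that("noisy windows recover a 5% stretch with small bias", {
  # Monte-Carlo: 0.05-um localization noise, ~40 beads per window
  true_e1 <- (1.05^2 - 1) / 2
  reps <- 200
  e1 <- withr::with_seed(77, vapply(seq_len(reps), function(r) {
    ref <- cbind(runif(40, 0, 10), runif(40, 0, 10))
    def <- ref * 1.05 + matrix(rnorm(80, sd = 0.05), ncol = 2)
    field <- podomech:::new_bead_field(ref, def, cbind(1:40, 1:40))
    sf <- fit_deformation_gradient(field, grid = rbind(c(5, 5)),
                                   window_radius = 7.5)
    add_strain_columns(sf)$e1[1]
  }, numeric(1)))
  expect_lt(abs(mean(e1) - true_e1), 0.005)
})

test_that("the strain pipeline composes matching, fitting and summaries", {
  dom <- c(0, 40, 0, 40)
  tr <- generate_bead_field(deformation_spec("translation",
                                             list(tx = 0.4, ty = 0.1), dom),
                            density = 0.05, seed = 12)
  pip <- strain_pipeline(tr, grid = 2, window_radius = 5)
  expect_lt(max(abs(pip$field$e1), na.rm = TRUE), 1e-10)
  expect_lt(abs(pip$summary$max_e1), 1e-10)

  # relaxation measured from the contracted reference appears as extension
  con <- generate_bead_field(deformation_spec("radial_contraction",
                                              list(alpha = 0.05), dom),
                             density = 0.3, seed = 13)
  pip2 <- strain_pipeline(con$def, con$ref, grid = 2, window_radius = 5,
                          max_disp = 3)
  expect_gt(pip2$summary$mean_e1, 0)
})
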
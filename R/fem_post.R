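#' Interfacial shear stress profile across the cell footprint
#'
#' Samples the shear stress transmitted across the cell-substrate interface
#' (z = 0) along a line in the y direction at a given x station. Stresses are
#' recovered from the cell-side elements whose base face lies on the
#' interface, averaged to the interface nodes of the nearest grid column.
#' `sigma_zx` (shear acting in x on the xy plane) is even in y for this
#' y-mirror-symmetric geometry; `sigma_zy` is odd.
#'
#' @param solution a [solve_contraction()] result.
#' @param x_position x station of the line, um; default: mid-length of the
#'   cylindrical portion of the process.
#' @param summary_fn unused; reserved.
#' @return data frame with `y_um`, `sigma_zx_kPa`, `sigma_zy_kPa`, sorted by
#'   y, plus attributes `x_used` (grid x actually sampled) and `x_requested`.
#' @export
interface_shear_profile <- function(solution, x_position = NULL,
                                    summary_fn = NULL) {
  stopifnot(inherits(solution, "podomech_solution"))
  model <- solution$model
  mesh <- solution$mesh
  r <- model$cell_radius
  x0 <- -model$cell_length / 2
  xc <- model$cell_length / 2 - r
  if (is.null(x_position)) x_position <- (x0 + xc) / 2
  if (x_position < x0 || x_position > model$cell_length / 2)
    stop_podomech("x_position %.3g um outside the cell footprint [%.3g, %.3g]",
                  x_position, x0, model$cell_length / 2,
                  class = "podomech_bounds_error")
  nodal <- interface_nodal_stress(solution)
  xg <- mesh$axes$x[which.min(abs(mesh$axes$x - x_position))]
  sel <- abs(nodal$x - xg) < 1e-9
  if (!any(sel))
    stop_podomech("no interface nodes at x = %.3g um", xg,
                  class = "podomech_bounds_error")
  out <- data.frame(y_um = nodal$y[sel], sigma_zx_kPa = nodal$szx[sel],
                    sigma_zy_kPa = nodal$szy[sel])
  out <- out[order(out$y_um), ]
  rownames(out) <- NULL
  attr(out, "x_used") <- xg
  attr(out, "x_requested") <- x_position
  out
}

# Average the centroid stresses of interface-face cell elements onto their
# interface nodes. Returns per-node x, y, sigma_zx, sigma_zy.
interface_nodal_stress <- function(solution) {
  mesh <- solution$mesh
  z <- mesh$nodes[, 3]
  tol <- 1e-9
  on_iface <- abs(z) < tol
  cell_el <- which(solution$mesh$region == "cell")
  corner_on <- matrix(on_iface[mesh$elems[cell_el, 1:4]], length(cell_el), 4)
  base_el <- cell_el[rowSums(corner_on) >= 3]
  if (length(base_el) == 0)
    stop_podomech("no cell elements on the interface",
                  class = "podomech_bounds_error")
  # node-element incidence restricted to interface nodes
  nd <- as.vector(mesh$elems[base_el, ])
  el <- rep(base_el, times = 10)
  keep <- on_iface[nd]
  nd <- nd[keep]; el <- el[keep]
  szx <- tapply(solution$stress[el, "xz"], nd, mean)
  szy <- tapply(solution$stress[el, "yz"], nd, mean)
  ids <- as.integer(names(szx))
  list(x = mesh$nodes[ids, 1], y = mesh$nodes[ids, 2],
       szx = as.numeric(szx), szy = as.numeric(szy), node = ids)
}

#' Lateral width change of the contracted cell
#'
#' Signed difference of the lateral (y) displacement across the cell
#' midsection, measured between the two footprint-edge interface nodes of
#' the grid column nearest `x_position`: `u_y(+edge) - u_y(-edge)`. Negative
#' values mean narrowing.
#'
#' @inheritParams interface_shear_profile
#' @return width change in um (negative = narrowing).
#' @export
cell_width_change <- function(solution, x_position = NULL) {
  stopifnot(inherits(solution, "podomech_solution"))
  model <- solution$model
  mesh <- solution$mesh
  if (is.null(x_position))
    x_position <- (-model$cell_length / 2 + model$cell_length / 2 -
                     model$cell_radius) / 2
  z <- mesh$nodes[, 3]
  tol <- 1e-9
  cell_nodes <- unique(as.vector(mesh$elems[mesh$region == "cell", ]))
  base <- cell_nodes[abs(z[cell_nodes]) < tol]
  xg <- mesh$axes$x[which.min(abs(mesh$axes$x - x_position))]
  col <- base[abs(mesh$nodes[base, 1] - xg) < 1e-9]
  if (length(col) < 2)
    stop_podomech("no interface node column at x = %.3g um", xg,
                  class = "podomech_bounds_error")
  top <- col[which.max(mesh$nodes[col, 2])]
  bot <- col[which.min(mesh$nodes[col, 2])]
  solution$u[top, 2] - solution$u[bot, 2]
}

#' Maximum principal Cauchy stress per element
#'
#' Largest eigenvalue of the 3 x 3 Cauchy stress tensor at each element
#' centroid, computed by the trigonometric closed form for symmetric
#' matrices.
#'
#' @param solution a [solve_contraction()] result.
#' @return numeric vector (kPa), one value per element.
#' @export
max_principal_cauchy <- function(solution) {
  s <- solution$stress
  s11 <- s[, "xx"]; s22 <- s[, "yy"]; s33 <- s[, "zz"]
  s23 <- s[, "yz"]; s13 <- s[, "xz"]; s12 <- s[, "xy"]
  q <- (s11 + s22 + s33) / 3
  p2 <- (s11 - q)^2 + (s22 - q)^2 + (s33 - q)^2 +
    2 * (s12^2 + s13^2 + s23^2)
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  b11 <- (s11 - q) / p; b22 <- (s22 - q) / p; b33 <- (s33 - q) / p
  b12 <- s12 / p; b13 <- s13 / p; b23 <- s23 / p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  rr <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(rr) / 3
  out[nz] <- (q + 2 * p * cos(phi))[nz]
  out
}

#' Substrate stiffness and contractility sweep
#'
#' Solves the contraction model over a grid of substrate moduli and
#' contraction levels, reporting for each combination the peak interfacial
#' shear `max |sigma_zx|` along the default y line, the maximum principal
#' Cauchy stress over all elements, and the cell width change. Monotonicity
#' of the stress measures in the substrate modulus (at each level) is
#' reported as an attribute.
#'
#' @param moduli numeric vector of substrate moduli, kPa.
#' @param levels numeric vector of contraction levels in (0, 1].
#' @param model template [contraction_model()] supplying everything else.
#' @param x_position x station for the shear profile (default: mid-cylinder).
#' @return data frame with one row per (modulus, level):
#'   `substrate_modulus_kPa`, `contraction_level`, `max_abs_sigma_zx_kPa`,
#'   `max_principal_cauchy_kPa`, `width_change_um`; attribute
#'   `monotone_in_modulus` (named logical: shear, principal).
#' @export
stiffness_sweep <- function(moduli, levels = 1.0,
                            model = contraction_model(),
                            x_position = NULL) {
  if (length(moduli) == 0 || length(levels) == 0)
    stop_podomech("moduli and levels must be non-empty",
                  class = "podomech_validation_error")
  mesh <- build_mesh(model)
  rows <- NULL
  for (Es in moduli) for (lev in levels) {
    m <- model
    m$substrate_modulus <- Es
    m$contraction_level <- lev
    sol <- solve_contraction(m, mesh)
    prof <- interface_shear_profile(sol, x_position)
    rows <- rbind(rows, data.frame(
      substrate_modulus_kPa = Es, contraction_level = lev,
      max_abs_sigma_zx_kPa = max(abs(prof$sigma_zx_kPa)),
      max_principal_cauchy_kPa = max(max_principal_cauchy(sol)),
      width_change_um = cell_width_change(sol, x_position)))
  }
  mono <- c(shear = TRUE, principal = TRUE)
  for (lev in levels) {
    sub <- rows[rows$contraction_level == lev, ]
    sub <- sub[order(sub$substrate_modulus_kPa), ]
    if (nrow(sub) > 1) {
      mono["shear"] <- mono["shear"] && !is.unsorted(sub$max_abs_sigma_zx_kPa,
                                                     strictly = TRUE)
      mono["principal"] <- mono["principal"] &&
        !is.unsorted(sub$max_principal_cauchy_kPa, strictly = TRUE)
    }
  }
  attr(rows, "monotone_in_modulus") <- mono
  rows
}

#' Export a solution as a legacy VTK file
#'
#' Writes the quadratic tetrahedral mesh with nodal displacements and
#' element stresses in ASCII legacy VTK format, viewable in ParaView.
#'
#' @param solution a [solve_contraction()] result.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_solution_vtk <- function(solution, path) {
  mesh <- solution$mesh
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "podomech contraction solution",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * 11), con)
  utils::write.table(cbind(10L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(24L, ne)), con) # VTK_QUADRATIC_TETRA
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS displacement double"), con)
  utils::write.table(solution$u, con, row.names = FALSE, col.names = FALSE)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS max_principal_stress double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(max_principal_cauchy(solution)), con)
  invisible(path)
}
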
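#' Match beads between reference and deformed frames
#'
#' Mutual-nearest-neighbor pairing within a displacement cutoff: a reference
#' bead and a deformed bead are matched only if each is the other's nearest
#' neighbor and they lie within `max_disp`. Ambiguous beads are dropped, never
#' double-assigned.
#'
#' @param ref,def n x 2 matrices of bead positions, um.
#' @param max_disp maximum admissible displacement, um.
#' @return a `bead_field` with `match_indices` (pairs of row indices into
#'   `ref` and `def`) and the unmatched indices of both frames.
#' @export
match_beads <- function(ref, def, max_disp) {
  ref <- as.matrix(ref); def <- as.matrix(def)
  if (max_disp <= 0)
    stop_podomech("max_disp must be > 0", class = "podomech_validation_error")
  d2 <- outer(ref[, 1], def[, 1], "-")^2 + outer(ref[, 2], def[, 2], "-")^2
  nn_rd <- apply(d2, 1, which.min) # for each ref, nearest def
  nn_dr <- apply(d2, 2, which.min) # for each def, nearest ref
  i <- seq_len(nrow(ref))
  mutual <- nn_dr[nn_rd[i]] == i &
    d2[cbind(i, nn_rd[i])] <= max_disp^2
  pairs <- cbind(i[mutual], nn_rd[i][mutual])
  if (nrow(pairs) == 0)
    stop_podomech("no bead pairs matched within max_disp = %g um", max_disp,
                  class = "podomech_empty_field_error")
  new_bead_field(ref, def, pairs,
                 unmatched_ref = setdiff(i, pairs[, 1]),
                 unmatched_def = setdiff(seq_len(nrow(def)), pairs[, 2]))
}

#' Fit a deformation-gradient field by windowed weighted affine fits
#'
#' At each grid point, beads within `window_radius` are fit by weighted least
#' squares to the local affine model `x_def ~ F x_ref + t` with Gaussian
#' weights (sd = `window_radius / 2`). The fit is exact on affine bead fields
#' regardless of layout. Grid points with fewer than `min_neighbors` beads, or
#' with a degenerate (collinear) neighborhood, are flagged undefined.
#'
#' @param field a `bead_field`.
#' @param grid m x 2 matrix of grid points (um), or a single number taken as
#'   a grid spacing over the bounding box of the matched reference beads.
#' @param window_radius fitting window radius, um.
#' @param min_neighbors minimum beads required for a defined fit.
#' @return an object of class `strain_field`: data frame with `x`, `y`,
#'   `F11`, `F12`, `F21`, `F22` and `support_count`; undefined points carry
#'   NA gradients.
#' @export
fit_deformation_gradient <- function(field, grid = 2, window_radius = 5,
                                     min_neighbors = 4) {
  stopifnot(inherits(field, "bead_field"))
  if (window_radius <= 0)
    stop_podomech("window_radius must be > 0",
                  class = "podomech_validation_error")
  mi <- field$match_indices
  xr <- field$ref[mi[, 1], , drop = FALSE]
  xd <- field$def[mi[, 2], , drop = FALSE]
  if (!is.matrix(grid)) {
    h <- as.numeric(grid)
    gx <- seq(min(xr[, 1]), max(xr[, 1]), by = h)
    gy <- seq(min(xr[, 2]), max(xr[, 2]), by = h)
    grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  }
  sigw <- window_radius / 2
  m <- nrow(grid)
  out <- matrix(NA_real_, m, 4)
  support <- integer(m)
  for (k in seq_len(m)) {
    d2 <- (xr[, 1] - grid[k, 1])^2 + (xr[, 2] - grid[k, 2])^2
    nb <- which(d2 <= window_radius^2)
    support[k] <- length(nb)
    if (length(nb) < max(min_neighbors, 3)) next
    w <- exp(-d2[nb] / (2 * sigw^2))
    A <- cbind(xr[nb, 1], xr[nb, 2], 1)
    Aw <- A * sqrt(w)
    sv <- svd(Aw, nu = 0, nv = 0)$d
    if (sv[3] < 1e-8 * sv[1]) next # collinear neighborhood
    coef <- qr.solve(crossprod(Aw), crossprod(A * w, xd[nb, , drop = FALSE]))
    out[k, ] <- c(coef[1, 1], coef[2, 1], coef[1, 2], coef[2, 2])
  }
  if (all(is.na(out[, 1])))
    stop_podomech("no grid point has sufficient bead coverage",
                  class = "podomech_coverage_error")
  structure(data.frame(x = grid[, 1], y = grid[, 2], F11 = out[, 1],
                       F12 = out[, 2], F21 = out[, 3], F22 = out[, 4],
                       support_count = support),
            class = c("strain_field", "data.frame"))
}

#' Green-Lagrange strain tensor from a deformation gradient
#'
#' `E = (F^T F - I) / 2`; symmetric by construction and exactly zero for any
#' rigid motion (objectivity).
#'
#' @param F 2 x 2 deformation gradient with `det F > 0`.
#' @return 2 x 2 symmetric Green-Lagrange tensor.
#' @export
green_lagrange <- function(F) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0)
    stop_podomech("det F = %.3g <= 0: inverted configuration", det(F),
                  class = "podomech_inverted_element_error")
  0.5 * (t(F) %*% F - diag(2))
}

#' Principal Green-Lagrange strains
#'
#' Eigen-decomposition of a symmetric 2 x 2 strain tensor: `e1 >= e2`, with
#' the unit direction of the first principal strain.
#'
#' @param E 2 x 2 symmetric tensor (symmetry checked to 1e-8).
#' @return list with `e1`, `e2` and `direction` (unit 2-vector of e1).
#' @export
principal_strain <- function(E) {
  E <- matrix(as.numeric(E), 2, 2)
  if (abs(E[1, 2] - E[2, 1]) > 1e-8)
    stop_podomech("strain tensor is not symmetric",
                  class = "podomech_validation_error")
  E[1, 2] <- E[2, 1] <- (E[1, 2] + E[2, 1]) / 2
  eg <- eigen(E, symmetric = TRUE)
  list(e1 = eg$values[1], e2 = eg$values[2], direction = eg$vectors[, 1])
}

#' Append Green-Lagrange and principal strain columns to a strain field
#'
#' Vectorised over all grid points: adds `E11`, `E12`, `E22` (from
#' `E = (F^T F - I) / 2`) and the principal values `e1 >= e2`.
#'
#' @param sf a `strain_field` from [fit_deformation_gradient()].
#' @return the data frame with strain columns appended.
#' @export
add_strain_columns <- function(sf) {
  E11 <- 0.5 * (sf$F11^2 + sf$F21^2 - 1)
  E22 <- 0.5 * (sf$F12^2 + sf$F22^2 - 1)
  E12 <- 0.5 * (sf$F11 * sf$F12 + sf$F21 * sf$F22)
  tr <- E11 + E22
  disc <- sqrt(pmax(((E11 - E22) / 2)^2 + E12^2, 0))
  sf$E11 <- E11; sf$E12 <- E12; sf$E22 <- E22
  sf$e1 <- tr / 2 + disc
  sf$e2 <- tr / 2 - disc
  sf
}

#' Full strain-mapping pipeline from two bead frames
#'
#' Matches beads, fits the deformation-gradient field on a reference grid
#' (Lagrangian sampling), derives the Green-Lagrange tensor and its first
#' principal value at every defined grid point, and summarises the field.
#' The reference state is the pre-treatment frame, so relaxation after an
#' actin-disrupting drug appears as positive (extension) strain.
#'
#' @param ref,def bead positions of the two frames (n x 2, um), or a
#'   `bead_field` passed as `ref` (then `def` is ignored).
#' @param grid grid spacing (um) or explicit grid points.
#' @param window_radius fitting window radius, um.
#' @param max_disp matching cutoff, um.
#' @param min_neighbors minimum beads per window.
#' @param mask optional `function(x, y) -> logical` selecting grid points for
#'   the mask summary (e.g. the under-cell region); default: interior points
#'   at least `window_radius` from the grid bounding box.
#' @return list with `field` (a `strain_field` with E and principal columns)
#'   and `summary` (max and mean `e1` over defined masked points, plus
#'   counts).
#' @export
strain_pipeline <- function(ref, def = NULL, grid = 2, window_radius = 5,
                            max_disp = 2, min_neighbors = 4, mask = NULL) {
  field <- if (inherits(ref, "bead_field")) ref
           else match_beads(ref, def, max_disp)
  sf <- fit_deformation_gradient(field, grid, window_radius, min_neighbors)
  sf <- add_strain_columns(sf)
  ok <- !is.na(sf$e1)
  if (is.null(mask)) {
    rx <- range(sf$x); ry <- range(sf$y)
    inmask <- sf$x >= rx[1] + window_radius & sf$x <= rx[2] - window_radius &
      sf$y >= ry[1] + window_radius & sf$y <= ry[2] - window_radius
  } else inmask <- mask(sf$x, sf$y)
  use <- ok & inmask
  summary <- list(max_e1 = if (any(use)) max(sf$e1[use]) else NA_real_,
                  mean_e1 = if (any(use)) mean(sf$e1[use]) else NA_real_,
                  n_defined = sum(ok), n_masked = sum(use),
                  n_grid = nrow(sf))
  list(field = sf, summary = summary)
}

#' Write a strain field to CSV
#'
#' Columns `x, y, F11..F22, E11, E12, E22, e1` (strain columns added if
#' absent).
#'
#' @param sf a `strain_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(sf, path) {
  if (!"e1" %in% names(sf)) sf <- add_strain_columns(sf)
  write.csv(as.data.frame(sf), path, row.names = FALSE)
  invisible(path)
}
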
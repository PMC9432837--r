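#' Eigenstrain contraction model of a cell process on an elastic substrate
#'
#' Geometry and material parameters for the finite-element model: a cell
#' process shaped as half of a cylinder capped by a quarter sphere (radius
#' 4 um), bonded to a slab substrate (100 x 100 x 10 um) whose base is fixed
#' and whose sides are traction free. Contractility is an anisotropic
#' stress-free eigenstrain prescribed in the cell volume:
#' `contraction_level * (-10%, -8%, -2%)` along x, y, z, the x axis being the
#' fiber/micropattern direction. Both bodies are isotropic linear elastic.
#'
#' @param cell_modulus cell elastic modulus, kPa.
#' @param cell_poisson cell Poisson ratio, in (0, 0.5).
#' @param substrate_modulus substrate elastic modulus in kPa (physiologic to
#'   pathologic range 0.2-6.0), or `"rigid"` (glass: interface displacements
#'   fixed), or `"none"` (free-floating cell, rigid-body constraints only —
#'   used for patch tests).
#' @param substrate_poisson substrate Poisson ratio.
#' @param cell_radius radius of cylinder and cap, um.
#' @param cell_length total footprint length of the process, um (cylinder
#'   plus cap; must be >= `cell_radius`).
#' @param substrate_size `c(width, length)` of the substrate slab, um.
#' @param substrate_thickness substrate thickness, um.
#' @param eigenstrain_base full-contraction eigenstrain `c(ex, ey, ez)`
#'   (negative = contraction).
#' @param contraction_level scale factor in (0, 1] applied to the eigenstrain
#'   (1 = full, 0.5 / 0.2 = attenuated contractility, e.g. blebbistatin);
#'   0 is admitted for null tests.
#' @param mesh_resolution number of elements across the cell radius (>= 3).
#' @return an object of class `contraction_model`.
#' @export
contraction_model <- function(cell_modulus = 1.0, cell_poisson = 0.3,
                              substrate_modulus = 0.9, substrate_poisson = 0.3,
                              cell_radius = 4, cell_length = 20,
                              substrate_size = c(100, 100),
                              substrate_thickness = 10,
                              eigenstrain_base = c(-0.10, -0.08, -0.02),
                              contraction_level = 1.0, mesh_resolution = 4) {
  rigid <- identical(substrate_modulus, "rigid")
  none <- identical(substrate_modulus, "none")
  if (!rigid && !none &&
      (!is.numeric(substrate_modulus) || substrate_modulus <= 0))
    stop_podomech("substrate_modulus must be > 0, \"rigid\" or \"none\"",
                  class = "podomech_validation_error")
  if (cell_modulus <= 0)
    stop_podomech("cell_modulus must be > 0", class = "podomech_validation_error")
  for (p in c(cell_poisson, substrate_poisson))
    if (p <= 0 || p >= 0.5)
      stop_podomech("Poisson ratios must lie in (0, 0.5)",
                    class = "podomech_validation_error")
  if (any(abs(eigenstrain_base) >= 0.5))
    stop_podomech("|eigenstrain| must be < 0.5",
                  class = "podomech_validation_error")
  if (contraction_level < 0 || contraction_level > 1)
    stop_podomech("contraction_level must lie in [0, 1]",
                  class = "podomech_validation_error")
  if (cell_length < cell_radius)
    stop_podomech("degenerate geometry: cell_length %g < cell_radius %g",
                  cell_length, cell_radius, class = "podomech_validation_error")
  if (mesh_resolution < 3)
    stop_podomech("mesh_resolution must be >= 3",
                  class = "podomech_validation_error")
  structure(list(cell_modulus = cell_modulus, cell_poisson = cell_poisson,
                 substrate_modulus = substrate_modulus,
                 substrate_poisson = substrate_poisson,
                 cell_radius = cell_radius, cell_length = cell_length,
                 substrate_size = substrate_size,
                 substrate_thickness = substrate_thickness,
                 eigenstrain_base = eigenstrain_base,
                 contraction_level = contraction_level,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "contraction_model")
}

# Graded symmetric 1D axis: uniform spacing ~h0 over [-fine_hw, fine_hw],
# geometric coarsening (ratio `growth`) out to +/- outer_hw.
graded_axis <- function(fine_hw, outer_hw, h0, growth = 1.6) {
  nf <- max(1, ceiling(fine_hw / h0))
  pos <- seq(0, fine_hw, length.out = nf + 1)
  h <- fine_hw / nf
  while (pos[length(pos)] < outer_hw - 1e-9) {
    h <- h * growth
    nxt <- min(pos[length(pos)] + h, outer_hw)
    if (outer_hw - nxt < 0.35 * h) nxt <- outer_hw
    pos <- c(pos, nxt)
  }
  sort(unique(c(-rev(pos), pos)))
}

# Substrate depth axis: spacing ~h0 at the interface, geometric growth down.
depth_axis <- function(thickness, h0, growth = 1.7) {
  z <- 0; h <- h0
  while (z[length(z)] > -thickness + 1e-9) {
    nxt <- max(z[length(z)] - h, -thickness)
    if (nxt + thickness < 0.35 * h) nxt <- -thickness
    z <- c(z, nxt)
    h <- h * growth
  }
  rev(z)
}

inside_cell <- function(x, y, z, model) {
  r <- model$cell_radius
  xc <- model$cell_length / 2 - r # cap center x
  x0 <- -model$cell_length / 2
  cyl <- x >= x0 & x <= xc & (y^2 + z^2 <= r^2)
  cap <- x > xc & ((x - xc)^2 + y^2 + z^2 <= r^2)
  (cyl | cap) & z >= 0
}

# 5-tetrahedra split of a hexahedron, alternating chirality by hex parity so
# that face diagonals of neighboring hexes coincide (conforming mesh) and a
# mirror-symmetric grid with an even cell count stays exactly symmetric.
# Local vertex ids: 1..8 = (0,0,0),(1,0,0),(0,1,0),(1,1,0),
#                          (0,0,1),(1,0,1),(0,1,1),(1,1,1)
TET5 <- list(
  even = rbind(c(1, 2, 3, 5), c(4, 3, 2, 8), c(6, 5, 8, 2), c(7, 8, 5, 3),
               c(2, 3, 5, 8)),
  odd  = rbind(c(2, 1, 4, 6), c(3, 4, 1, 7), c(5, 6, 7, 1), c(8, 7, 6, 4),
               c(1, 4, 6, 7)))

#' Build a conforming quadratic-tetrahedron mesh for a contraction model
#'
#' The cell and substrate are meshed together from a graded tensor-product
#' hexahedral grid (spacing `cell_radius / mesh_resolution` near the cell,
#' geometric coarsening toward the slab edges), each hexahedron split into
#' five tetrahedra with alternating chirality, then promoted to 10-node
#' quadratic tetrahedra via shared edge midpoints. Cell elements are those
#' hexahedra (above the interface plane z = 0) whose centroid falls inside
#' the half-cylinder + quarter-sphere; interface nodes are shared between the
#' two bodies (perfect bonding). The grid is mirror symmetric in y.
#'
#' @param model a [contraction_model()].
#' @return an object of class `podomech_mesh`: list with `nodes` (n x 3, um),
#'   `elems` (ne x 10 integer), `region` (`"cell"`/`"substrate"` per
#'   element), `h0`, `axes`, `n_vertex` and the generating `model` geometry.
#' @export
build_mesh <- function(model) {
  stopifnot(inherits(model, "contraction_model"))
  r <- model$cell_radius
  h0 <- r / model$mesh_resolution
  Lc <- model$cell_length
  cell_only <- identical(model$substrate_modulus, "rigid") ||
    identical(model$substrate_modulus, "none")
  xs <- graded_axis(Lc / 2 + h0, if (cell_only) Lc / 2 + h0 else
    model$substrate_size[1] / 2, h0)
  ys <- graded_axis(r + h0, if (cell_only) r + h0 else
    model$substrate_size[2] / 2, h0)
  z_cell <- seq(0, r, length.out = model$mesh_resolution + 1)
  zs <- if (cell_only) z_cell else
    c(depth_axis(model$substrate_thickness, h0), z_cell[-1])
  nx <- length(xs) - 1; ny <- length(ys) - 1; nz <- length(zs) - 1
  # hex classification by centroid
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  cz <- (zs[-1] + zs[-length(zs)]) / 2
  hx <- rep(seq_len(nx), times = ny * nz)
  hy <- rep(rep(seq_len(ny), each = nx), times = nz)
  hz <- rep(seq_len(nz), each = nx * ny)
  cen_x <- cx[hx]; cen_y <- cy[hy]; cen_z <- cz[hz]
  is_sub <- cen_z < 0
  is_cell <- cen_z > 0 & inside_cell(cen_x, cen_y, cen_z, model)
  keep <- if (cell_only) is_cell else (is_sub | is_cell)
  hx <- hx[keep]; hy <- hy[keep]; hz <- hz[keep]
  region_hex <- ifelse(is_cell[keep], "cell", "substrate")
  nhex <- length(hx)
  if (nhex == 0)
    stop_podomech("empty mesh", class = "podomech_validation_error")
  # global vertex ids on the full grid
  nvx <- nx + 1L; nvy <- ny + 1L
  vid <- function(i, j, k) (k - 1) * (nvx * nvy) + (j - 1) * nvx + i
  corner <- matrix(0, nhex, 8)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  for (c8 in 1:8)
    corner[, c8] <- vid(hx + offs[c8, 1], hy + offs[c8, 2], hz + offs[c8, 3])
  parity <- (hx + hy + hz) %% 2
  tet4 <- matrix(0L, 5L * nhex, 4L)
  for (t in 1:5) {
    loc_e <- TET5$even[t, ]; loc_o <- TET5$odd[t, ]
    rows <- seq.int(t, by = 5L, length.out = nhex)
    pick <- ifelse(parity == 0, 1L, 2L)
    sel <- rbind(loc_e, loc_o)[pick, , drop = FALSE]
    for (c4 in 1:4)
      tet4[rows, c4] <- corner[cbind(seq_len(nhex), sel[, c4])]
  }
  region <- rep(region_hex, each = 5)
  # compact vertex numbering
  used <- sort(unique(as.vector(tet4)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tet4[] <- remap[tet4]
  gi <- ((used - 1) %% nvx) + 1
  gj <- ((used - 1) %/% nvx) %% nvy + 1
  gk <- (used - 1) %/% (nvx * nvy) + 1
  verts <- cbind(xs[gi], ys[gj], zs[gk])
  nv <- nrow(verts)
  # fix orientation (positive volume)
  v6 <- tet_signed_volume(verts, tet4)
  flip <- v6 < 0
  if (any(flip)) tet4[flip, c(3, 4)] <- tet4[flip, c(4, 3)]
  # quadratic promotion: shared edge midpoints; edge order matches the
  # element kernels: (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)
  ep <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  ekey <- matrix(0, nrow(tet4), 6)
  for (e in 1:6) {
    a <- tet4[, ep[e, 1]]; b <- tet4[, ep[e, 2]]
    ekey[, e] <- pmin(a, b) * (nv + 1) + pmax(a, b)
  }
  ukey <- sort(unique(as.vector(ekey)))
  eid <- matrix(match(ekey, ukey), nrow(tet4), 6) + nv
  ua <- floor(ukey / (nv + 1)); ub <- ukey - ua * (nv + 1)
  midpts <- (verts[ua, , drop = FALSE] + verts[ub, , drop = FALSE]) / 2
  nodes <- rbind(verts, midpts)
  elems <- cbind(tet4, eid)
  storage.mode(elems) <- "integer"
  structure(list(nodes = nodes, elems = elems, region = region, h0 = h0,
                 axes = list(x = xs, y = ys, z = zs), n_vertex = nv,
                 model = model),
            class = "podomech_mesh")
}

tet_signed_volume <- function(verts, tet4) {
  a <- verts[tet4[, 1], , drop = FALSE]
  b <- verts[tet4[, 2], , drop = FALSE] - a
  c <- verts[tet4[, 3], , drop = FALSE] - a
  d <- verts[tet4[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Mesh quality and conformity report
#'
#' @param mesh a [build_mesh()] result.
#' @return list with element/node counts per region, volume statistics, and
#'   `interface_conforming`: whether every interface node of the cell is
#'   shared with the substrate (vacuously TRUE for cell-only meshes).
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "podomech_mesh"))
  vol <- tet_signed_volume(mesh$nodes, mesh$elems[, 1:4])
  zs <- mesh$nodes[, 3]
  tol <- 1e-9
  iface_cell <- unique(as.vector(mesh$elems[mesh$region == "cell", ]))
  iface_cell <- iface_cell[abs(zs[iface_cell]) < tol]
  conforming <- TRUE
  if (any(mesh$region == "substrate")) {
    sub_nodes <- unique(as.vector(mesh$elems[mesh$region == "substrate", ]))
    conforming <- all(iface_cell %in% sub_nodes)
  }
  list(n_elements = nrow(mesh$elems),
       n_cell_elements = sum(mesh$region == "cell"),
       n_substrate_elements = sum(mesh$region == "substrate"),
       n_nodes = nrow(mesh$nodes),
       min_volume = min(vol), max_volume = max(vol),
       total_volume = sum(vol),
       n_interface_nodes = length(iface_cell),
       interface_conforming = conforming)
}

#' @export
print.podomech_mesh <- function(x, ...) {
  cat(sprintf(
    "podomech_mesh: %d tet10 elements (%d cell, %d substrate), %d nodes, h0 = %.3g um\n",
    nrow(x$elems), sum(x$region == "cell"), sum(x$region == "substrate"),
    nrow(x$nodes), x$h0))
  invisible(x)
}
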
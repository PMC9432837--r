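#' Solve the eigenstrain contraction problem
#'
#' Small-strain linear elasticity with the anisotropic eigenstrain applied in
#' the cell volume only: cell stress is `C : (eps - eps*)`, substrate stress
#' `C : eps`. Boundary conditions: substrate base fully fixed, substrate
#' sides and cell surface traction free. For a `"rigid"` substrate the cell
#' base (z = 0) is fixed instead; for `"none"` the free-floating cell is
#' restrained by minimal rigid-body constraints compatible with a uniform
#' eigenstrain (3-2-1 scheme on grid-aligned nodes).
#'
#' @param model a [contraction_model()].
#' @param mesh optional [build_mesh()] result (built from `model` if absent).
#' @return an object of class `podomech_solution`: list with `u` (n x 3 nodal
#'   displacements, um), `stress` (ne x 6 Cauchy stress per element centroid,
#'   kPa, Voigt order xx, yy, zz, yz, xz, xy), `centroids`, `volumes`,
#'   `reaction_sum` (net reaction force per component, kPa um^2),
#'   `equilibrium_residual` (relative residual on free DOFs), `mesh`,
#'   `model`.
#' @export
solve_contraction <- function(model, mesh = NULL) {
  stopifnot(inherits(model, "contraction_model"))
  if (is.null(mesh)) mesh <- build_mesh(model)
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  is_cell <- mesh$region == "cell"
  Emod <- ifelse(is_cell, model$cell_modulus,
                 if (is.numeric(model$substrate_modulus))
                   model$substrate_modulus else NA_real_)
  nu <- ifelse(is_cell, model$cell_poisson, model$substrate_poisson)
  eig <- matrix(0, ne, 6)
  eig[is_cell, 1:3] <- matrix(model$contraction_level * model$eigenstrain_base,
                              sum(is_cell), 3, byrow = TRUE)
  asm <- .fem_assemble(mesh$nodes, mesh$elems, Emod, nu, eig)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                            dims = c(3 * nn, 3 * nn), symmetric = TRUE)
  f <- asm$f
  fixed <- fixed_dofs(model, mesh)
  free <- setdiff(seq_len(3 * nn), fixed)
  Kff <- Matrix::forceSymmetric(K[free, free], uplo = "L")
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
  u <- numeric(3 * nn)
  u[free] <- as.numeric(Matrix::solve(ch, f[free]))
  resid <- as.numeric(K %*% u - f)
  fnorm <- sqrt(sum(f[free]^2))
  rel_resid <- if (fnorm > 0) sqrt(sum(resid[free]^2)) / fnorm else
    sqrt(sum(resid[free]^2))
  reactions <- resid[fixed]
  comp <- (fixed - 1) %% 3 + 1
  reaction_sum <- vapply(1:3, function(d) sum(reactions[comp == d]), numeric(1))
  stress <- .fem_element_stress(mesh$nodes, mesh$elems, Emod, nu, eig, u)
  colnames(stress) <- c("xx", "yy", "zz", "yz", "xz", "xy")
  centroids <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
                mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  structure(list(u = matrix(u, nn, 3, byrow = TRUE),
                 stress = stress, centroids = centroids, volumes = asm$vol,
                 reaction_sum = reaction_sum,
                 equilibrium_residual = rel_resid,
                 mesh = mesh, model = model),
            class = "podomech_solution")
}

fixed_dofs <- function(model, mesh) {
  z <- mesh$nodes[, 3]
  tol <- 1e-9
  if (identical(model$substrate_modulus, "rigid")) {
    nodes <- which(abs(z) < tol)
    return(sort(c(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * nodes)))
  }
  if (identical(model$substrate_modulus, "none")) {
    # 3-2-1 rigid-body constraints on base-plane nodes sharing grid lines,
    # compatible with any homogeneous diagonal eigenstrain
    base <- which(abs(z) < tol)
    xy <- mesh$nodes[base, 1:2, drop = FALSE]
    A <- base[order(xy[, 2], xy[, 1])][1]
    sameyz <- base[abs(mesh$nodes[base, 2] - mesh$nodes[A, 2]) < tol]
    B <- sameyz[which.max(mesh$nodes[sameyz, 1])]
    othery <- base[abs(mesh$nodes[base, 2] - mesh$nodes[A, 2]) > tol]
    C <- othery[which.max(mesh$nodes[othery, 2])]
    return(sort(c(3 * (A - 1) + 1:3, 3 * (B - 1) + 2:3, 3 * C)))
  }
  nodes <- which(abs(z - min(z)) < tol)
  sort(c(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * nodes))
}

#' @export
print.podomech_solution <- function(x, ...) {
  cat(sprintf(
    "podomech_solution: %d nodes, %d elements; relative residual %.2e\n",
    nrow(x$u), nrow(x$stress), x$equilibrium_residual))
  cat(sprintf("  max |u| = %.4g um, max principal Cauchy stress = %.4g kPa\n",
              max(sqrt(rowSums(x$u^2))), max(max_principal_cauchy(x))))
  invisible(x)
}
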
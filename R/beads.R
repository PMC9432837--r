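#' Specification of a planar deformation applied to a bead cloud
#'
#' Forward model for testing strain mapping: an analytic 2D map with a known,
#' spatially resolved deformation gradient. Rotations, stretches, shears and
#' radial contractions act about the domain center.
#'
#' @param kind one of `"translation"`, `"rotation"`, `"uniform_stretch"`,
#'   `"simple_shear"`, `"radial_contraction"`, `"imported_field"`.
#' @param parameters named list of per-kind scalars:
#'   * translation: `tx`, `ty` (um)
#'   * rotation: `theta` (radians, counterclockwise)
#'   * uniform_stretch: `lambda_x`, `lambda_y` (> 0)
#'   * simple_shear: `gamma` (x displaced by `gamma * (y - yc)`)
#'   * radial_contraction: `alpha` in (0, 1); points move toward the center by
#'     the fraction `alpha` of their radius
#'   * imported_field: `fun`, a function `(pts) -> list(pos = n x 2, F = n x 4)`
#'     defined on the whole domain (F columns F11, F12, F21, F22)
#' @param domain `c(xmin, xmax, ymin, ymax)` rectangle, um.
#' @return an object of class `deformation_spec`.
#' @export
deformation_spec <- function(kind, parameters = list(),
                             domain = c(0, 50, 0, 50)) {
  kinds <- c("translation", "rotation", "uniform_stretch", "simple_shear",
             "radial_contraction", "imported_field")
  kind <- match.arg(kind, kinds)
  if (kind == "uniform_stretch") {
    lx <- parameters$lambda_x %||% parameters$lambda
    ly <- parameters$lambda_y %||% parameters$lambda
    if (is.null(lx) || is.null(ly) || lx <= 0 || ly <= 0)
      stop_podomech("uniform_stretch needs lambda_x, lambda_y > 0 (or lambda)",
                    class = "podomech_validation_error")
    parameters$lambda_x <- lx; parameters$lambda_y <- ly
  }
  if (kind == "radial_contraction" &&
      (is.null(parameters$alpha) || parameters$alpha <= 0 || parameters$alpha >= 1))
    stop_podomech("radial_contraction needs alpha in (0, 1)",
                  class = "podomech_validation_error")
  if (kind == "imported_field" && !is.function(parameters$fun))
    stop_podomech("imported_field needs parameters$fun",
                  class = "podomech_validation_error")
  if (length(domain) != 4 || domain[2] <= domain[1] || domain[4] <= domain[3])
    stop_podomech("domain must be c(xmin, xmax, ymin, ymax)",
                  class = "podomech_validation_error")
  structure(list(kind = kind, parameters = parameters, domain = domain),
            class = "deformation_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a deformation spec to points
#'
#' @param def a [deformation_spec()].
#' @param pts n x 2 matrix of reference positions, um.
#' @return list with `pos` (n x 2 mapped positions) and `F` (n x 4 matrix of
#'   the true deformation gradient at each point; columns F11, F12, F21, F22).
#' @export
apply_deformation <- function(def, pts) {
  stopifnot(inherits(def, "deformation_spec"))
  pts <- as.matrix(pts)
  n <- nrow(pts)
  ctr <- c(mean(def$domain[1:2]), mean(def$domain[3:4]))
  pars <- def$parameters
  constF <- function(F) matrix(rep(as.numeric(t(F)), each = n), n, 4)
  switch(def$kind,
    translation = list(pos = cbind(pts[, 1] + pars$tx, pts[, 2] + pars$ty),
                       F = constF(diag(2))),
    rotation = {
      R <- matrix(c(cos(pars$theta), sin(pars$theta),
                    -sin(pars$theta), cos(pars$theta)), 2, 2)
      rel <- sweep(pts, 2, ctr)
      list(pos = sweep(rel %*% t(R), 2, ctr, "+"), F = constF(R))
    },
    uniform_stretch = {
      F <- diag(c(pars$lambda_x, pars$lambda_y))
      rel <- sweep(pts, 2, ctr)
      list(pos = sweep(rel %*% t(F), 2, ctr, "+"), F = constF(F))
    },
    simple_shear = {
      F <- matrix(c(1, 0, pars$gamma, 1), 2, 2)
      rel <- sweep(pts, 2, ctr)
      list(pos = sweep(rel %*% t(F), 2, ctr, "+"), F = constF(F))
    },
    radial_contraction = {
      F <- (1 - pars$alpha) * diag(2)
      rel <- sweep(pts, 2, ctr)
      list(pos = sweep((1 - pars$alpha) * rel, 2, ctr, "+"), F = constF(F))
    },
    imported_field = {
      out <- pars$fun(pts)
      stopifnot(is.matrix(out$pos), ncol(out$F) == 4)
      out
    })
}

#' Compose deformation specs into a single map
#'
#' Returns an `imported_field` spec applying the given specs in order; the
#' ground-truth gradient is the product of the per-stage gradients (chain
#' rule). Composing a rotation with a translation therefore yields a rigid
#' map with zero Green-Lagrange strain.
#'
#' @param specs list of [deformation_spec()] objects, applied left to right.
#' @param domain domain of the composite map.
#' @return a [deformation_spec()] of kind `imported_field`.
#' @export
compose_deformations <- function(specs, domain = specs[[1]]$domain) {
  fun <- function(pts) {
    pos <- as.matrix(pts)
    F <- matrix(rep(c(1, 0, 0, 1), each = nrow(pos)), nrow(pos), 4)
    for (sp in specs) {
      st <- apply_deformation(sp, pos)
      pos <- st$pos
      # F_new = F_stage %*% F  (per point, 2x2)
      F <- cbind(st$F[, 1] * F[, 1] + st$F[, 2] * F[, 3],
                 st$F[, 1] * F[, 2] + st$F[, 2] * F[, 4],
                 st$F[, 3] * F[, 1] + st$F[, 4] * F[, 3],
                 st$F[, 3] * F[, 2] + st$F[, 4] * F[, 4])
    }
    list(pos = pos, F = F)
  }
  deformation_spec("imported_field", list(fun = fun), domain = domain)
}

#' Generate a microbead field under a known deformation
#'
#' Scatters beads uniformly over the domain, maps them through the analytic
#' deformation, and stores the true deformation gradient at every bead —
#' emulating fiducial microbeads embedded in a hydrogel imaged before and
#' after a contractility perturbation.
#'
#' @param def a [deformation_spec()].
#' @param density beads per um^2.
#' @param seed integer seed.
#' @param localization_sd isotropic Gaussian localization noise added to the
#'   deformed positions, um (default 0).
#' @return an object of class `bead_field`: list with `ref`, `def` (n x 2
#'   positions, um), `F_true` (n x 4), `match_indices` (n x 2, identity
#'   pairing), `localization_sd` and `domain`.
#' @export
generate_bead_field <- function(def, density = 0.5, seed = NULL,
                                localization_sd = 0) {
  stopifnot(inherits(def, "deformation_spec"), density > 0)
  area <- (def$domain[2] - def$domain[1]) * (def$domain[4] - def$domain[3])
  n <- round(density * area)
  if (n < 4)
    stop_podomech("expected bead count %d < 4: insufficient sampling", n,
                  class = "podomech_sampling_error")
  with_seed(seed, {
    ref <- cbind(runif(n, def$domain[1], def$domain[2]),
                 runif(n, def$domain[3], def$domain[4]))
    st <- apply_deformation(def, ref)
    pos <- st$pos
    if (localization_sd > 0)
      pos <- pos + matrix(rnorm(2 * n, sd = localization_sd), n, 2)
    new_bead_field(ref, pos, cbind(seq_len(n), seq_len(n)),
                   F_true = st$F, localization_sd = localization_sd,
                   domain = def$domain)
  })
}

new_bead_field <- function(ref, def, match_indices, F_true = NULL,
                           localization_sd = 0, domain = NULL,
                           unmatched_ref = integer(), unmatched_def = integer()) {
  if (!all(is.finite(ref)) || !all(is.finite(def)))
    stop_podomech("bead positions must be finite",
                  class = "podomech_validation_error")
  structure(list(ref = ref, def = def, match_indices = match_indices,
                 F_true = F_true, localization_sd = localization_sd,
                 domain = domain, unmatched_ref = unmatched_ref,
                 unmatched_def = unmatched_def),
            class = "bead_field")
}

#' @export
print.bead_field <- function(x, ...) {
  cat(sprintf("bead_field: %d matched pairs (%d/%d unmatched ref/def)\n",
              nrow(x$match_indices), length(x$unmatched_ref),
              length(x$unmatched_def)))
  invisible(x)
}

#' Write / read a bead field as CSV
#'
#' Columns: `x_ref, y_ref, x_def, y_def` and, when ground truth is available,
#' `F11_true, F12_true, F21_true, F22_true`.
#'
#' @param field a `bead_field`.
#' @param path file path.
#' @return `write_bead_csv` returns `path` invisibly; `read_bead_csv` returns
#'   a `bead_field`.
#' @export
write_bead_csv <- function(field, path) {
  stopifnot(inherits(field, "bead_field"))
  i <- field$match_indices
  df <- data.frame(x_ref = field$ref[i[, 1], 1], y_ref = field$ref[i[, 1], 2],
                   x_def = field$def[i[, 2], 1], y_def = field$def[i[, 2], 2])
  if (!is.null(field$F_true)) {
    colnames(field$F_true) <- NULL
    df$F11_true <- field$F_true[, 1]; df$F12_true <- field$F_true[, 2]
    df$F21_true <- field$F_true[, 3]; df$F22_true <- field$F_true[, 4]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_csv
#' @export
read_bead_csv <- function(path) {
  df <- read.csv(path)
  F_true <- if ("F11_true" %in% names(df))
    as.matrix(df[, c("F11_true", "F12_true", "F21_true", "F22_true")])
  new_bead_field(as.matrix(df[, c("x_ref", "y_ref")]),
                 as.matrix(df[, c("x_def", "y_def")]),
                 cbind(seq_len(nrow(df)), seq_len(nrow(df))), F_true = F_true)
}
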
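#' Read fiber polylines from CSV
#'
#' Expected columns: `fiber_id`, `vertex_index`, `x_um`, `y_um` — the tabular
#' form of manually traced fiber lines.
#'
#' @param path CSV path.
#' @return named list of n x 2 polyline matrices, one per fiber.
#' @export
read_fiber_polylines <- function(path) {
  df <- read.csv(path)
  need <- c("fiber_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop_podomech("fiber CSV needs columns %s", paste(need, collapse = ", "),
                  class = "podomech_validation_error")
  out <- lapply(split(df, df$fiber_id), function(d) {
    d <- d[order(d$vertex_index), ]
    as_polyline(cbind(d$x_um, d$y_um))
  })
  out
}

#' Write fiber polylines to CSV
#'
#' @param polylines named list of n x 2 matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_polylines <- function(polylines, path) {
  rows <- do.call(rbind, lapply(names(polylines), function(id) {
    p <- polylines[[id]]
    data.frame(fiber_id = id, vertex_index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Build a contraction model from a JSON config
#'
#' The JSON object mirrors the arguments of [contraction_model()]; absent
#' fields take the defaults.
#'
#' @param path JSON file path.
#' @return a [contraction_model()].
#' @export
contraction_model_from_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read JSON configs")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(contraction_model))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_podomech("unknown config field(s): %s", paste(bad, collapse = ", "),
                  class = "podomech_validation_error")
  do.call(contraction_model, cfg)
}
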
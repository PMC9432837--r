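#' SLS phenotype categories
#'
#' The four scoring classes used for cultured podocytes: sarcomere-like
#' structures (SLSs) both centrally and peripherally, SLSs in the periphery
#' only, a loose (widely spaced) striated pattern, or no SLSs.
#'
#' @return character vector of the four category labels, in canonical order.
#' @export
sls_categories <- function() {
  c("sls_central_peripheral", "sls_peripheral_only", "loose_striated", "no_sls")
}

#' Specification of a synthetic phenotype population
#'
#' @param probabilities numeric vector of 4 nonnegative category
#'   probabilities (order of [sls_categories()]) summing to 1. The default
#'   puts just over 70% of cells in the SLS-containing classes, the regime
#'   reported for freshly reseeded primary podocytes.
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(probabilities = c(0.45, 0.2, 0.1, 0.25),
                           n_cells = 100, seed = NULL) {
  if (length(probabilities) != 4 || any(probabilities < 0))
    stop_podomech("probabilities must be 4 nonnegative fractions",
                  class = "podomech_validation_error")
  if (abs(sum(probabilities) - 1) > 1e-12)
    stop_podomech("probabilities must sum to 1 (got %.15g)", sum(probabilities),
                  class = "podomech_validation_error")
  if (n_cells < 0 || n_cells != round(n_cells))
    stop_podomech("n_cells must be a nonnegative integer",
                  class = "podomech_validation_error")
  structure(list(probabilities = as.numeric(probabilities),
                 n_cells = as.integer(n_cells), seed = seed),
            class = "phenotype_spec")
}

#' Draw a synthetic cell population of SLS phenotypes
#'
#' Multinomial draw over the four phenotype categories, reproducible under a
#' fixed seed.
#'
#' @param spec a [phenotype_spec()].
#' @return character vector of `n_cells` category labels.
#' @export
generate_phenotype_population <- function(spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (spec$n_cells == 0) return(character())
  with_seed(spec$seed,
            sample(sls_categories(), spec$n_cells, replace = TRUE,
                   prob = spec$probabilities))
}
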
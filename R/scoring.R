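#' Score a population of cells into SLS phenotype categories
#'
#' Tallies category labels into counts and fractions. The "any-SLS" fraction
#' is one minus the fraction of cells without SLSs.
#'
#' @param labels character vector of labels from [sls_categories()].
#' @return an object of class `phenotype_count`: list with `counts`, `total`,
#'   `fractions` (both named by category) and `any_sls_fraction`.
#' @export
score_cells <- function(labels) {
  cats <- sls_categories()
  if (length(labels) == 0)
    stop_podomech("no cells to score", class = "podomech_validation_error")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), cats)
  if (length(bad) > 0)
    stop_podomech("unknown phenotype label(s): %s", paste(bad, collapse = ", "),
                  class = "podomech_validation_error")
  counts <- table(factor(labels, levels = cats))
  counts <- setNames(as.integer(counts), cats)
  fractions <- counts / sum(counts)
  structure(list(counts = counts, total = sum(counts), fractions = fractions,
                 any_sls_fraction = unname(1 - fractions["no_sls"])),
            class = "phenotype_count")
}

#' @export
print.phenotype_count <- function(x, ...) {
  cat(sprintf("phenotype_count: %d cells, %.1f%% with SLSs\n", x$total,
              100 * x$any_sls_fraction))
  print(data.frame(category = names(x$counts), count = x$counts,
                   fraction = round(x$fractions, 4), row.names = NULL))
  invisible(x)
}

#' Cell length from a traced polyline or a binary mask
#'
#' For a polyline trace the length is the total path length. For a binary
#' mask it is the maximum Feret diameter, computed over pixel centers and
#' augmented by one pixel size so that a single pixel measures `pixel_size`
#' and an axis-aligned rectangle of w x h pixels measures approximately
#' `sqrt(w^2 + h^2)` pixels.
#'
#' @param x either an n x 2 numeric matrix (polyline vertices, um) or a
#'   logical/0-1 matrix (mask).
#' @param pixel_size pixel size for masks, um.
#' @return cell length in um.
#' @export
cell_length <- function(x, pixel_size = 1) {
  if (is.matrix(x) && ncol(x) == 2 && !is.logical(x) &&
      !all(x %in% c(0, 1))) {
    return(polyline_length(x))
  }
  mask <- x > 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop_podomech("empty mask", class = "podomech_validation_error")
  pts <- (idx - 0.5) * pixel_size # pixel centers, (row -> y, col -> x)
  if (nrow(pts) == 1) return(pixel_size)
  # Feret over pixel centers; convex hull keeps the pairwise search small
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  d <- max(dist(hp))
  d + pixel_size
}

#' Detachment assay series
#'
#' @param time_min numeric vector of time points, minutes (strictly
#'   increasing).
#' @param attached attached cell counts at each time point.
#' @param initial initial (time-zero) cell count.
#' @return an object of class `detachment_series`.
#' @export
detachment_series <- function(time_min, attached, initial = attached[1]) {
  if (length(time_min) != length(attached))
    stop_podomech("time and attached counts must have equal length",
                  class = "podomech_validation_error")
  if (is.unsorted(time_min, strictly = TRUE))
    stop_podomech("time points must be strictly increasing",
                  class = "podomech_validation_error")
  if (any(attached < 0) || initial <= 0 || any(attached > initial))
    stop_podomech("attached counts must lie in [0, initial]",
                  class = "podomech_validation_error")
  if (is.unsorted(rev(attached)))
    stop_podomech("attached counts must be non-increasing in time",
                  class = "podomech_validation_error")
  structure(list(time_min = time_min, attached = attached, initial = initial),
            class = "detachment_series")
}

#' Detached fraction over time
#'
#' @param series a [detachment_series()].
#' @return data frame with `time_min`, `attached`, `detached_fraction`
#'   (`1 - attached / initial`, in `[0, 1]` and non-decreasing).
#' @export
detachment_fraction <- function(series) {
  stopifnot(inherits(series, "detachment_series"))
  data.frame(time_min = series$time_min, attached = series$attached,
             detached_fraction = 1 - series$attached / series$initial)
}

#' Group comparison by ANOVA with multiple-comparison correction
#'
#' Thin wrapper over standard routines, mirroring the study's statistical
#' workflow: one-way ANOVA followed by Tukey's multiple comparisons (used for
#' sarcomeric spacing), or two-way ANOVA followed by Sidak-adjusted pairwise
#' comparisons of the primary factor within levels of the second (used for
#' detachment assays).
#'
#' @param values numeric response vector.
#' @param labels primary grouping factor.
#' @param design `"one_way"` or `"two_way"`.
#' @param labels2 secondary factor (required for `"two_way"`; e.g. time point).
#' @return list with `anova` (data frame of F and p per term) and `pairwise`
#'   (data frame of pairwise comparisons with adjusted p values; Tukey for
#'   one-way, Sidak for two-way).
#' @export
compare_groups <- function(values, labels, design = c("one_way", "two_way"),
                           labels2 = NULL) {
  design <- match.arg(design)
  f1 <- factor(labels)
  tab <- table(f1)
  if (nlevels(f1) < 2 || any(tab < 2))
    stop_podomech("need >= 2 groups with >= 2 values each",
                  class = "podomech_validation_error")
  if (design == "one_way") {
    fit <- aov(values ~ f1, data = data.frame(values = values, f1 = f1))
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$f1
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           row.names = NULL)
    anova_tab <- data.frame(term = "group", F = an$`F value`[1],
                            p = an$`Pr(>F)`[1])
  } else {
    if (is.null(labels2))
      stop_podomech("two_way design requires labels2",
                    class = "podomech_validation_error")
    f2 <- factor(labels2)
    dat <- data.frame(values = values, f1 = f1, f2 = f2)
    fit <- aov(values ~ f1 * f2, data = dat)
    an <- summary(fit)[[1]]
    anova_tab <- data.frame(term = trimws(rownames(an)[-nrow(an)]),
                            F = an$`F value`[-nrow(an)],
                            p = an$`Pr(>F)`[-nrow(an)])
    emm <- emmeans::emmeans(fit, ~ f1 | f2)
    cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "sidak"))
    pairwise <- data.frame(comparison = paste(cmp$contrast, "|", cmp$f2),
                           diff = cmp$estimate, p_adj = cmp$p.value,
                           row.names = NULL)
  }
  list(anova = anova_tab, pairwise = pairwise)
}
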
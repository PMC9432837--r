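#' Extract an intensity profile along a fiber polyline
#'
#' Samples each channel by bilinear interpolation at points spaced `step` um
#' along the polyline, averaging across a band of the given perpendicular
#' `width` — the digital counterpart of plotting fluorescence intensity along
#' a line drawn through a striated fiber.
#'
#' @param image a `striation_image`.
#' @param polyline n x 2 matrix of vertices, um (image coordinates).
#' @param width averaging width perpendicular to the line, um (0 = none).
#' @param step sampling step along the line, um; a step at or below the pixel
#'   size is recommended.
#' @return an object of class `fiber_profile`: list with `arclength` (um,
#'   strictly increasing), `intensity` (matrix samples x channels),
#'   `source_polyline` and `sampling_step`.
#' @export
extract_profile <- function(image, polyline, width = 0, step = NULL) {
  stopifnot(inherits(image, "striation_image"))
  polyline <- as_polyline(polyline)
  if (is.null(step)) step <- image$pixel_size / 2
  if (step <= 0 || width < 0)
    stop_podomech("step must be > 0 and width >= 0",
                  class = "podomech_validation_error")
  L <- polyline_length(polyline)
  if (L <= 0)
    stop_podomech("zero-length polyline", class = "podomech_validation_error")
  s <- seq(0, L, by = step)
  ctr <- polyline_point(polyline, s)
  # per-sample unit tangent -> normal
  seg <- polyline_lengths(polyline)
  cs <- c(0, cumsum(seg))
  idx <- pmin(findInterval(s, cs, rightmost.closed = TRUE), length(seg))
  tang <- polyline_tangents(polyline)[idx, , drop = FALSE]
  nrm <- cbind(-tang[, 2], tang[, 1])
  offs <- if (width > 0)
    seq(-width / 2, width / 2, by = min(image$pixel_size / 2, width / 2))
  else 0
  d <- dim(image$data)
  acc <- matrix(0, length(s), length(image$channels))
  for (o in offs) {
    pts <- ctr + o * nrm
    for (ci in seq_along(image$channels))
      acc[, ci] <- acc[, ci] + bilinear_sample(image$data[, , ci], pts,
                                               image$pixel_size)
  }
  acc <- acc / length(offs)
  colnames(acc) <- image$channels
  structure(list(arclength = s, intensity = acc,
                 channels = image$channels, source_polyline = polyline,
                 sampling_step = step),
            class = "fiber_profile")
}

# Bilinear interpolation of an image (rows = y, cols = x, pixel centers at
# (i - 0.5) * px). Errors if any point falls outside the image extent.
bilinear_sample <- function(img, pts, px) {
  nr <- nrow(img); nc <- ncol(img)
  fx <- pts[, 1] / px - 0.5
  fy <- pts[, 2] / px - 0.5
  if (any(pts[, 1] < 0 | pts[, 1] > nc * px | pts[, 2] < 0 | pts[, 2] > nr * px))
    stop_podomech("sample point outside the image extent",
                  class = "podomech_bounds_error")
  # clamp to the center grid; constant extrapolation in the half-pixel margin
  fx <- pmin(pmax(fx, 0), nc - 1)
  fy <- pmin(pmax(fy, 0), nr - 1)
  x0 <- pmin(floor(fx), nc - 2); y0 <- pmin(floor(fy), nr - 2)
  tx <- fx - x0; ty <- fy - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - tx) * (1 - ty) +
    img[cbind(y0 + 1, x0 + 2)] * tx * (1 - ty) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - tx) * ty +
    img[cbind(y0 + 2, x0 + 2)] * tx * ty
}

#' Detect intensity peaks along a fiber profile
#'
#' Finds local maxima with a prominence of at least `min_prominence` times
#' the channel's intensity range, enforces a minimum pairwise separation
#' (keeping the higher peak), and refines each position to sub-sample
#' precision by a 3-point parabolic fit. The range-relative prominence makes
#' the detection invariant to adding a constant to the profile and to
#' uniform intensity rescaling.
#'
#' @param profile a [extract_profile()] result.
#' @param channel channel name or index.
#' @param min_prominence minimum prominence as a fraction of the channel's
#'   intensity range.
#' @param min_separation minimum distance between reported peaks, um; the
#'   default sits below the smallest sarcomeric spacing of interest (0.8 um).
#' @return numeric vector of sorted peak positions, um (possibly empty).
#' @export
detect_peaks <- function(profile, channel = 1, min_prominence = 0.2,
                         min_separation = 0.4) {
  stopifnot(inherits(profile, "fiber_profile"))
  if (min_separation <= 0)
    stop_podomech("min_separation must be > 0",
                  class = "podomech_validation_error")
  if (is.character(channel)) channel <- match(channel, profile$channels)
  v <- profile$intensity[, channel]
  s <- profile$arclength
  rng <- diff(range(v))
  if (length(v) < 3 || rng <= .Machine$double.eps * max(abs(v), 1))
    return(numeric())
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0) return(numeric())
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- cand[prom >= min_prominence * rng]
  if (length(keep) == 0) return(numeric())
  # enforce separation, highest peaks first
  keep <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer()
  for (i in keep)
    if (all(abs(s[i] - s[sel]) >= min_separation)) sel <- c(sel, i)
  sel <- sort(sel)
  # parabolic sub-sample refinement on a uniform grid
  step <- profile$sampling_step
  pos <- vapply(sel, function(i) {
    if (i <= 1 || i >= n) return(s[i])
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den >= 0) return(s[i])
    s[i] + 0.5 * step * (v[i - 1] - v[i + 1]) / den
  }, numeric(1))
  sort(pos)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two saddle minima separating it from higher terrain (or the
# profile ends).
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- v[seq_len(i - 1)]
  right <- v[seq.int(i + 1, n)]
  higher_l <- which(left >= v[i])
  min_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), i - 1)]) else min(left)
  higher_r <- which(right >= v[i])
  min_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
  v[i] - max(min_l, min_r)
}

#' Sarcomeric spacings from detected peaks
#'
#' Spacings are successive differences of the sorted peak positions. The
#' per-fiber mean spacing is only defined for fibers at least
#' `min_fiber_length` long (default 6 um, the eligibility rule used when
#' averaging per stress fiber) with at least two peaks; shorter fibers keep
#' their pooled spacings but are flagged ineligible for per-fiber statistics.
#'
#' @param peaks sorted numeric vector of peak positions, um.
#' @param fiber_length length of the analysed fiber, um.
#' @param min_fiber_length eligibility threshold for the per-fiber mean, um.
#' @return an object of class `spacing_set`: list with `peaks`, `spacings`,
#'   `fiber_length`, `per_fiber_mean` (NA when undefined) and `eligible`.
#' @export
compute_spacings <- function(peaks, fiber_length, min_fiber_length = 6) {
  if (is.unsorted(peaks))
    stop_podomech("peaks must be sorted", class = "podomech_validation_error")
  spac <- diff(peaks)
  eligible <- fiber_length >= min_fiber_length && length(peaks) >= 2
  structure(list(peaks = peaks, spacings = spac, fiber_length = fiber_length,
                 per_fiber_mean = if (eligible) mean(spac) else NA_real_,
                 eligible = eligible),
            class = "spacing_set")
}

#' Two-channel alternation index
#'
#' Fraction of consecutive intervals between peaks of channel A that contain
#' exactly one peak of channel B: 1 for a perfectly alternating sarcomeric
#' pattern (e.g. myosin IIA bands midway between synaptopodin bands), 0 when
#' no interval holds exactly one B peak.
#'
#' @param peaks_a,peaks_b sorted peak positions of the two channels, um.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when channel A has
#'   fewer than two peaks.
#' @export
alternation_index <- function(peaks_a, peaks_b) {
  if (is.unsorted(peaks_a) || is.unsorted(peaks_b))
    stop_podomech("peak positions must be sorted",
                  class = "podomech_validation_error")
  if (length(peaks_a) < 2) {
    warning("alternation index undefined with < 2 reference peaks")
    return(NA_real_)
  }
  counts <- vapply(seq_len(length(peaks_a) - 1), function(i)
    sum(peaks_b > peaks_a[i] & peaks_b < peaks_a[i + 1]), integer(1))
  mean(counts == 1L)
}

#' Group-wise sarcomeric spacing statistics
#'
#' Summarises spacing sets two ways, matching the two conventions used for
#' sarcomeric spacing: pooled statistics where n is the total number of
#' spacings in a group (histogram convention), and per-fiber statistics where
#' n is the number of eligible fibers and each fiber contributes its mean
#' spacing. Groups with no data are dropped with a warning.
#'
#' @param spacing_sets list of [compute_spacings()] results.
#' @param group_labels group label per spacing set.
#' @param breaks histogram breaks (um) passed to [hist()].
#' @return list with `pooled` (data frame: group, n_spacings, mean, sd),
#'   `per_fiber` (data frame: group, n_fibers, mean, sd) and `histograms`
#'   (per group: counts and break points of the pooled spacings).
#' @export
spacing_statistics <- function(spacing_sets, group_labels,
                               breaks = seq(0, 3, by = 0.1)) {
  stopifnot(length(spacing_sets) == length(group_labels))
  if (length(spacing_sets) == 0)
    stop_podomech("need at least one group", class = "podomech_validation_error")
  groups <- unique(as.character(group_labels))
  pooled <- per_fiber <- NULL
  histograms <- list()
  for (g in groups) {
    sets <- spacing_sets[group_labels == g]
    all_sp <- unlist(lapply(sets, `[[`, "spacings"))
    fm <- unlist(lapply(sets, `[[`, "per_fiber_mean"))
    fm <- fm[!is.na(fm)]
    if (length(all_sp) == 0) {
      warning(sprintf("group '%s' has no spacings; excluded", g))
      next
    }
    pooled <- rbind(pooled, data.frame(
      group = g, n_spacings = length(all_sp), mean = mean(all_sp),
      sd = if (length(all_sp) > 1) sd(all_sp) else 0))
    per_fiber <- rbind(per_fiber, data.frame(
      group = g, n_fibers = length(fm),
      mean = if (length(fm)) mean(fm) else NA_real_,
      sd = if (length(fm) > 1) sd(fm) else 0))
    br <- breaks
    if (max(all_sp) >= max(br))
      br <- seq(min(br), max(all_sp) + 0.1, by = diff(br)[1])
    h <- graphics::hist(all_sp, breaks = br, plot = FALSE)
    histograms[[g]] <- data.frame(mid = h$mids, count = h$counts)
  }
  if (is.null(pooled))
    stop_podomech("all groups empty", class = "podomech_validation_error")
  list(pooled = pooled, per_fiber = per_fiber, histograms = histograms)
}

#' Measure sarcomeric spacing of one synthetic or traced fiber
#'
#' Convenience composition: profile extraction, peak detection and spacing
#' computation for a single channel.
#'
#' @inheritParams extract_profile
#' @inheritParams detect_peaks
#' @return a `spacing_set`.
#' @export
measure_fiber_spacing <- function(image, polyline, channel = 1, width = 0.4,
                                  step = NULL, min_prominence = 0.2,
                                  min_separation = 0.4, min_fiber_length = 6) {
  prof <- extract_profile(image, polyline, width = width, step = step)
  pk <- detect_peaks(prof, channel, min_prominence, min_separation)
  compute_spacings(pk, polyline_length(polyline), min_fiber_length)
}
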
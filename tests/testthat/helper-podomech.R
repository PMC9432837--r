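# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# A straight horizontal fiber image: polyline from (2, y0) to (2 + len, y0).
straight_fiber_spec <- function(spacing, len = 12, noise_sd = 0, seed = NULL,
                                pixel_size = 0.1, ...) {
  striation_spec(spacing = spacing,
                 fiber_polyline = rbind(c(2, 3), c(2 + len, 3)),
                 pixel_size = pixel_size,
                 image_shape = c(round(6 / pixel_size),
                                 round((len + 4) / pixel_size)),
                 noise_sd = noise_sd, seed = seed, ...)
}

straight_fiber_polyline <- function(len = 12) rbind(c(2, 3), c(2 + len, 3))

# Independent peak oracle: exhaustive scan over all strict local maxima with
# the same range-relative prominence rule and greedy separation filter, but
# no sub-sample refinement. O(n^2), no shared code with detect_peaks.
oracle_peaks <- function(s, v, min_prominence = 0.2, min_separation = 0.4) {
  n <- length(v)
  rng <- diff(range(v))
  hits <- integer()
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] >= v[i + 1])) next
    # prominence by explicit walk
    jl <- i
    minl <- v[i]
    while (jl > 1 && v[jl - 1] < v[i]) {
      jl <- jl - 1
      minl <- min(minl, v[jl])
    }
    if (jl > 1) minl <- min(v[jl:(i - 1)])
    else minl <- min(v[1:(i - 1)])
    jr <- i
    minr <- v[i]
    while (jr < n && v[jr + 1] < v[i]) {
      jr <- jr + 1
      minr <- min(minr, v[jr])
    }
    if (jr < n) minr <- min(v[(i + 1):jr])
    else minr <- min(v[(i + 1):n])
    if (v[i] - max(minl, minr) >= min_prominence * rng) hits <- c(hits, i)
  }
  keep <- integer()
  for (i in hits[order(v[hits], decreasing = TRUE)])
    if (all(abs(s[i] - s[keep]) >= min_separation)) keep <- c(keep, i)
  sort(s[keep])
}

# Build a bare fiber_profile object for synthetic 1D signals.
make_profile <- function(s, v, channel = "ch") {
  structure(list(arclength = s, intensity = matrix(v, ncol = 1,
                                                   dimnames = list(NULL, channel)),
                 channels = channel, source_polyline = rbind(c(0, 0), c(max(s), 0)),
                 sampling_step = s[2] - s[1]),
            class = "fiber_profile")
}

# Coarse-mesh model reused across FEM tests.
fem_test_model <- function(...) {
  contraction_model(mesh_resolution = 3, ...)
}
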
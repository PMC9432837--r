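#' Specification of a synthetic striated stress fiber image
#'
#' Describes a two-(or more-)channel fluorescence image of a single striated
#' fiber with alternating protein bands (e.g. synaptopodin vs myosin IIA) at a
#' controlled sarcomeric spacing. Band intensity is modelled as a Gaussian
#' bump along the fiber axis (sd = `band_width / 2.355`, i.e. `band_width` is
#' a FWHM) times a transverse Gaussian of sd `fiber_sigma`, optionally blurred
#' by an isotropic Gaussian PSF and corrupted by additive Gaussian noise.
#'
#' @param spacing sarcomeric band spacing, um (> 2 * `pixel_size`).
#' @param fiber_polyline n x 2 matrix of polyline vertices, um; image
#'   coordinates have the origin at the top-left corner, x rightward and
#'   y downward.
#' @param band_width FWHM of a band along the fiber, um.
#' @param channel_phase_offsets named numeric vector of per-channel phase
#'   offsets as fractions of the period, each in `[0, 1)`. A channel with
#'   offset 0.5 has band centers midway between those of a channel with
#'   offset 0.
#' @param psf_sigma Gaussian PSF sd, um (0 disables blurring).
#' @param noise_sd additive Gaussian noise sd, intensity units (images are
#'   generated on a `[0, 1]` intensity scale).
#' @param pixel_size pixel size, um.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param fiber_sigma transverse Gaussian sd of the fiber, um.
#' @param amplitude peak band intensity before blur/noise.
#' @param seed integer seed for the noise draw.
#' @return an object of class `striation_spec`.
#' @export
striation_spec <- function(spacing, fiber_polyline, band_width = 0.25,
                           channel_phase_offsets = c(synpo = 0, myosin = 0.5),
                           psf_sigma = 0.1, noise_sd = 0, pixel_size = 0.1,
                           image_shape = c(64, 160), fiber_sigma = 0.25,
                           amplitude = 0.8, seed = NULL) {
  fiber_polyline <- as_polyline(fiber_polyline)
  if (spacing <= 2 * pixel_size)
    stop_podomech("spacing %.3g um violates the Nyquist bound 2 * pixel_size = %.3g um",
                  spacing, 2 * pixel_size, class = "podomech_nyquist_error")
  if (is.null(names(channel_phase_offsets)) || any(!nzchar(names(channel_phase_offsets))))
    stop_podomech("channel_phase_offsets must be a named vector",
                  class = "podomech_validation_error")
  if (any(channel_phase_offsets < 0 | channel_phase_offsets >= 1))
    stop_podomech("phase offsets must lie in [0, 1)",
                  class = "podomech_validation_error")
  if (psf_sigma < 0 || noise_sd < 0 || pixel_size <= 0 || band_width <= 0)
    stop_podomech("band_width, pixel_size must be > 0; psf_sigma, noise_sd >= 0",
                  class = "podomech_validation_error")
  ext <- c(image_shape[2], image_shape[1]) * pixel_size # (x, y) extent
  if (any(fiber_polyline < 0) || any(fiber_polyline[, 1] > ext[1]) ||
      any(fiber_polyline[, 2] > ext[2]))
    stop_podomech("fiber polyline extends outside the %g x %g um image",
                  ext[1], ext[2], class = "podomech_bounds_error")
  structure(list(spacing = spacing, fiber_polyline = fiber_polyline,
                 band_width = band_width,
                 channel_phase_offsets = channel_phase_offsets,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 pixel_size = pixel_size, image_shape = as.integer(image_shape),
                 fiber_sigma = fiber_sigma, amplitude = amplitude, seed = seed),
            class = "striation_spec")
}

#' Generate a synthetic striated fiber image with known band centers
#'
#' Renders the image described by a [striation_spec()] and returns it together
#' with the ground-truth band center positions of every channel, so that
#' downstream spacing quantification can be validated by parameter recovery.
#'
#' @param spec a [striation_spec()].
#' @return an object of class `striation_image`: a list with `data` (array
#'   `rows x cols x channels`, intensities in arbitrary units on a nominal
#'   `[0, 1]` scale), `pixel_size` (um), `channels`, `band_centers` (per
#'   channel: data frame of arclength `s` and image coordinates `x`, `y`, um)
#'   and the generating `spec`.
#' @export
generate_striation_image <- function(spec) {
  stopifnot(inherits(spec, "striation_spec"))
  p <- spec$fiber_polyline
  L <- polyline_length(p)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- spec$pixel_size
  # pixel-center coordinates
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, nc), nr, nc)
  # nearest point on the polyline: per-segment projection, keep the closest
  tang <- polyline_tangents(p)
  seg <- polyline_lengths(p)
  cs <- c(0, cumsum(seg))
  best_d2 <- matrix(Inf, nr, nc)
  best_s <- matrix(0, nr, nc)
  for (k in seq_len(nrow(p) - 1)) {
    dx <- X - p[k, 1]; dy <- Y - p[k, 2]
    t <- pmin(pmax(dx * tang[k, 1] + dy * tang[k, 2], 0), seg[k])
    d2 <- (dx - t * tang[k, 1])^2 + (dy - t * tang[k, 2])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cs[k] + t[upd]
  }
  sig_b <- spec$band_width / (2 * sqrt(2 * log(2)))
  transverse <- exp(-best_d2 / (2 * spec$fiber_sigma^2))
  channels <- names(spec$channel_phase_offsets)
  img <- array(0, dim = c(nr, nc, length(channels)),
               dimnames = list(NULL, NULL, channels))
  centers <- list()
  for (ci in seq_along(channels)) {
    s0 <- spec$channel_phase_offsets[ci] * spec$spacing
    sc <- seq(s0, L, by = spec$spacing)
    pts <- polyline_point(p, sc)
    centers[[channels[ci]]] <- data.frame(s = sc, x = pts[, 1], y = pts[, 2])
    axial <- matrix(0, nr, nc)
    for (s_k in sc)
      axial <- axial + exp(-(best_s - s_k)^2 / (2 * sig_b^2))
    img[, , ci] <- spec$amplitude * axial * transverse
  }
  if (spec$psf_sigma > 0) {
    for (ci in seq_along(channels))
      img[, , ci] <- as.numeric(EBImage::gblur(
        EBImage::Image(img[, , ci]), sigma = spec$psf_sigma / px))
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      img + array(rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
    })
    dimnames(img) <- list(NULL, NULL, channels)
  }
  structure(list(data = img, pixel_size = px, channels = channels,
                 band_centers = centers, spec = spec),
            class = "striation_image")
}

#' @export
print.striation_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("striation_image: %d x %d px (%.2f um/px), channels: %s\n",
              d[1], d[2], x$pixel_size, paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Write / read a multichannel striation image as TIFF
#'
#' Images are stored as 16-bit multi-page TIFF (one page per channel), with
#' intensities clamped to `[0, 1]`. The pixel size cannot round-trip through
#' the plain TIFF container, so it must be re-supplied on read.
#'
#' @param image a `striation_image`.
#' @param path output file path.
#' @return `write_striation_tiff` returns `path` invisibly;
#'   `read_striation_tiff` returns a `striation_image` (without ground-truth
#'   band centers).
#' @export
write_striation_tiff <- function(image, path) {
  stopifnot(inherits(image, "striation_image"))
  pages <- lapply(seq_along(image$channels), function(ci)
    pmin(pmax(image$data[, , ci], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_striation_tiff
#' @param path input file path.
#' @param pixel_size pixel size of the stored image, um.
#' @param channels optional channel names (defaults to `ch1`, `ch2`, ...).
#' @export
read_striation_tiff <- function(path, pixel_size, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) if (length(dim(pg)) == 3) pg[, , 1] else pg)
  if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
  img <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, channels))
  structure(list(data = img, pixel_size = pixel_size, channels = channels,
                 band_centers = NULL, spec = NULL),
            class = "striation_image")
}
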
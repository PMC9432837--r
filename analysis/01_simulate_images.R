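#!/usr/bin/env Rscript
# Simulate striated-fiber image sets for the four substrate conditions.
#
# Each condition gets 30 two-channel fibers (synaptopodin / myosin IIA,
# half-period phase offset) at the sarcomeric spacing characteristic of that
# substrate: 1.4 um (0.2 kPa), 1.2 um (0.9 kPa), 1.0 um (6.0 kPa), 0.8 um
# (glass). Images carry 0.05 additive noise and a 0.1-um PSF at 0.1-um
# pixels. A representative TIFF per condition and the full fiber-trace table
# are written under results/.

library(podomech)

dir.create("results/images", recursive = TRUE, showWarnings = FALSE)
conditions <- data.frame(
  condition = c("0.2kPa", "0.9kPa", "6.0kPa", "glass"),
  spacing = c(1.4, 1.2, 1.0, 0.8))
n_fibers <- 30
polyline <- rbind(c(2, 3), c(14, 3))

all_polylines <- list()
for (ci in seq_len(nrow(conditions))) {
  cond <- conditions$condition[ci]
  for (i in seq_len(n_fibers)) {
    spec <- striation_spec(conditions$spacing[ci], polyline,
                           pixel_size = 0.1, image_shape = c(60, 160),
                           noise_sd = 0.05, seed = 10000 * ci + i)
    img <- generate_striation_image(spec)
    if (i == 1)
      write_striation_tiff(img, sprintf("results/images/%s_fiber01.tif", cond))
    all_polylines[[sprintf("%s_f%02d", cond, i)]] <- polyline
  }
  cat(sprintf("condition %s: %d fibers at true spacing %.1f um\n",
              cond, n_fibers, conditions$spacing[ci]))
}
write_fiber_polylines(all_polylines, "results/fiber_traces.csv")
write.csv(conditions, "results/conditions.csv", row.names = FALSE)
cat("wrote results/fiber_traces.csv and per-condition TIFFs\n")
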
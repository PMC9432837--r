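test_that("profile extraction reproduces constant images and checks bounds", {
  flat <- structure(list(
    data = array(0.4, dim = c(40, 40, 1), dimnames = list(NULL, NULL, "ch")),
    pixel_size = 0.1, channels = "ch", band_centers = NULL, spec = NULL),
    class = "striation_image")
  prof <- extract_profile(flat, rbind(c(0.5, 2), c(3.5, 2)), width = 0.4)
  expect_equal(prof$intensity[, 1], rep(0.4, length(prof$arclength)))
  expect_true(all(diff(prof$arclength) > 0))
  expect_error(extract_profile(flat, rbind(c(0.5, 2), c(10, 2))),
               class = "podomech_bounds_error")
  expect_error(extract_profile(flat, rbind(c(1, 1), c(1, 1))),
               class = "podomech_validation_error")
})

test_that("profile maxima coincide with ground-truth band centers", {
  img <- generate_striation_image(straight_fiber_spec(1.0))
  prof <- extract_profile(img, straight_fiber_polyline(), step = 0.05)
  pk <- detect_peaks(prof, "synpo")
  truth <- img$band_centers$synpo$s
  truth <- truth[truth > 0.2 & truth < 11.8] # boundary bands are not maxima
  matched <- vapply(pk, function(p) min(abs(p - truth)), numeric(1))
  expect_lte(max(matched), 0.05 / 2 + 1e-9) # within half a sampling step
  expect_equal(length(pk), length(truth))
})

test_that("peak detection matches closed forms and handles flat profiles", {
  # cosine with unit period; half a period of padding keeps every expected
  # peak an interior local maximum
  s <- seq(0, 7, by = 0.05)
  pk <- detect_peaks(make_profile(s, cos(2 * pi * (s - 0.5))), 1)
  expect_equal(pk, 0.5 + 0:6, tolerance = 0.01)
  expect_identical(detect_peaks(make_profile(s, rep(1, length(s))), 1),
                   numeric())
  expect_error(detect_peaks(make_profile(s, cos(s)), 1, min_separation = 0),
               class = "podomech_validation_error")
})

test_that("noisy peak detection agrees with an exhaustive local-maximum oracle", {
  img <- generate_striation_image(straight_fiber_spec(0.9, noise_sd = 0.05,
                                                      seed = 42))
  prof <- extract_profile(img, straight_fiber_polyline(), step = 0.05)
  pk <- detect_peaks(prof, "synpo")
  orc <- oracle_peaks(prof$arclength, prof$intensity[, "synpo"])
  # same peak set (sub-sample refinement moves each by < half a step)
  expect_equal(length(pk), length(orc))
  expect_lte(max(abs(pk - orc)), 0.05 / 2 + 1e-9)
  # every detected peak lies within 0.1 um of a true band center, none missed
  truth <- img$band_centers$synpo$s
  interior <- truth[truth > 0.2 & truth < 11.8]
  expect_equal(length(pk), length(interior))
  expect_lte(max(vapply(pk, function(p) min(abs(p - interior)), numeric(1))),
             0.1)
})

test_that("peak detection is invariant to intensity offset and rescaling", {
  img <- generate_striation_image(straight_fiber_spec(1.0, noise_sd = 0.03,
                                                      seed = 5))
  prof <- extract_profile(img, straight_fiber_polyline(), step = 0.05)
  pk0 <- detect_peaks(prof, "synpo")
  shifted <- prof; shifted$intensity <- prof$intensity + 7.5
  scaled <- prof; scaled$intensity <- prof$intensity * 0.013
  expect_equal(detect_peaks(shifted, "synpo"), pk0)
  expect_equal(detect_peaks(scaled, "synpo"), pk0)
})

test_that("spacings are successive differences with the fiber-length gate", {
  ss <- compute_spacings(c(0, 1, 2, 3), fiber_length = 10)
  expect_equal(ss$spacings, c(1, 1, 1))
  expect_equal(ss$per_fiber_mean, 1.0)
  short <- compute_spacings(c(0, 1, 2, 3), fiber_length = 5)
  expect_true(is.na(short$per_fiber_mean))
  expect_false(short$eligible)
  expect_equal(short$spacings, c(1, 1, 1)) # still pooled
  single <- compute_spacings(2.5, fiber_length = 10)
  expect_identical(single$spacings, numeric())
  expect_true(is.na(single$per_fiber_mean))
  expect_error(compute_spacings(c(2, 1), 10),
               class = "podomech_validation_error")
})

test_that("alternation index counts interleaved peaks", {
  expect_equal(alternation_index(c(0, 1, 2), c(0.5, 1.5)), 1.0)
  expect_equal(alternation_index(c(0, 1, 2), numeric()), 0.0)
  expect_warning(ai <- alternation_index(0.5, c(0.1, 0.9)))
  expect_true(is.na(ai))
  # brute force oracle on random b peaks
  a <- 0:10
  b <- withr::with_seed(3, sort(runif(200, 0, 10)))
  brute <- mean(vapply(seq_len(10), function(i)
    sum(findInterval(b, c(a[i], a[i + 1]), left.open = TRUE,
                     rightmost.closed = FALSE) == 1L) == 1L, logical(1)))
  expect_equal(alternation_index(a, b), brute)
})

test_that("group statistics distinguish pooled and per-fiber conventions", {
  sets <- list(compute_spacings(c(0, 1, 2), 10),
               compute_spacings(c(0, 1, 2, 3), 10),
               compute_spacings(c(0, 1), 4)) # ineligible per-fiber
  st <- spacing_statistics(sets, c("g1", "g1", "g1"))
  expect_equal(st$pooled$n_spacings, 6) # 2 + 3 + 1
  expect_equal(st$pooled$mean, 1.0)
  expect_equal(st$pooled$sd, 0)
  expect_equal(st$per_fiber$n_fibers, 2) # short fiber excluded
  expect_equal(st$per_fiber$mean, 1.0)
  expect_warning(st2 <- spacing_statistics(
    list(compute_spacings(c(0, 1), 10), compute_spacings(3, 10)),
    c("a", "b")), "no spacings")
  expect_equal(st2$pooled$group, "a")
})

test_that("two synthetic groups with distinct spacings are recovered and ordered", {
  measure_group <- function(spacing, n, seed0) {
    lapply(seq_len(n), function(i)
      measure_fiber_spacing(
        generate_striation_image(straight_fiber_spec(spacing, noise_sd = 0.03,
                                                     seed = seed0 + i)),
        straight_fiber_polyline(), channel = "synpo", step = 0.05))
  }
  sets <- c(measure_group(1.0, 8, 100), measure_group(1.4, 8, 200))
  st <- spacing_statistics(sets, rep(c("s1.0", "s1.4"), each = 8))
  m <- setNames(st$per_fiber$mean, st$per_fiber$group)
  expect_lt(abs(m["s1.0"] - 1.0) / 1.0, 0.05)
  expect_lt(abs(m["s1.4"] - 1.4) / 1.4, 0.05)
  expect_lt(m["s1.0"], m["s1.4"])
})
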
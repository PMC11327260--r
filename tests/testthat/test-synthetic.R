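test_that("parameter validation catches impossible settings", {
  expect_error(synth_params(crystallinity = 0), "crystallinity")
  expect_error(synth_params(crystallinity = 1.2), "crystallinity")
  expect_error(synth_params(noise_sd = -1), "noise_sd")
  expect_error(synth_params(irsf_targets = c(3, 2.5, 4)), "increasing")
  expect_error(synth_params(grinding_kernel_widths = c(4, 7, 10)),
               "decreasing")
  expect_error(synth_grid(400, 4000), "invalid grid")
})

test_that("identical parameters and seed give bit-identical spectra", {
  p <- synth_params(seed = 77)
  a <- synth_grinding_series(p)
  b <- synth_grinding_series(p)
  for (g in 1:3) {
    expect_identical(a[[g]]$absorbance, b[[g]]$absorbance)
    expect_identical(a[[g]]$wavenumber, b[[g]]$wavenumber)
  }
})

test_that("changing only the seed changes only the noise", {
  p1 <- synth_params(seed = 1, irsf_jitter_sd = 0, replicate_jitter_sd = 0,
                     noise_sd = 0.002)
  p2 <- p1; p2$seed <- 2L
  s1 <- synth_grinding_series(p1)[[2]]
  s2 <- synth_grinding_series(p2)[[2]]
  expect_false(identical(s1$absorbance, s2$absorbance))
  expect_lt(max(abs(s1$absorbance - s2$absorbance)), 6 * p1$noise_sd)
  # and the clean parts are identical: truths coincide
  expect_identical(attr(s1, "truth")$k, attr(s2, "truth")$k)
})

test_that("a single noise-free nu3 band recovers its closed-form width", {
  bs <- data.frame(band = "v3", center = 1034, amplitude = 1, sigma = 14,
                   group = "v3")
  p <- synth_params(band_set = bs, noise_sd = 0, baseline_drift = c(0, 0))
  s <- ftir_spectrum(aligned_grid(), grindcurve:::.synth_clean(p, 0, 1,
                                                               aligned_grid()))
  expect_lt(abs(compute_fwhm_v3(s)$fwhm - 2 * sqrt(2 * log(2)) * 14), 0.1)
})

test_that("noise-free grinding trajectories are monotone and collinear", {
  p <- synth_params(seed = 12, noise_sd = 0, irsf_jitter_sd = 0,
                    replicate_jitter_sd = 0)
  m <- lapply(synth_grinding_series(p), compute_band_metrics)
  irsf <- vapply(m, function(x) x$irsf$irsf, 0)
  fwhm <- vapply(m, function(x) x$fwhm$fwhm, 0)
  expect_true(all(diff(irsf) > 0))
  expect_true(all(diff(fwhm) < 0))
  cu <- fit_grinding_curve(m)
  expect_gt(cu$r2, 1 - 1e-6)
  # solved particle-size kernels shrink with grinding
  tr <- attr(synth_grinding_series(p), "truth")
  expect_true(all(diff(tr$kernel_width) < 0))
})

test_that("forward mode with explicit kernels is monotone too", {
  p <- synth_params(seed = 3, noise_sd = 0, irsf_jitter_sd = 0,
                    replicate_jitter_sd = 0,
                    grinding_kernel_widths = c(10, 7, 4))
  m <- lapply(synth_grinding_series(p), compute_band_metrics)
  expect_true(all(diff(vapply(m, function(x) x$irsf$irsf, 0)) > 0))
  expect_true(all(diff(vapply(m, function(x) x$fwhm$fwhm, 0)) < 0))
})

test_that("grinding moves points along the curve; crystallinity moves the curve", {
  base <- list(seed = 5, noise_sd = 0, irsf_jitter_sd = 0,
               replicate_jitter_sd = 0)
  p_lo <- do.call(synth_params, c(base, crystallinity = 0.84))
  p_hi <- do.call(synth_params, c(base, crystallinity = 0.96))
  line_of <- function(p) {
    m <- lapply(synth_grinding_series(p), compute_band_metrics)
    fit_grinding_curve(m)
  }
  cu_lo <- line_of(p_lo); cu_hi <- line_of(p_hi)
  # same grinding targets: identical IRSF coordinates (along-curve motion)
  expect_equal(cu_lo$points$irsf, cu_hi$points$irsf, tolerance = 1e-6)
  # higher order: whole curve lower at matched IRSF, by the known amount
  want <- 52 / 0.96 - 52 / 0.84
  got <- mean(cu_hi$points$fwhm - cu_lo$points$fwhm)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("default-noise grinding series keep r2 above 0.9", {
  for (seed in 1:25) {
    p <- synth_params(seed = seed, crystallinity = 0.8 + 0.15 * (seed %% 5) / 5)
    cu <- fit_grinding_curve(lapply(synth_grinding_series(p),
                                    compute_band_metrics))
    expect_gt(cu$r2, 0.9)
  }
})

test_that("two-grinding series yield minimal curves", {
  p <- synth_params(seed = 8)
  ser <- synth_grinding_series(p, n_grindings = 2)
  expect_length(ser, 2)
  cu <- fit_grinding_curve(lapply(ser, compute_band_metrics))
  expect_equal(cu$flag, "minimal")
  expect_error(synth_grinding_series(p, n_grindings = 1), ">= 2")
})

test_that("shift_for_offset inverts the latent-line anchor", {
  p <- synth_params(crystallinity = 0.82)
  sh <- shift_for_offset(p, -8)
  expect_equal(52 / (0.82 + sh) - 52 / 0.82, -8)
  expect_error(shift_for_offset(synth_params(crystallinity = 0.99), -8),
               "outside")
})

test_that("assemblage truth records exact injected offsets and labels", {
  p <- synth_params(crystallinity = 0.82, seed = 31)
  shifts <- c(0, shift_for_offset(p, -2), shift_for_offset(p, -8))
  asm <- synth_assemblage(p, n_reference_replicates = 3, fossils = shifts)
  expect_length(asm$reference, 3)
  expect_length(asm$fossils, 3)
  expect_equal(asm$truth$injected_offset, c(0, -2, -8), tolerance = 1e-10)
  expect_equal(asm$truth$label,
               c("overlapping", "offset_ordered", "offset_disordered")[
                 c(1, 2, 2)])
})

test_that("the screening pipeline recovers a large injected offset", {
  p <- synth_params(crystallinity = 0.82, seed = 19,
                    replicate_jitter_sd = 1.5)
  asm <- synth_assemblage(p, n_reference_replicates = 5,
                          fossils = shift_for_offset(p, -8))
  ref <- pool_reference(lapply(asm$reference, function(ser)
    fit_grinding_curve(lapply(ser, compute_band_metrics))))
  test <- fit_grinding_curve(lapply(asm$fossils[[1]], compute_band_metrics))
  a <- assess_offset(test, ref)
  expect_equal(a$label, "offset_ordered")
  expect_equal(a$mean_offset, -8, tolerance = 0.25 * 8)
})

test_that("written libraries mirror the deposited layout", {
  dir <- withr::local_tempdir()
  res <- write_synthetic_library(dir, seed = 2, species = c("Giraffe", "Eland"),
                                 crystallinity = c(0.85, 0.9),
                                 n_replicates = 2, n_grindings = 3,
                                 formats = c("csv", "jdx"))
  expect_length(res$files, 2 * 2 * 3 * 2)
  expect_true(file.exists(file.path(dir, "Giraffe2_03.csv")))
  expect_true(file.exists(file.path(dir, "Eland1_01.jdx")))
  expect_equal(nrow(res$truth), 12)
  # determinism across calls
  dir2 <- withr::local_tempdir()
  write_synthetic_library(dir2, seed = 2, species = c("Giraffe", "Eland"),
                          crystallinity = c(0.85, 0.9),
                          n_replicates = 2, n_grindings = 3,
                          formats = c("csv", "jdx"))
  expect_identical(readLines(file.path(dir, "Giraffe1_02.csv")),
                   readLines(file.path(dir2, "Giraffe1_02.csv")))
})
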
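test_that("collinear points give an exact line with r2 = 1", {
  cu <- fit_grinding_curve(data.frame(irsf = c(2.5, 3.0, 3.5),
                                      fwhm = c(60, 50, 40)))
  expect_equal(cu$slope, -20)
  expect_equal(cu$intercept, 110)
  expect_equal(cu$r2, 1.0)
  expect_equal(cu$flag, "standard")
})

test_that("two points fit exactly but are flagged minimal", {
  cu <- fit_grinding_curve(data.frame(irsf = c(2.5, 3.5), fwhm = c(60, 40)))
  expect_equal(cu$slope, -20)
  expect_equal(cu$r2, 1.0)
  expect_equal(cu$flag, "minimal")
})

test_that("ill-posed curves are rejected", {
  expect_error(fit_grinding_curve(data.frame(irsf = 3, fwhm = 50)),
               "at least 2")
  expect_error(fit_grinding_curve(data.frame(irsf = c(3, 3, 3),
                                             fwhm = c(50, 48, 46))),
               "vertical")
  expect_error(fit_grinding_curve(data.frame(irsf = c(2.5, 3, 3.5),
                                             fwhm = c(60, 50, 40),
                                             grinding = c(1, 2, 2))),
               "duplicate grinding")
})

test_that("least-squares fit matches the normal-equations oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    x <- sort(runif(n, 2.2, 4.5))
    y <- 95 - 9 * x + rnorm(n, 0, 1.2)
    cu <- fit_grinding_curve(data.frame(irsf = x, fwhm = y))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # independent normal equations
    expect_equal(cu$intercept, beta[1], tolerance = 1e-10)
    expect_equal(cu$slope, beta[2], tolerance = 1e-10)
    sst <- sum((y - mean(y))^2)
    ssr <- sum((y - X %*% beta)^2)
    expect_equal(cu$r2, 1 - ssr / sst, tolerance = 1e-10)
    # r2 is symmetric in which variable is the predictor
    swap <- fit_grinding_curve(data.frame(irsf = y, fwhm = x))
    expect_equal(swap$r2, cu$r2, tolerance = 1e-12)
  }
})

test_that("identical replicates pool to themselves with zero spread", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  curves <- lapply(1:5, function(i) fit_grinding_curve(pts))
  ref <- pool_reference(curves, species = "Test")
  expect_equal(ref$slope, -20)
  expect_equal(ref$intercept, 110)
  expect_equal(ref$replicate_spread, 0)
  expect_equal(ref$n_replicates, 5)
  expect_equal(ref$irsf_range, c(2.5, 3.5))
})

test_that("a single replicate pools to itself and is flagged", {
  cu <- fit_grinding_curve(data.frame(irsf = c(2.5, 3, 3.5),
                                      fwhm = c(61, 50, 41)))
  ref <- pool_reference(list(cu))
  expect_equal(ref$slope, cu$slope)
  expect_equal(ref$replicate_spread, 0)
  expect_equal(ref$flag, "single_replicate")
})

test_that("mixed-species replicates are refused", {
  mk <- function(sp) fit_grinding_curve(
    data.frame(irsf = c(2.5, 3.5), fwhm = c(60, 40)),
    key = list(species = sp, replicate = 1))
  expect_error(pool_reference(list(mk("Giraffe"), mk("Impala"))), "mixed species")
})

test_that("replicate spread recovers the injected jitter at n = 5", {
  set.seed(2024)
  sigma_rep <- 1.5
  est <- replicate(200, {
    curves <- lapply(1:5, function(r) {
      e <- rnorm(1, 0, sigma_rep)
      x <- c(2.6, 3.3, 4.0)
      fit_grinding_curve(data.frame(irsf = x,
                                    fwhm = 85 - 8 * x + e + rnorm(3, 0, 0.1)))
    })
    pool_reference(curves, species = "Sim")$replicate_spread
  })
  expect_lt(abs(mean(est) - sigma_rep) / sigma_rep, 0.4)
})

test_that("a test identical to the reference is overlapping with zero offset", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  ref <- pool_reference(lapply(1:3, function(i) fit_grinding_curve(pts)))
  a <- assess_offset(fit_grinding_curve(pts), ref)
  expect_equal(a$mean_offset, 0)
  expect_equal(a$label, "overlapping")
  expect_equal(a$spread_used, 0.5)   # floored
})

test_that("tests outside the reference IRSF range report insufficient overlap", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  ref <- pool_reference(lapply(1:3, function(i) fit_grinding_curve(pts)))
  far <- fit_grinding_curve(data.frame(irsf = c(4.0, 4.5), fwhm = c(30, 25)))
  a <- assess_offset(far, ref)
  expect_equal(a$label, "insufficient_overlap")
  expect_true(is.na(a$score))
  # marginal overlap below the configured fraction is also refused
  graze <- fit_grinding_curve(data.frame(irsf = c(3.45, 4.2), fwhm = c(41, 33)))
  expect_equal(assess_offset(graze, ref, min_overlap_fraction = 0.25)$label,
               "insufficient_overlap")
})

test_that("offset sign encodes the direction of atomic order", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  ref <- pool_reference(lapply(1:3, function(i) fit_grinding_curve(pts)))
  down <- pts; down$fwhm <- down$fwhm - 8   # more ordered: lower FWHM
  a <- assess_offset(fit_grinding_curve(down), ref)
  expect_equal(a$mean_offset, -8)
  expect_equal(a$label, "offset_ordered")
  up <- pts; up$fwhm <- up$fwhm + 8
  expect_equal(assess_offset(fit_grinding_curve(up), ref)$label,
               "offset_disordered")
})

test_that("mean offset is antisymmetric for matched IRSF ranges", {
  x <- c(2.6, 3.1, 3.6)
  a_pts <- data.frame(irsf = x, fwhm = 88 - 9 * x)
  b_pts <- data.frame(irsf = x, fwhm = 83 - 9 * x)
  ref_a <- pool_reference(list(fit_grinding_curve(a_pts)))
  ref_b <- pool_reference(list(fit_grinding_curve(b_pts)))
  o_ab <- assess_offset(fit_grinding_curve(a_pts), ref_b)$mean_offset
  o_ba <- assess_offset(fit_grinding_curve(b_pts), ref_a)$mean_offset
  expect_equal(o_ab, -o_ba, tolerance = 1e-10)
  expect_equal(o_ab, 5)
})

test_that("screening ranks by |score| and recommends overlapping samples", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  ref <- pool_reference(lapply(1:5, function(i) fit_grinding_curve(pts)))
  shift <- function(d) {
    q <- pts; q$fwhm <- q$fwhm + d; fit_grinding_curve(q)
  }
  tests <- list(clean = shift(0), mild = shift(-0.6), bad = shift(-6),
                far = fit_grinding_curve(data.frame(irsf = c(5, 6),
                                                    fwhm = c(20, 10))))
  rep <- screen_assemblage(tests, ref)
  expect_equal(rep$sample, c("clean", "mild", "bad", "far"))
  expect_equal(rep$label, c("overlapping", "overlapping", "offset_ordered",
                            "insufficient_overlap"))
  expect_equal(rep$recommended, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("identical tests sort stably by sample id", {
  pts <- data.frame(irsf = c(2.5, 3.0, 3.5), fwhm = c(60, 50, 40))
  ref <- pool_reference(lapply(1:3, function(i) fit_grinding_curve(pts)))
  tests <- list(b = fit_grinding_curve(pts), a = fit_grinding_curve(pts),
                c = fit_grinding_curve(pts))
  expect_equal(screen_assemblage(tests, ref)$sample, c("a", "b", "c"))
})
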
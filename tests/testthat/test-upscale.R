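daily_scene <- function(values, year = 2021, nr = 2, nc = 2) {
  nt <- length(values)
  arr <- array(rep(values, each = nr * nc), c(nr, nc, nt))
  grid_scene(list(v = arr), geotransform = c(0.5, 1, nr - 0.5, 1),
             time = as.Date(sprintf("%d-01-01", year)) + seq_len(nt) - 1)
}

test_that("unit conversions follow carbon molar-mass arithmetic", {
  expect_equal(convert_flux_units(1, "umol m-2 s-1", "gC m-2 d-1"),
               12.011e-6 * 86400, tolerance = 1e-12)
  expect_equal(convert_flux_units(0, "umol m-2 s-1", "gC m-2 y-1"), 0)
  set.seed(1); v <- rnorm(20)
  round_trip <- convert_flux_units(
    convert_flux_units(v, "umol m-2 s-1", "gC m-2 y-1"),
    "gC m-2 y-1", "umol m-2 s-1")
  expect_equal(round_trip, v, tolerance = 1e-12)
  expect_error(convert_flux_units(1, "umol m-2 s-1", "furlongs"),
               "unsupported")
})

test_that("8-day compositing averages windows and handles year end", {
  sc <- daily_scene(rep(7, 8))
  cp <- composite_8day(sc)
  expect_equal(cp$ntime, 1)
  expect_equal(unname(cp$bands$v[1, 1, 1]), 7)

  cp2 <- composite_8day(daily_scene(1:8))
  expect_equal(unname(cp2$bands$v[1, 1, 1]), 4.5)

  # a full 365-day year: 46 composites, the last built from 5 days
  cp3 <- composite_8day(daily_scene(seq_len(365)))
  expect_equal(cp3$ntime, 46)
  expect_equal(unname(cp3$bands$v[1, 1, 46]), mean(361:365))
  expect_equal(as.Date(cp3$time[46]), as.Date("2021-01-01") + 45 * 8)

  # fewer than min_valid_days valid days: masked, not an error
  vals <- c(1, 2, 3, rep(NA, 5))
  cp4 <- composite_8day(daily_scene(vals))
  expect_true(is.na(cp4$bands$v[1, 1, 1]))
})

test_that("bilinear resampling reproduces constants and hand weights", {
  const <- grid_scene(list(v = matrix(3.3, 4, 4)),
                      geotransform = c(0.5, 1, 3.5, 1))
  up <- resample_to_grid(const, c(0.25, 0.5, 3.75, 0.5), 8, 8, "bilinear")
  expect_equal(unname(as.vector(up$bands$v)), rep(3.3, 64))

  # 2x2 field ((0,0),(1,1)): values depend linearly on the row coordinate
  f <- grid_scene(list(v = matrix(c(0, 1, 0, 1), 2, 2)),
                  geotransform = c(0.5, 1, 1.5, 1))
  up2 <- resample_to_grid(f, c(0.25, 0.5, 1.75, 0.5), 4, 4, "bilinear")
  # target row centres at y = 1.75, 1.25, 0.75, 0.25 -> source row index
  # 0.75, 1.25, 1.75, 2.25; interior rows interpolate linearly
  expect_equal(unname(up2$bands$v[2, 2, 1]), 0.25)
  expect_equal(unname(up2$bands$v[3, 2, 1]), 0.75)

  # categorical nearest introduces no new labels
  cat_f <- grid_scene(list(v = matrix(c(1, 2, 3, 4), 2, 2)),
                      geotransform = c(0.5, 1, 1.5, 1))
  up3 <- resample_to_grid(cat_f, c(0.25, 0.5, 1.75, 0.5), 4, 4, "nearest")
  expect_true(all(up3$bands$v %in% 1:4))

  far <- grid_scene(list(v = matrix(1, 2, 2)),
                    geotransform = c(1000.5, 1, 1001.5, 1))
  expect_error(resample_to_grid(far, c(0.5, 1, 1.5, 1), 2, 2), "overlap")
})

test_that("resampling does not interpolate across nodata", {
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  sc <- grid_scene(list(v = m), geotransform = c(0.5, 1, 2.5, 1))
  up <- resample_to_grid(sc, c(0.3, 0.6, 2.7, 0.6), 5, 5, "bilinear")
  # valid neighbours all equal 1, so every valid output must be exactly 1
  out <- up$bands$v
  expect_true(all(out[is.finite(out)] == 1))
})

test_that("bilinear resampling preserves the spatial mean of smooth fields", {
  for (seed in 1:5) {
    set.seed(seed)
    # smooth field: coarse noise around 10, bilinearly enlarged first
    src <- resample_to_grid(
      grid_scene(list(v = matrix(10 + rnorm(16), 4, 4)),
                 geotransform = c(0.5, 2, 6.5, 2)),
      c(0.25, 0.5, 7.75, 0.5), 16, 16, "bilinear")
    # 2x finer target covering the same extent (pixel-centre convention)
    fine <- resample_to_grid(src, c(0.125, 0.25, 7.875, 0.25), 32, 32,
                             "bilinear")
    expect_equal(mean(fine$bands$v), mean(src$bands$v),
                 tolerance = 5e-3)
  }
})

test_that("predict_map equals point prediction and is chunk-invariant", {
  p <- sample_predictors(40, seed = 17)
  fl <- generate_fluxes(p, seed = 18)
  fit <- gpr_fit(training_matrix(as.matrix(p), fl$GPP, "GPP"),
                 restarts = 1, maxit = 60, seed = 1)

  # 1-pixel scene = the first training row
  bands <- lapply(as.list(p[1, , drop = FALSE]), function(v) matrix(v, 1, 1))
  sc1 <- grid_scene(bands, time = as.Date("2020-01-01"))
  fm1 <- predict_map(fit, sc1)
  pt <- predict(fit, as.matrix(p[1, , drop = FALSE]))
  expect_equal(unname(fm1$estimate[1, 1, 1]), pt$mean)
  expect_equal(unname(fm1$sigma[1, 1, 1]), pt$sigma)

  # chunk-size invariance, bitwise
  nr <- 5; nc <- 4
  idx <- matrix(sample(40, nr * nc, replace = TRUE), nr, nc)
  bands2 <- lapply(names(p), function(b) matrix(p[[b]][idx], nr, nc))
  names(bands2) <- names(p)
  sc2 <- grid_scene(bands2, time = as.Date("2020-01-01"))
  f_small <- predict_map(fit, sc2, chunk_size = 1L)
  f_big <- predict_map(fit, sc2, chunk_size = 4096L)
  expect_identical(f_small$estimate, f_big$estimate)
  expect_identical(f_small$sigma, f_big$sigma)

  sc_missing <- grid_scene(bands2[-1], time = as.Date("2020-01-01"))
  expect_error(predict_map(fit, sc_missing), "missing predictor")
})

test_that("a noise-free model lifts its training row across a scene", {
  p <- sample_predictors(30, seed = 19)
  y <- attr(generate_fluxes(p, noise_sd = 0, seed = 1), "truth")$GPP
  tm <- training_matrix(as.matrix(p), y, "GPP")
  m <- manual_gpr(tm$X, tm$y, 1, rep(1, tm$D), 0)
  m$training <- tm
  row7 <- p[7, , drop = FALSE]
  bands <- lapply(as.list(row7), function(v) matrix(v, 3, 3))
  fm <- predict_map(m, grid_scene(bands, time = as.Date("2020-01-01")))
  expect_equal(unname(as.vector(fm$estimate)), rep(y[7], 9), tolerance = 1e-6)
  expect_lt(max(fm$sigma), 1e-4)
})

test_that("out-of-range pixels are clamped and flagged (or masked)", {
  p <- sample_predictors(30, seed = 23)
  fl <- generate_fluxes(p, seed = 24)
  fit <- gpr_fit(training_matrix(as.matrix(p), fl$GPP, "GPP"),
                 restarts = 1, maxit = 50, seed = 1)
  bands <- lapply(as.list(p[2, , drop = FALSE]), function(v) matrix(v, 2, 2))
  bands$LAI[1, 1] <- 11  # above the schema maximum of 9.38
  sc <- grid_scene(bands, time = as.Date("2020-01-01"))
  fm <- predict_map(fit, sc)
  expect_equal(unname(fm$flags[1, 1, 1]), 1)
  expect_equal(unname(fm$flags[2, 2, 1]), 0)
  expect_true(is.finite(fm$estimate[1, 1, 1]))
  clamped <- bands; clamped$LAI[1, 1] <- 9.38
  fm_ref <- predict_map(fit, grid_scene(clamped,
                                        time = as.Date("2020-01-01")))
  expect_equal(fm$estimate[1, 1, 1], fm_ref$estimate[1, 1, 1])

  fm_mask <- predict_map(fit, sc, range_mode = "mask")
  expect_true(is.na(fm_mask$estimate[1, 1, 1]))
})

test_that("annual totals follow unit arithmetic, linearity and masking", {
  nt <- 46
  est <- array(1, c(2, 2, nt))
  fm <- make_fmap(est, est * 0, year = 2021)
  ann <- aggregate_annual(fm)
  expect_equal(unname(ann$estimate[1, 1, 1]), 12.011e-6 * 86400 * 365,
               tolerance = 1e-10)
  expect_equal(ann$units, "gC m-2 y-1")

  # doubling every composite doubles the annual total
  fm2 <- make_fmap(est * 2, est * 0, year = 2021)
  expect_equal(aggregate_annual(fm2)$estimate, ann$estimate * 2)

  # fully masked pixel stays masked; low coverage masks too
  est3 <- est; est3[1, 1, ] <- NA
  est3[2, 2, 1:20] <- NA  # 26 composites ~ 205 days < 80% of 365
  ann3 <- aggregate_annual(make_fmap(est3, est3 * 0, year = 2021))
  expect_true(is.na(ann3$estimate[1, 1, 1]))
  expect_true(is.na(ann3$estimate[2, 2, 1]))
  expect_false(is.na(ann3$estimate[1, 2, 1]))

  # invariance to splitting the year's composites into batches is implied
  # by the weighted-mean form; check weights: leap year last window 6 days
  fm_leap <- flux_map(array(1, c(1, 1, 46)), array(0, c(1, 1, 46)),
                      "GPP", period = as.Date("2020-01-01") +
                        (0:45) * 8)
  ann_leap <- aggregate_annual(fm_leap)
  expect_equal(unname(ann_leap$estimate[1, 1, 1]),
               12.011e-6 * 86400 * 366, tolerance = 1e-10)
})

test_that("sigma aggregates as day-weighted RMS", {
  sig <- array(rep(c(2, 4), each = 1, times = 23), c(1, 1, 46))
  fm <- make_fmap(array(1, c(1, 1, 46)), sig, year = 2021)
  ann <- aggregate_annual(fm)
  w <- c(rep(8, 45), 5)
  expected_rms <- sqrt(sum(w * as.vector(sig)^2) / sum(w))
  expect_equal(unname(ann$sigma[1, 1, 1]),
               convert_flux_units(expected_rms, "umol m-2 s-1",
                                  "gC m-2 y-1"), tolerance = 1e-10)
})
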
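test_that("metrics match hand-computed cases", {
  m1 <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m1$r2, 1); expect_equal(m1$rmse, 0); expect_equal(m1$nrmse, 0)

  m2 <- compute_metrics(c(0, 2), c(1, 1))
  expect_equal(m2$rmse, 1)
  expect_equal(m2$nrmse, 50)

  m3 <- compute_metrics(c(1, 2, 3), c(3, 2, 1))  # SS_res 8, SS_tot 2
  expect_equal(m3$r2, -3)

  m4 <- compute_metrics(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(m4$nrmse))
  expect_match(m4$nrmse_reason, "constant")
})

test_that("metrics are order-invariant and bounded above by 1", {
  set.seed(2)
  obs <- rnorm(50); pred <- obs + rnorm(50, 0, 0.3)
  perm <- sample(50)
  m <- compute_metrics(obs, pred)
  mp <- compute_metrics(obs[perm], pred[perm])
  expect_equal(m$r2, mp$r2); expect_equal(m$rmse, mp$rmse)
  expect_lte(m$r2, 1)
  # affine recalibration of obs: r2 equals squared Pearson correlation
  pred_aff <- 2 * obs + 1
  fitted <- fitted(lm(obs ~ pred_aff))
  m_aff <- compute_metrics(obs, fitted)
  expect_equal(m_aff$r2, cor(obs, pred_aff)^2, tolerance = 1e-12)
})

test_that("fold plans are balanced, disjoint and exhaustive", {
  pl <- make_folds(1369, 10, seed = 3)
  sizes <- tabulate(pl$assignment, 10)
  expect_equal(sort(sizes), c(136, rep(137, 9)))
  expect_equal(sort(unique(pl$assignment)), 1:10)
  expect_equal(length(pl$assignment), 1369)
  # train sizes are 1232 or 1233
  expect_true(all((1369 - sizes) %in% c(1232, 1233)))

  loo <- make_folds(10, 10, seed = 1)
  expect_equal(sort(tabulate(loo$assignment, 10)), rep(1, 10))

  expect_identical(make_folds(100, 10, seed = 7)$assignment,
                   make_folds(100, 10, seed = 7)$assignment)
  expect_error(make_folds(5, 10), "exceeds")
})

test_that("stratified folds preserve class proportions within rounding", {
  set.seed(4)
  cls <- sample(c("A", "B", "C"), 300, replace = TRUE, prob = c(.5, .3, .2))
  pl <- make_folds(300, 10, seed = 2, strat_key = cls)
  sizes <- tabulate(pl$assignment, 10)
  expect_lte(diff(range(sizes)), 1)
  for (g in unique(cls)) {
    per_fold <- tabulate(pl$assignment[cls == g], 10)
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("training-table assembly filters, averages and audits", {
  p <- sample_predictors(5, seed = 3)
  df <- cbind(data.frame(site_id = paste0("S", 1:5),
                         date = as.Date("2020-01-01") + 1:5,
                         vegetation_class = "ENF"),
              p, GPP = 1:5)
  df$SW[2] <- NA
  # need >= 10 rows to survive: replicate valid ones
  big <- do.call(rbind, replicate(4, df, simplify = FALSE))
  big$site_id <- paste0(big$site_id, rep(1:4, each = 5))
  tm <- assemble_training_table(big, "GPP")
  expect_equal(tm$audit$dropped[["missing predictor SW"]], 4)
  expect_equal(tm$n, 16)

  # out-of-range target predictor is dropped with its own audit rule
  big2 <- big; big2$LAI[1] <- 12
  tm2 <- assemble_training_table(big2, "GPP")
  expect_equal(tm2$audit$dropped[["out-of-range LAI"]], 1)

  # sub-daily rows average to daily means before matching
  dup <- big[c(1, 1), ]; dup$SW <- c(10, 20)
  both <- rbind(big[-1, ], dup)
  tm3 <- assemble_training_table(both, "GPP")
  i <- which(tm3$site_id == big$site_id[1] & tm3$date == big$date[1])
  sw_raw <- tm3$X[i, "SW"] * tm3$x_scale["SW"] + tm3$x_mean["SW"]
  expect_equal(unname(sw_raw), 15)

  expect_error(assemble_training_table(df, "GPP"), "at least 10")
})

test_that("cross-validation covers every sample exactly once", {
  tt <- generate_tower_table(60, seed = 11)
  tm <- assemble_training_table(tt, "GPP")
  cv <- cross_validate(tm, k = 5, seed = 2, restarts = 1, maxit = 60)
  expect_equal(sort(unique(cv$pairs$fold)), 1:5)
  expect_true(all(is.finite(cv$pairs$pred)))
  expect_equal(nrow(cv$pairs), tm$n)
  expect_equal(cv$pooled$n, tm$n)
})

test_that("injected perfect predictions give r2 = 1 and null targets ~ 0", {
  expect_equal(compute_metrics(1:20, 1:20)$r2, 1)

  # target independent of the predictors: pooled R2 near zero or below
  set.seed(13)
  p <- sample_predictors(80, seed = 13)
  tm <- training_matrix(as.matrix(p), rnorm(80), "GPP")
  cv <- cross_validate(tm, k = 5, seed = 3, restarts = 1, maxit = 60)
  expect_lte(cv$pooled$r2, 0.05)
})

test_that("a smooth noiseless target is recovered almost perfectly", {
  p <- sample_predictors(400, seed = 21)
  fl <- generate_fluxes(p, noise_sd = 0, seed = 1)
  tm <- training_matrix(as.matrix(p), fl$GPP, "GPP")
  cv <- cross_validate(tm, k = 5, seed = 4, restarts = 1, maxit = 100)
  expect_gte(cv$pooled$r2, 0.99)
})
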
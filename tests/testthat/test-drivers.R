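test_that("ARD relevance scales inverse lengthscales to max 1", {
  m <- manual_gpr(matrix(rnorm(30), 10, 3), rnorm(10), 1,
                  c(x1 = 1, x2 = 2, x3 = 4), 0.1)
  rs <- ard_relevance(m)
  expect_equal(rs$score, c(1, 0.5, 0.25))
  expect_equal(rs$predictor, c("x1", "x2", "x3"))

  # tied lengthscales share the score
  m2 <- manual_gpr(matrix(rnorm(30), 10, 3), rnorm(10), 1, rep(2, 3), 0.1)
  expect_equal(ard_relevance(m2)$score, rep(1, 3))
})

test_that("a planted-irrelevant predictor gets the minimum ARD score", {
  set.seed(7)
  n <- 250
  X <- cbind(runif(n, 0, 6), runif(n, 0, 300), rnorm(n))
  colnames(X) <- c("LAI", "SW", "NOISE")
  y <- 4 * (1 - exp(-0.5 * X[, 1])) * X[, 2] / (X[, 2] + 100) +
    rnorm(n, 0, 0.1)
  fit <- gpr_fit(training_matrix(X, y), restarts = 2, maxit = 120, seed = 3)
  rs <- ard_relevance(fit)
  expect_equal(rs$predictor[which.min(rs$score)], "NOISE")
})

test_that("pearson matches hand computation and its invariants", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(pearson(x, y), 0.6, tolerance = 1e-12)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_true(is.na(pearson(c(1, 1, 1), y[1:3])))
  expect_error(pearson(1:2, 1:2), "at least 3")
  # positive affine invariance
  set.seed(5); a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(2 * a + 3, b), pearson(a, b), tolerance = 1e-12)
})

test_that("spearman is pearson on mid-ranks, exactly, including ties", {
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:8, 15, replace = TRUE)  # plenty of ties
    y <- sample(1:8, 15, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y), pearson(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
  xs <- c(1, 2, 4, 8, 16)
  expect_equal(spearman(xs, exp(xs / 4)), 1)       # monotone invariance
  expect_equal(spearman(xs, rev(xs)), -1)
  expect_equal(spearman(c(1, 1, 2), c(1, 2, 3)),
               pearson(rank(c(1, 1, 2)), rank(c(1, 2, 3))))
})

test_that("regional series average unmasked pixels only", {
  m1 <- matrix(1:16, 4, 4)
  arr <- array(c(m1, m1 * 2), c(4, 4, 2))
  sc <- grid_scene(list(v = arr), geotransform = c(0.5, 1, 3.5, 1),
                   time = 1:2)
  one <- regional_series(sc, list(rows = 2, cols = 3))
  expect_equal(one$v, c(m1[2, 3], 2 * m1[2, 3]))

  arrm <- arr; arrm[, 1:2, ] <- NA
  scm <- grid_scene(list(v = arrm), geotransform = c(0.5, 1, 3.5, 1),
                    time = 1:2)
  half <- regional_series(scm, list(rows = 1:4, cols = 1:4))
  expect_equal(half$v[1], mean(m1[, 3:4]))

  # linear-in-x field: region mean = mean of pixel-centre x values
  xs <- matrix(rep(1:4, each = 4), 4, 4)  # value = column index = x + 0.5
  scl <- grid_scene(list(v = xs), geotransform = c(0.5, 1, 3.5, 1), time = 1)
  got <- regional_series(scl, list(xmin = 0, xmax = 2.6, ymin = 0, ymax = 4))
  expect_equal(got$v, mean(1:3))

  expect_error(regional_series(sc, list(xmin = 90, xmax = 99,
                                        ymin = 90, ymax = 99)),
               "intersect")
})

test_that("correlation tables flag generator-driven couplings", {
  # region whose GPP variability comes from radiation alone: the other
  # generative drivers are held flat, two bystander bands are white noise
  set.seed(31)
  nt <- 46; nr <- 4; nc <- 4
  mk <- function(v) array(rep(v, each = nr * nc), c(nr, nc, nt))
  sw <- 180 + 150 * sin(2 * pi * (1:nt) / nt) + rnorm(nt, 0, 5)
  bands <- list(LAI = mk(rep(3, nt)), SW = mk(sw),
                SWC_1 = mk(rep(30, nt)), TA = mk(rep(18, nt)),
                TS_1 = mk(rep(12, nt)),
                H = mk(rnorm(nt, 40, 10)), WS = mk(rnorm(nt, 3, 0.5)))
  pred_sc <- grid_scene(bands, time = seq_len(nt))
  pt <- data.frame(LAI = 3, SW = sw, SWC_1 = 30, TA = 18, TS_1 = 12)
  g <- attr(generate_fluxes(pt, noise_sd = 0), "truth")$GPP
  gpp <- flux_map(mk(g), mk(g) * 0, variable = "GPP",
                  period = seq_len(nt))
  regions <- list(all = list(rows = 1:nr, cols = 1:nc))
  tab <- correlation_heatmap(regions, gpp, pred_sc)
  expect_s3_class(tab, "correlation_table")
  expect_true(all(abs(tab$pearson) <= 1, na.rm = TRUE))
  expect_equal(unique(tab$n), nt)
  ord <- tab$predictor[order(-abs(tab$pearson))]
  expect_true("SW" %in% ord[1:2])

  # predictor identical to the flux: both coefficients exactly 1
  self_sc <- grid_scene(list(GPPcopy = mk(g)), time = seq_len(nt))
  tab2 <- correlation_heatmap(regions, gpp, self_sc)
  expect_equal(tab2$pearson, 1)
  expect_equal(tab2$spearman, 1)
})

test_that("white-noise predictors rarely correlate at n = 46", {
  set.seed(99)
  hits <- 0; trials <- 40
  for (i in 1:trials) {
    flux <- sin(2 * pi * (1:46) / 46) + rnorm(46, 0, 0.2)
    noise <- rnorm(46)
    if (abs(pearson(flux, noise)) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})
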
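test_that("kernel matches hand evaluations and the ARD limit", {
  # zero distance: diagonal equals the signal variance
  x <- matrix(c(0.3, -1.2), 1, 2)
  expect_equal(gpr_kernel(x, x, 2.5, c(1, 1))[1, 1], 2.5)

  # hand evaluation: unit lengthscales, x = (0,0), x' = (1,1) -> exp(-1)
  A <- matrix(0, 1, 2); B <- matrix(1, 1, 2)
  expect_equal(gpr_kernel(A, B, 1, c(1, 1))[1, 1], exp(-1), tolerance = 1e-12)

  # a huge lengthscale removes that coordinate's influence
  B2 <- matrix(c(1, 57), 1, 2)
  k_inf <- gpr_kernel(A, B2, 1, c(1, 1e9))[1, 1]
  k_ref <- gpr_kernel(A, matrix(c(1, 0), 1, 2), 1, c(1, 1e9))[1, 1]
  expect_equal(k_inf, k_ref, tolerance = 1e-8)

  expect_error(gpr_kernel(matrix(0, 1, 2), matrix(0, 1, 3), 1, c(1, 1)),
               "dimension mismatch")
})

test_that("self-kernels are symmetric and positive semi-definite", {
  for (seed in 1:10) {
    inst <- random_instance(seed, n = 15, D = 4)
    K <- gpr_kernel(inst$Xs, inst$Xs, inst$sv, inst$ell)
    expect_equal(max(abs(K - t(K))), 0)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K)) / nrow(K))
  }
})

test_that("log marginal likelihood matches the scalar closed form", {
  # n = 1: lml = -y^2/(2c) - log(c)/2 - log(2*pi)/2 with c = sv + nv
  sv <- 1.7; nv <- 0.3; y1 <- 0.9
  got <- gpr_lml(log(c(sv, 1.1, nv)), matrix(0.4, 1, 1), y1)$value
  c_ <- sv + nv
  expect_equal(got, -y1^2 / (2 * c_) - 0.5 * log(c_) - 0.5 * log(2 * pi),
               tolerance = 1e-9)
})

test_that("lml is scale-equivariant: scaling y by 2 and variances by 4", {
  inst <- random_instance(3, n = 9, D = 2)
  l1 <- gpr_lml(log(c(inst$sv, inst$ell, inst$nv)), inst$Xs, inst$ys)$value
  l2 <- gpr_lml(log(c(4 * inst$sv, inst$ell, 4 * inst$nv)), inst$Xs,
                2 * inst$ys)$value
  # quadratic term unchanged; log-det picks up n*log(4)/2 = n*log(2)
  expect_equal(l2, l1 - length(inst$ys) * log(2), tolerance = 1e-8)
})

test_that("analytic lml gradient matches central finite differences", {
  for (seed in 1:15) {
    inst <- random_instance(seed, n = 8, D = 3)
    th <- log(c(inst$sv, inst$ell, inst$nv))
    g <- gpr_lml(th, inst$Xs, inst$ys)$grad
    h <- 1e-5
    g_fd <- vapply(seq_along(th), function(k) {
      e <- th; e[k] <- e[k] + h; up <- gpr_lml(e, inst$Xs, inst$ys)$value
      e[k] <- e[k] - 2 * h; dn <- gpr_lml(e, inst$Xs, inst$ys)$value
      (up - dn) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - g_fd) / pmax(abs(g_fd), 1e-6)), 1e-5)
  }
})

test_that("Cholesky predictions match the dense-inverse brute force", {
  for (seed in 1:25) {
    inst <- random_instance(seed, n = sample(3:20, 1), D = sample(1:5, 1))
    m <- manual_gpr(inst$Xs, inst$ys, inst$sv, inst$ell, inst$nv)
    pr <- predict(m, inst$Xq)
    or <- gp_bruteforce(inst$Xs, inst$ys, inst$sv, inst$ell, inst$nv, inst$Xq)
    expect_equal(pr$mean, or$mean, tolerance = 1e-8)
    expect_equal(pr$sigma^2, or$var, tolerance = 1e-8)
  }
})

test_that("noise-free model interpolates its training data", {
  inst <- random_instance(11, n = 10, D = 2)
  m <- manual_gpr(inst$Xs, inst$ys, 1.5, inst$ell, 0)
  pr <- predict(m, inst$Xs)
  expect_equal(pr$mean, inst$ys, tolerance = 1e-6)
  expect_lt(max(pr$sigma), 1e-4)
})

test_that("predictions revert to the prior far from all training points", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 5, 2)
  tm <- training_matrix(X, y)
  m <- manual_gpr(tm$X, tm$y, 1.2, c(0.8, 0.8), 0.05)
  m$training <- tm  # real standardizers: raw-unit query, de-standardized out
  far <- matrix(50, 1, 2)
  pr <- predict(m, far)
  expect_equal(pr$mean, mean(y), tolerance = 1e-6)
  expect_equal(pr$sigma, sqrt(1.2) * sd(y), tolerance = 1e-6)
})

test_that("single-training-point posterior matches the hand solution", {
  # k(x*, x1) = 0.5, sv = 1, nv = 0.25:
  # mean = 0.5*y1/1.25, var = 1 - 0.25/1.25 = 0.8
  ell <- 1
  d <- sqrt(-2 * log(0.5))      # distance giving kernel value 0.5
  m <- manual_gpr(matrix(0, 1, 1), 2, 1, ell, 0.25)
  pr <- predict(m, matrix(d, 1, 1))
  expect_equal(pr$mean, 0.5 * 2 / 1.25, tolerance = 1e-9)
  expect_equal(pr$sigma^2, 0.8, tolerance = 1e-9)
})

test_that("predictive variance never exceeds the prior and shrinks with data", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 40, n = 12, D = 2, q = 5)
    m_all <- manual_gpr(inst$Xs, inst$ys, inst$sv, inst$ell, inst$nv)
    m_less <- manual_gpr(inst$Xs[-1, , drop = FALSE], inst$ys[-1],
                         inst$sv, inst$ell, inst$nv)
    v_all <- predict(m_all, inst$Xq)$sigma^2
    v_less <- predict(m_less, inst$Xq)$sigma^2
    expect_true(all(v_all <= inst$sv + 1e-10))
    expect_true(all(v_all <= v_less + 1e-8))
  }
})

test_that("fit recovers planted ARD lengthscales and flags the noise dim", {
  set.seed(101)
  n <- 300; D <- 3
  ell_true <- c(0.5, 2.0, 50)
  X <- matrix(rnorm(n * D), n, D)
  K <- gpr_kernel(X, X, 1, ell_true)
  y <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) + rnorm(n, 0, 0.1)
  fit <- gpr_fit(training_matrix(X, y), restarts = 3, seed = 7, maxit = 150)
  ell_hat <- fit$hyperparameters$lengthscales
  # informative dims within a factor of ~1.5 of truth (standardization
  # leaves the scales comparable: sd(X) ~ 1)
  expect_lt(max(abs(log(ell_hat[1:2] / ell_true[1:2]))), log(1.6))
  # irrelevant dim: recovered lengthscale far above the data spread
  expect_gt(ell_hat[3], 5)
})

test_that("fit handles constant targets and duplicate rows", {
  X <- matrix(rnorm(30), 15, 2)
  fit <- gpr_fit(training_matrix(X, rep(3.3, 15)), restarts = 2, seed = 1)
  pr <- predict(fit, X)
  expect_equal(pr$mean, rep(3.3, 15), tolerance = 1e-3)

  Xd <- rbind(X, X[1:5, ])
  yd <- c(rnorm(15), rnorm(5))
  yd[16:20] <- yd[1:5]
  expect_s3_class(gpr_fit(training_matrix(Xd, yd), restarts = 2, seed = 2),
                  "gpr")
})

test_that("fit is reproducible for a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2); y <- sin(X[, 1]) + rnorm(30, 0, 0.1)
  f1 <- gpr_fit(training_matrix(X, y), restarts = 3, seed = 5)
  f2 <- gpr_fit(training_matrix(X, y), restarts = 3, seed = 5)
  expect_identical(f1$hyperparameters, f2$hyperparameters)
})

test_that("agreement with an independent GP implementation (kernlab)", {
  skip_if_no_kernlab()
  # isotropic case at fixed hyperparameters (no fitting on either side):
  # kernlab rbfdot uses k = exp(-s*|x-x'|^2), our kernel with sv = 1 and
  # common lengthscale ell gives s = 1/(2*ell^2)
  set.seed(21)
  n <- 30; D <- 2; ell <- 1.3; nv <- 0.1
  Xs <- matrix(rnorm(n * D), n, D); ys <- rnorm(n)
  Xq <- matrix(rnorm(16), 8, D)
  m <- manual_gpr(Xs, ys, 1, rep(ell, D), nv)
  km <- kernlab::gausspr(Xs, ys, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ell^2)),
                         var = nv, scaled = FALSE, fit = FALSE)
  expect_equal(predict(m, Xq)$mean,
               as.numeric(kernlab::predict(km, Xq)), tolerance = 1e-6)
})
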
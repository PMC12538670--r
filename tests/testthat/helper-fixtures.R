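# Shared fixtures and independent oracles for the test suite.

# A gpr object with prescribed hyperparameters and identity standardizers:
# lets tests exercise predict()/uncertainty against hand-solved systems
# without running the optimizer.
manual_gpr <- function(Xs, ys, signal_var, lengthscales, noise_var,
                       flux_variable = "GPP") {
  Xs <- as.matrix(Xs)
  D <- ncol(Xs)
  tm <- structure(list(
    X = Xs, y = ys,
    x_mean = rep(0, D), x_scale = rep(1, D), y_mean = 0, y_scale = 1,
    n = nrow(Xs), D = D, names = colnames(Xs) %||% paste0("x", 1:D),
    flux_variable = flux_variable
  ), class = "training_matrix")
  K <- gpr_kernel(Xs, Xs, signal_var, lengthscales)
  L <- t(chol(K + diag(noise_var, nrow(Xs)) + diag(1e-12, nrow(Xs))))
  alpha <- backsolve(t(L), forwardsolve(L, ys))
  structure(list(
    hyperparameters = list(signal_var = signal_var,
                           lengthscales = lengthscales,
                           noise_var = noise_var),
    training = tm, alpha = alpha, chol_L = L, jitter = 1e-12,
    log_marginal_likelihood = NA_real_
  ), class = "gpr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force GP posterior via explicit dense inverse — the independent
# oracle for the Cholesky prediction path (standardized scale).
gp_bruteforce <- function(Xs, ys, signal_var, lengthscales, noise_var, Xq) {
  k <- function(A, B) {
    out <- matrix(0, nrow(A), nrow(B))
    for (b in seq_len(ncol(A)))
      out <- out + outer(A[, b], B[, b], "-")^2 / lengthscales[b]^2
    signal_var * exp(-0.5 * out)
  }
  Kinv <- solve(k(Xs, Xs) + diag(noise_var + 1e-12, nrow(Xs)))
  Ks <- k(Xs, Xq)
  list(mean = drop(crossprod(Ks, Kinv %*% ys)),
       var = pmax(signal_var - diag(crossprod(Ks, Kinv %*% Ks)), 0))
}

# Small random GP test instance on the standardized scale.
random_instance <- function(seed, n = 12, D = 3, q = 6) {
  set.seed(seed)
  list(Xs = matrix(rnorm(n * D), n, D),
       ys = rnorm(n),
       Xq = matrix(rnorm(q * D), q, D),
       sv = exp(runif(1, -1, 1)),
       ell = exp(runif(D, -0.7, 0.9)),
       nv = exp(runif(1, -4, -1)))
}

# A flux_map filled with given arrays (defaults: one-year 8-day calendar).
make_fmap <- function(est, sig = est * 0 + 0.1, variable = "GPP",
                      year = 2021) {
  nt <- if (length(dim(est)) == 3) dim(est)[3] else 1
  flux_map(est, sig, variable = variable,
           period = as.Date(sprintf("%d-01-01", year)) + (seq_len(nt) - 1) * 8)
}

skip_if_no_kernlab <- function() {
  testthat::skip_if_not_installed("kernlab")
}
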
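# squared scaled distances: entry (i,j) = sum_b ((A[i,b]-B[j,b]) / ell[b])^2
# computed dimension-wise (not via a Gram-matrix identity) so each output
# column is bit-identical however the point set is chunked
sq_dist_scaled <- function(A, B, ell) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (b in seq_along(ell))
    d2 <- d2 + (outer(A[, b], B[, b], "-") / ell[b])^2
  d2
}

# Gram-identity variant: faster for the repeated self-kernels of training,
# where chunk determinism is irrelevant (the point set never splits)
sq_dist_scaled_fast <- function(A, B, ell) {
  As <- sweep(A, 2, ell, "/")
  Bs <- sweep(B, 2, ell, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  d2[d2 < 0] <- 0
  d2
}

#' ARD squared-exponential kernel matrix
#'
#' Evaluates the anisotropic (automatic relevance determination) radial
#' basis function kernel
#' \deqn{k(x_i, x_j) = \sigma_s^2 \exp\left(-\tfrac12 \sum_{b=1}^{D}
#'   \left[\frac{x_i(b) - x_j(b)}{\sigma_b}\right]^2\right)}
#' between two point sets. Each dimension b has its own lengthscale
#' \eqn{\sigma_b}; a large lengthscale makes the kernel insensitive to that
#' coordinate, which is what encodes predictor (ir)relevance.
#'
#' @param A m x D matrix of (standardized) points.
#' @param B p x D matrix of (standardized) points.
#' @param signal_var Output variance \eqn{\sigma_s^2 > 0}.
#' @param lengthscales Length-D vector of positive per-dimension
#'   lengthscales.
#' @return m x p kernel matrix.
#' @export
gpr_kernel <- function(A, B, signal_var, lengthscales) {
  A <- as.matrix(A); B <- as.matrix(B)
  D <- length(lengthscales)
  if (ncol(A) != D || ncol(B) != D)
    stop(sprintf("dimension mismatch: points have D = %d / %d, lengthscales D = %d",
                 ncol(A), ncol(B), D), call. = FALSE)
  if (signal_var <= 0 || any(lengthscales <= 0))
    stop("signal_var and all lengthscales must be positive", call. = FALSE)
  signal_var * exp(-0.5 * sq_dist_scaled(A, B, lengthscales))
}

# Cholesky of K + noise_var*I with escalating diagonal jitter.
# Returns list(L lower-triangular, jitter actually added).
chol_with_jitter <- function(K, noise_var, jitter0 = 1e-10, jitter_max = 1e-4) {
  n <- nrow(K)
  base_jit <- jitter0 * sum(diag(K)) / n
  max_jit <- jitter_max * sum(diag(K)) / n
  jit <- 0
  repeat {
    R <- tryCatch(chol(K + diag(noise_var + jit, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(L = t(R), jitter = jit))
    jit <- if (jit == 0) base_jit else jit * 10
    if (jit > max_jit)
      stop(sprintf(
        "Cholesky failed even with jitter %.3e (trace/n = %.3e): matrix too ill-conditioned",
        jit / 10, sum(diag(K)) / n), call. = FALSE)
  }
}

#' Log marginal likelihood of a GP and its gradient
#'
#' Computes
#' \deqn{\log p(y \mid X, \theta) = -\tfrac12 y^\top (K + \sigma_n^2 I)^{-1} y
#'   - \tfrac12 \log\det(K + \sigma_n^2 I) - \tfrac{n}{2}\log 2\pi}
#' via a Cholesky factorization (no explicit inverse or determinant), along
#' with its analytic gradient with respect to the log-hyperparameters
#' \eqn{(\log \sigma_s^2, \log \sigma_1, \dots, \log \sigma_D, \log \sigma_n^2)}.
#'
#' @param theta_log Numeric vector of length D + 2: log signal variance,
#'   log lengthscales, log noise variance.
#' @param X n x D matrix of standardized inputs.
#' @param y Length-n standardized target vector.
#' @return List with `value` (scalar log marginal likelihood) and `grad`
#'   (length D + 2 gradient w.r.t. `theta_log`).
#' @export
gpr_lml <- function(theta_log, X, y) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  stopifnot(length(theta_log) == D + 2L, length(y) == n)
  signal_var <- exp(theta_log[1L])
  ell <- exp(theta_log[2:(D + 1L)])
  noise_var <- exp(theta_log[D + 2L])

  K <- signal_var * exp(-0.5 * sq_dist_scaled_fast(X, X, ell))
  cf <- chol_with_jitter(K, noise_var)
  L <- cf$L
  alpha <- backsolve(t(L), forwardsolve(L, y))
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)

  # grad_t = 0.5 * tr((alpha alpha' - Kinv) dK/dt); W = alpha alpha' - Kinv
  Kinv <- chol2inv(t(L))
  W <- tcrossprod(alpha) - Kinv
  grad <- numeric(D + 2L)
  grad[1L] <- 0.5 * sum(W * K)                       # dK/dlog(sigma_s^2) = K
  for (b in seq_len(D)) {
    Mb <- outer(X[, b], X[, b], "-")^2 / ell[b]^2    # dK/dlog(ell_b) = K * Mb
    grad[1L + b] <- 0.5 * sum(W * (K * Mb))
  }
  grad[D + 2L] <- 0.5 * noise_var * sum(diag(W))     # dK/dlog(sigma_n^2)
  list(value = value, grad = grad)
}

#' Assemble a training matrix with standardization
#'
#' Centres and scales each predictor column and the target; the GP is a
#' zero-mean process on the standardized target, and predictions are
#' de-standardized back to physical units.
#'
#' @param X n x D numeric matrix or data.frame of raw predictor values.
#' @param y Length-n numeric target (flux, umol m-2 s-1).
#' @param flux_variable Tag, one of [flux_variables()] (or any label).
#' @return A `training_matrix` list: standardized `X`, `y`, the
#'   standardizers, dimensions, and the tag.
#' @export
training_matrix <- function(X, y, flux_variable = "GPP") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("training data contain non-finite values", call. = FALSE)
  x_mean <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1       # constant column: centre only
  y_mean <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1   # constant target: degenerate but allowed
  Xs <- sweep(sweep(X, 2, x_mean, "-"), 2, x_scale, "/")
  structure(list(
    X = Xs, y = (y - y_mean) / y_scale,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean, y_scale = y_scale,
    n = nrow(X), D = ncol(X),
    names = colnames(X), flux_variable = flux_variable
  ), class = "training_matrix")
}

#' Fit a GP regression model by marginal-likelihood maximization
#'
#' Maximizes the log marginal likelihood over
#' \eqn{\theta = \{\sigma_s^2, \sigma_1, \dots, \sigma_D, \sigma_n^2\}}
#' with a quasi-Newton optimizer (L-BFGS-B) in log-hyperparameter space,
#' using the analytic gradient. The first start is a fixed heuristic
#' (unit lengthscales and signal variance, noise variance 0.1 on the
#' standardized scale); the remaining restarts are drawn log-uniform within
#' the box bounds. The restart with the highest log marginal likelihood
#' wins; ties go to the lowest restart index.
#'
#' @param training A `training_matrix` (see [training_matrix()]), or a raw
#'   matrix together with `y`.
#' @param y Target vector when `training` is a raw matrix.
#' @param restarts Number of optimizer starts (default 5).
#' @param bounds Length-2 positive vector: box bounds for lengthscales and
#'   signal variance on the standardized scale (default `c(1e-2, 1e2)`).
#' @param noise_bounds Box bounds for the noise variance
#'   (default `c(1e-6, 1e1)`).
#' @param maxit Maximum L-BFGS-B iterations per restart.
#' @param seed Integer seed controlling the random restarts.
#' @param flux_variable Tag stored with the model.
#' @return A fitted model of class `gpr`: hyperparameters, standardizers,
#'   retained standardized training inputs, cached weight vector alpha and
#'   lower Cholesky factor, and the attained log marginal likelihood.
#' @export
gpr_fit <- function(training, y = NULL, restarts = 5L,
                    bounds = c(1e-2, 1e2), noise_bounds = c(1e-6, 1e1),
                    maxit = 200L, seed = 1L, flux_variable = NULL) {
  if (!inherits(training, "training_matrix"))
    training <- training_matrix(training, y,
                                flux_variable = flux_variable %||% "flux")
  tm <- training
  D <- tm$D
  lo <- c(log(bounds[1]), rep(log(bounds[1]), D), log(noise_bounds[1]))
  hi <- c(log(bounds[2]), rep(log(bounds[2]), D), log(noise_bounds[2]))

  # L-BFGS-B asks for the value and gradient at the same point separately;
  # compute both once and cache
  cache <- new.env(parent = emptyenv())
  lml_at <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- gpr_lml(p, tm$X, tm$y)
      cache$key <- key
    }
    cache$res
  }
  obj <- function(p) -lml_at(p)$value
  gr  <- function(p) -lml_at(p)$grad

  starts <- vector("list", restarts)
  starts[[1L]] <- pmin(pmax(c(0, rep(0, D), log(0.1)), lo), hi)
  if (restarts > 1L) {
    rs <- local({
      set.seed(seed)
      lapply(seq_len(restarts - 1L), function(i)
        stats::runif(D + 2L, pmax(lo, log(1e-2)), pmin(hi, log(1e2))))
    })
    starts[2:restarts] <- rs
  }

  best <- NULL; best_val <- -Inf; diagnostics <- character(restarts)
  for (i in seq_len(restarts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], obj, gr, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = maxit, factr = 1e7)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics[i] <- sprintf("restart %d failed: %s", i, conditionMessage(res))
      next
    }
    diagnostics[i] <- sprintf("restart %d: lml = %.6f (conv %d)",
                              i, -res$value, res$convergence)
    if (-res$value > best_val) { best_val <- -res$value; best <- res }
  }
  if (is.null(best))
    stop(paste(c("all optimizer restarts failed:", diagnostics), collapse = "\n"),
         call. = FALSE)

  p <- best$par
  hyp <- list(signal_var = exp(p[1L]),
              lengthscales = stats::setNames(exp(p[2:(D + 1L)]),
                                             tm$names %||% paste0("x", 1:D)),
              noise_var = exp(p[D + 2L]))
  K <- gpr_kernel(tm$X, tm$X, hyp$signal_var, hyp$lengthscales)
  cf <- chol_with_jitter(K, hyp$noise_var)
  alpha <- backsolve(t(cf$L), forwardsolve(cf$L, tm$y))
  structure(list(
    hyperparameters = hyp, training = tm,
    alpha = alpha, chol_L = cf$L, jitter = cf$jitter,
    log_marginal_likelihood = best_val,
    restart_diagnostics = diagnostics
  ), class = "gpr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict flux mean and epistemic uncertainty at new points
#'
#' Posterior predictive mean \eqn{k(X_*, X)\,\alpha} and latent-function
#' standard deviation \eqn{\sigma_f(x_*) = \sqrt{k(x_*,x_*) - v^\top v}}
#' with \eqn{v = L \backslash k_*}, where L is the lower Cholesky factor of
#' \eqn{K + \sigma_n^2 I}. The reported sigma is the epistemic (model)
#' uncertainty of the latent function; set `include_noise = TRUE` to add
#' the observation-noise variance for predictive-observation intervals.
#' Inputs are given in raw physical units and standardized internally;
#' outputs are de-standardized to flux units.
#'
#' @param object Fitted `gpr` model.
#' @param newdata q x D matrix of raw-unit predictor values.
#' @param include_noise Add \eqn{\sigma_n^2} to the predictive variance?
#' @param ... Unused.
#' @return List with numeric vectors `mean` and `sigma` (length q).
#' @export
predict.gpr <- function(object, newdata, include_noise = FALSE, ...) {
  tm <- object$training
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != tm$D)
    stop(sprintf("newdata has D = %d, model expects D = %d", ncol(Xn), tm$D),
         call. = FALSE)
  if (!all(is.finite(Xn))) stop("newdata contains non-finite values", call. = FALSE)
  Xs <- sweep(sweep(Xn, 2, tm$x_mean, "-"), 2, tm$x_scale, "/")
  hyp <- object$hyperparameters
  Ks <- gpr_kernel(tm$X, Xs, hyp$signal_var, hyp$lengthscales)  # n x q
  mean_s <- colSums(Ks * object$alpha)  # column-wise: chunk-invariant
  v <- forwardsolve(object$chol_L, Ks)
  var_s <- hyp$signal_var - colSums(v^2)
  if (include_noise) var_s <- var_s + hyp$noise_var
  var_s[var_s < 0] <- 0
  list(mean = unname(mean_s * tm$y_scale + tm$y_mean),
       sigma = unname(sqrt(var_s) * tm$y_scale))
}

#' @export
print.gpr <- function(x, ...) {
  hyp <- x$hyperparameters
  cat(sprintf("GP regression model (%s): n = %d, D = %d\n",
              x$training$flux_variable, x$training$n, x$training$D))
  cat(sprintf("  log marginal likelihood: %.3f\n", x$log_marginal_likelihood))
  cat(sprintf("  signal sd: %.3f   noise sd: %.3f (standardized)\n",
              sqrt(hyp$signal_var), sqrt(hyp$noise_var)))
  cat("  lengthscales:\n")
  print(round(hyp$lengthscales, 3))
  invisible(x)
}

#' Portable prediction from an exported model record
#'
#' Reproduces [predict.gpr()] using only the plain serialized arrays of an
#' exported model (schema, hyperparameters, standardizers, training inputs
#' and weight vector): kernel evaluation, dot products and a triangular
#' solve — no model fitting code. This is the contract that lets an
#' exported model run on any platform that can do arithmetic.
#'
#' @param record A model record as produced by [export_model()] /
#'   [import_model()] (a plain list, not a `gpr` object).
#' @param newdata q x D matrix of raw-unit predictor values.
#' @param include_noise Add the noise variance to the predictive variance?
#' @return List with `mean` and `sigma`, identical to [predict.gpr()] on
#'   the originating model to ~1e-10 relative.
#' @export
standalone_predict <- function(record, newdata, include_noise = FALSE) {
  required <- c("version", "theta", "x_mean", "x_scale", "y_mean", "y_scale",
                "X_train", "alpha")
  missing_f <- setdiff(required, names(record))
  if (length(missing_f))
    stop("model record is missing fields: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  sv <- record$theta$signal_var
  ell <- as.numeric(record$theta$lengthscales)
  nv <- record$theta$noise_var
  Xt <- as.matrix(record$X_train)
  a <- as.numeric(record$alpha)
  D <- length(ell); n <- nrow(Xt)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != D)
    stop(sprintf("newdata has D = %d, record expects D = %d", ncol(Xn), D),
         call. = FALSE)
  Xs <- sweep(sweep(Xn, 2, as.numeric(record$x_mean), "-"),
              2, as.numeric(record$x_scale), "/")
  # kernel blocks by direct arithmetic
  kfun <- function(A, B) {
    out <- matrix(0, nrow(A), nrow(B))
    for (b in seq_len(D)) out <- out + outer(A[, b], B[, b], "-")^2 / ell[b]^2
    sv * exp(-0.5 * out)
  }
  Ks <- kfun(Xt, Xs)
  jit <- record$jitter %||% 0
  L <- t(chol(kfun(Xt, Xt) + diag(nv + jit, n)))
  v <- forwardsolve(L, Ks)
  var_s <- sv - colSums(v^2)
  if (include_noise) var_s <- var_s + nv
  var_s[var_s < 0] <- 0
  list(mean = unname(colSums(Ks * a)) * record$y_scale + record$y_mean,
       sigma = sqrt(var_s) * record$y_scale)
}
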
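MODEL_FORMAT_VERSION <- "fluxgpr-model-1"

#' Export a fitted GP model to a portable JSON file
#'
#' Writes everything needed to reproduce predictions without any fitting
#' code: format version, predictor names, hyperparameters, standardization
#' constants, the standardized training inputs and the precomputed weight
#' vector alpha. Numbers are written at full double precision so that
#' import/export round-trips predict identically to ~1e-10 relative.
#'
#' @param model Fitted `gpr` model.
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @seealso [import_model()], [standalone_predict()]
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "gpr"))
  tm <- model$training
  hyp <- model$hyperparameters
  rec <- list(
    version = MODEL_FORMAT_VERSION,
    flux_variable = tm$flux_variable,
    schema = tm$names %||% paste0("x", seq_len(tm$D)),
    theta = list(signal_var = hyp$signal_var,
                 lengthscales = unname(hyp$lengthscales),
                 noise_var = hyp$noise_var),
    x_mean = unname(tm$x_mean), x_scale = unname(tm$x_scale),
    y_mean = tm$y_mean, y_scale = tm$y_scale,
    jitter = model$jitter,
    log_marginal_likelihood = model$log_marginal_likelihood,
    X_train = unname(tm$X), alpha = unname(model$alpha)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a GP model record from a JSON export
#'
#' Reads a file written by [export_model()] and returns the plain record
#' for [standalone_predict()], or (with `as_gpr = TRUE`) a `gpr` object
#' whose [predict.gpr()] reproduces the original model.
#'
#' @param path JSON file written by [export_model()].
#' @param as_gpr Rebuild a `gpr` object (recomputes the Cholesky factor
#'   from the serialized arrays)?
#' @return A model record list, or a `gpr` object.
#' @export
import_model <- function(path, as_gpr = FALSE) {
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(rec$version) || !identical(rec$version, MODEL_FORMAT_VERSION))
    stop(sprintf("model file version '%s' does not match expected '%s'",
                 rec$version %||% "<missing>", MODEL_FORMAT_VERSION),
         call. = FALSE)
  required <- c("theta", "x_mean", "x_scale", "y_mean", "y_scale",
                "X_train", "alpha")
  miss <- setdiff(required, names(rec))
  if (length(miss))
    stop("model file is truncated or invalid; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rec$X_train <- as.matrix(rec$X_train)
  if (!as_gpr) return(rec)

  D <- length(rec$theta$lengthscales)
  hyp <- list(signal_var = rec$theta$signal_var,
              lengthscales = stats::setNames(as.numeric(rec$theta$lengthscales),
                                             rec$schema),
              noise_var = rec$theta$noise_var)
  Xs <- rec$X_train
  colnames(Xs) <- rec$schema
  tm <- structure(list(
    X = Xs, y = NULL,
    x_mean = stats::setNames(as.numeric(rec$x_mean), rec$schema),
    x_scale = stats::setNames(as.numeric(rec$x_scale), rec$schema),
    y_mean = rec$y_mean, y_scale = rec$y_scale,
    n = nrow(Xs), D = D, names = rec$schema,
    flux_variable = rec$flux_variable %||% "flux"
  ), class = "training_matrix")
  K <- gpr_kernel(Xs, Xs, hyp$signal_var, hyp$lengthscales)
  L <- t(chol(K + diag(hyp$noise_var + (rec$jitter %||% 0), nrow(Xs))))
  structure(list(
    hyperparameters = hyp, training = tm,
    alpha = as.numeric(rec$alpha), chol_L = L, jitter = rec$jitter %||% 0,
    log_marginal_likelihood = rec$log_marginal_likelihood %||% NA_real_
  ), class = "gpr")
}
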
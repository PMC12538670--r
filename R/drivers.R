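#' ARD predictor-relevance scores from a fitted model
#'
#' The ARD kernel assigns each predictor its own lengthscale; the larger
#' the lengthscale, the less the predictor informs the fit. Relevance is
#' the inverse lengthscale (computed on standardized inputs so units
#' cancel), normalized so the most relevant predictor scores 1 — the
#' scaled coefficients shown on a polar plot of predictor importance.
#'
#' @param model Fitted `gpr` model.
#' @param scaling `"inverse"` (default: `1/sigma_b`, normalized to max 1)
#'   or `"log_inverse"` (`1/(1 + log(sigma_b/min sigma))`, compressing the
#'   dynamic range).
#' @return Data.frame of class `relevance_scores`: `predictor`,
#'   `lengthscale`, `score` in (0, 1], sorted by decreasing score; the
#'   flux tag and scaling method as attributes.
#' @export
ard_relevance <- function(model, scaling = c("inverse", "log_inverse")) {
  scaling <- match.arg(scaling)
  ell <- model$hyperparameters$lengthscales
  r <- switch(scaling,
              inverse = 1 / ell,
              log_inverse = 1 / (1 + log(ell / min(ell))))
  score <- r / max(r)
  out <- data.frame(predictor = names(ell) %||% paste0("x", seq_along(ell)),
                    lengthscale = unname(ell), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$lengthscale), ]
  rownames(out) <- NULL
  attr(out, "flux_variable") <- model$training$flux_variable
  attr(out, "scaling") <- scaling
  class(out) <- c("relevance_scores", "data.frame")
  out
}

#' Pearson correlation with pairwise deletion
#'
#' @param x,y Equal-length numeric vectors; pairs with missing values are
#'   dropped. At least 3 complete pairs required.
#' @return Sample Pearson coefficient, or `NA` with attribute `reason`
#'   when either input is constant.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y)
}

#' Spearman rank correlation with pairwise deletion
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#' @inheritParams pearson
#' @return Spearman coefficient, or `NA` with a reason for constant input.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y, method = "spearman")
}

#' Spatial-mean time series over a region
#'
#' Mean of unmasked pixels per time step and band, over a rectangular
#' region given either in map coordinates or as pixel index ranges.
#'
#' @param scene A `grid_scene` (or `flux_map`, whose estimate and sigma
#'   become the series).
#' @param region List with `xmin`, `xmax`, `ymin`, `ymax` (map
#'   coordinates, pixel centres inside are selected) or `rows`, `cols`
#'   (index vectors).
#' @return Data.frame: `time` plus one column per band.
#' @export
regional_series <- function(scene, region) {
  if (inherits(scene, "flux_map"))
    scene <- grid_scene(stats::setNames(list(scene$estimate, scene$sigma),
                                        c(scene$variable, "sigma")),
                        geotransform = scene$geotransform, crs = scene$crs,
                        time = if (length(scene$period) == scene$ntime)
                          scene$period else seq_len(scene$ntime))
  if (!is.null(region$rows)) {
    rows <- region$rows; cols <- region$cols
  } else {
    cc <- scene_coords(scene)
    rows <- which(cc$y >= region$ymin & cc$y <= region$ymax)
    cols <- which(cc$x >= region$xmin & cc$x <= region$xmax)
  }
  if (!length(rows) || !length(cols))
    stop("region does not intersect the grid", call. = FALSE)
  out <- data.frame(time = scene$time)
  for (bn in names(scene$bands)) {
    a <- scene$bands[[bn]][rows, cols, , drop = FALSE]
    out[[bn]] <- apply(a, 3, function(m) {
      v <- m[is.finite(m)]
      if (!length(v)) NA_real_ else mean(v)
    })
  }
  out
}

#' Region-by-predictor temporal correlation table
#'
#' For each named region, correlates the regional-mean flux series with
#' each regional-mean predictor series over the shared 8-day time axis:
#' the cells of the driver heat map.
#'
#' @param regions Named list of regions (see [regional_series()]); names
#'   may carry a biome label.
#' @param flux_scene `flux_map` (or single-band `grid_scene`) of the flux.
#' @param predictor_scene `grid_scene` of predictor bands on the same
#'   time axis.
#' @return Long data.frame of class `correlation_table`: `region`,
#'   `predictor`, `pearson`, `spearman`, `n`.
#' @export
correlation_heatmap <- function(regions, flux_scene, predictor_scene) {
  res <- list()
  for (rn in names(regions)) {
    fs <- regional_series(flux_scene, regions[[rn]])
    ps <- regional_series(predictor_scene, regions[[rn]])
    if (nrow(fs) != nrow(ps) || !isTRUE(all(fs$time == ps$time)))
      stop("flux and predictor scenes have misaligned time axes",
           call. = FALSE)
    fv <- fs[[2L]]  # first band = the flux
    for (pn in setdiff(names(ps), "time")) {
      ok <- is.finite(fv) & is.finite(ps[[pn]])
      res[[length(res) + 1L]] <- data.frame(
        region = rn, predictor = pn,
        pearson = if (sum(ok) >= 3) as.numeric(pearson(fv, ps[[pn]]))
                  else NA_real_,
        spearman = if (sum(ok) >= 3) as.numeric(spearman(fv, ps[[pn]]))
                   else NA_real_,
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("correlation_table", "data.frame")
  out
}
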
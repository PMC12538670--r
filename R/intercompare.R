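fm_pix_time <- function(fmap) matrix(fmap$estimate, ncol = fmap$ntime)

#' Validate gridded flux estimates against tower observations
#'
#' Extracts the pixel containing each tower (nearest pixel centre; or the
#' mean of the surrounding 3x3 window) from a flux-map time series,
#' matches the tower's observed series on the composite index, and
#' computes per-tower metrics plus per-vegetation-class summaries
#' (median and quartiles of R2 and rmse — the boxplot statistics).
#'
#' @param fmap `flux_map` time series.
#' @param towers List of tower descriptors: each a list with `site_id`,
#'   `x`, `y` (map coordinates), `vegetation_class`, and `series` (a
#'   data.frame with `time` matching `fmap$period` and `value`,
#'   umol m-2 s-1).
#' @param window 1 (single containing pixel, default) or 3 (3x3 mean).
#' @return List: `per_tower` data.frame (site, class, r2, rmse, n) and
#'   `by_class` data.frame (class, n_towers, medians and quartiles).
#' @export
tower_validation <- function(fmap, towers, window = 1L) {
  cc <- scene_coords(fmap)
  rows <- list(); skipped <- character()
  for (tw in towers) {
    j <- which.min(abs(cc$x - tw$x)); i <- which.min(abs(cc$y - tw$y))
    gt <- fmap$geotransform
    if (abs(cc$x[j] - tw$x) > gt[2] / 2 + 1e-9 ||
        abs(cc$y[i] - tw$y) > gt[4] / 2 + 1e-9) {
      warning("tower ", tw$site_id, " falls outside the grid; skipped")
      skipped <- c(skipped, tw$site_id)
      next
    }
    if (window == 3L) {
      ri <- max(1, i - 1):min(fmap$nrow, i + 1)
      ci <- max(1, j - 1):min(fmap$ncol, j + 1)
      px <- apply(fmap$estimate[ri, ci, , drop = FALSE], 3,
                  function(m) mean(m[is.finite(m)]))
    } else {
      px <- fmap$estimate[i, j, ]
    }
    m <- match(tw$series$time, fmap$period)
    ok <- !is.na(m)
    met <- compute_metrics(tw$series$value[ok], px[m[ok]])
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = tw$site_id, vegetation_class = tw$vegetation_class,
      r2 = met$r2, rmse = met$rmse, n = met$n, stringsAsFactors = FALSE)
  }
  per_tower <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), vegetation_class = character(),
               r2 = numeric(), rmse = numeric(), n = integer())
  by_class <- do.call(rbind, lapply(split(per_tower,
                                          per_tower$vegetation_class),
    function(d) data.frame(
      vegetation_class = d$vegetation_class[1], n_towers = nrow(d),
      r2_median = stats::median(d$r2), r2_q1 = stats::quantile(d$r2, .25),
      r2_q3 = stats::quantile(d$r2, .75),
      rmse_median = stats::median(d$rmse),
      rmse_q1 = stats::quantile(d$rmse, .25),
      rmse_q3 = stats::quantile(d$rmse, .75))))
  rownames(by_class) <- NULL
  list(per_tower = per_tower, by_class = by_class, skipped = skipped)
}

#' Per-pixel intercomparison of two gridded flux products
#'
#' Computes, at every pixel of the common (coarser) grid, the temporal
#' Pearson correlation and rmse between two flux-map series over their
#' common periods, plus global median summaries. When resolutions differ
#' by an integer factor the finer product is aggregated to the coarser
#' grid by area-weighted (block) mean first.
#'
#' @param a,b `flux_map` time series with overlapping `period`s.
#' @param min_common Minimum common valid composites per pixel
#'   (default 3); pixels below it are masked.
#' @return List: `r_map`, `rmse_map` (matrices on the common grid),
#'   `summary` (median R, median rmse, n pixels compared), `period`
#'   (common periods), `geotransform`.
#' @export
gridded_intercompare <- function(a, b, min_common = 3L) {
  to_scene <- function(f) grid_scene(list(v = f$estimate),
                                     geotransform = f$geotransform,
                                     crs = f$crs,
                                     time = if (length(f$period) == f$ntime)
                                       f$period else seq_len(f$ntime))
  sa <- to_scene(a); sb <- to_scene(b)
  if (sa$nrow != sb$nrow || sa$ncol != sb$ncol) {
    fine <- if (sa$nrow > sb$nrow) sa else sb
    coarse <- if (sa$nrow > sb$nrow) sb else sa
    fct <- fine$nrow / coarse$nrow
    if (fct != round(fct) || fine$ncol / coarse$ncol != fct)
      stop("grids differ by a non-integer factor; cannot regrid",
           call. = FALSE)
    fine <- block_aggregate(fine, as.integer(fct))
    if (sa$nrow > sb$nrow) sa <- fine else sb <- fine
  }
  common <- intersect(as.character(sa$time), as.character(sb$time))
  if (length(common) < min_common)
    stop("fewer than ", min_common, " common periods", call. = FALSE)
  ia <- match(common, as.character(sa$time))
  ib <- match(common, as.character(sb$time))
  A <- matrix(sa$bands$v[, , ia], ncol = length(common))
  B <- matrix(sb$bands$v[, , ib], ncol = length(common))
  ok <- is.finite(A) & is.finite(B)
  A[!ok] <- NA; B[!ok] <- NA
  ncom <- rowSums(ok)

  rmse_px <- sqrt(rowMeans((A - B)^2, na.rm = TRUE))
  r_px <- vapply(seq_len(nrow(A)), function(i) {
    if (ncom[i] < min_common) return(NA_real_)
    x <- A[i, ]; y <- B[i, ]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(x, y, use = "complete.obs")
  }, 0)
  rmse_px[ncom < min_common] <- NA_real_

  nr <- sa$nrow; nc <- sa$ncol
  list(r_map = matrix(r_px, nr, nc), rmse_map = matrix(rmse_px, nr, nc),
       summary = list(median_r = stats::median(r_px, na.rm = TRUE),
                      median_rmse = stats::median(rmse_px, na.rm = TRUE),
                      n_pixels = sum(is.finite(rmse_px))),
       period = common, geotransform = sa$geotransform)
}

#' Consistency of directly-modelled NEE with GPP - RECO
#'
#' Compares net ecosystem exchange predicted by a dedicated NEE model
#' against the difference of the GPP and RECO model outputs, per pixel
#' over a common period: mean difference and rmse maps plus summary
#' quantiles. All three series must share the grid, period and NEE sign
#' convention.
#'
#' @param gpp,reco,nee `flux_map` series on one grid and period.
#' @param nee_sign Expected sign convention tag; `nee$nee_sign` must
#'   match (no silent flip).
#' @return List: `mean_diff_map`, `rmse_map`, `summary` (quantiles of the
#'   per-pixel mean difference, overall median absolute difference).
#' @export
nee_consistency <- function(gpp, reco, nee, nee_sign = "uptake_positive") {
  if (!identical(nee$nee_sign, nee_sign))
    stop(sprintf("NEE sign convention mismatch: map says '%s', expected '%s'",
                 nee$nee_sign, nee_sign), call. = FALSE)
  dims_ok <- gpp$nrow == reco$nrow && gpp$nrow == nee$nrow &&
    gpp$ncol == reco$ncol && gpp$ncol == nee$ncol &&
    gpp$ntime == reco$ntime && gpp$ntime == nee$ntime
  if (!dims_ok) stop("the three series must share grid and period",
                     call. = FALSE)
  diff <- (gpp$estimate - reco$estimate) - nee$estimate
  d2 <- matrix(diff, ncol = gpp$ntime)
  mean_diff <- rowMeans(d2, na.rm = TRUE)
  rmse_px <- sqrt(rowMeans(d2^2, na.rm = TRUE))
  list(
    mean_diff_map = matrix(mean_diff, gpp$nrow, gpp$ncol),
    rmse_map = matrix(rmse_px, gpp$nrow, gpp$ncol),
    summary = list(
      quantiles = stats::quantile(mean_diff, c(.05, .25, .5, .75, .95),
                                  na.rm = TRUE),
      median_abs_diff = stats::median(abs(mean_diff), na.rm = TRUE),
      median_rmse = stats::median(rmse_px, na.rm = TRUE)))
}
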
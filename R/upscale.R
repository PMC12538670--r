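SECONDS_PER_DAY <- 86400
CARBON_G_PER_UMOL <- 12.011e-6  # molar mass of C, g per umol

#' Convert between flux unit conventions
#'
#' Supported units: `"umol m-2 s-1"` (instantaneous CO2 flux),
#' `"gC m-2 d-1"` and `"gC m-2 y-1"` (carbon mass per area per time).
#' Conversion uses the molar mass of carbon (12.011 g mol-1); yearly
#' totals use `days` days per year.
#'
#' @param value Numeric vector.
#' @param from,to Unit strings from the supported set.
#' @param days Days per year for `y-1` conversions (365 or 366).
#' @return Converted numeric vector.
#' @export
convert_flux_units <- function(value, from, to, days = 365) {
  per_day <- CARBON_G_PER_UMOL * SECONDS_PER_DAY
  # factor to gC m-2 d-1
  fac <- c("umol m-2 s-1" = per_day, "gC m-2 d-1" = 1,
           "gC m-2 y-1" = 1 / days)
  if (!from %in% names(fac) || !to %in% names(fac))
    stop("unsupported unit pair: ", from, " -> ", to, call. = FALSE)
  value * fac[[from]] / fac[[to]]
}

# composite index (1-based) for a day-of-year under the 8-day calendar
composite_index <- function(doy) pmin((doy - 1L) %/% 8L, 45L) + 1L

#' Aggregate a daily scene into 8-day composites
#'
#' Per pixel and band, the mean over each 8-day window starting on day 1
#' of the year; the 46th window covers the final 5 days (6 in leap
#' years). Pixels with fewer than `min_valid_days` valid days in a window
#' are masked.
#'
#' @param scene Daily `grid_scene` whose `time` is a `Date` vector.
#' @param min_valid_days Minimum valid days per window (default 4; capped
#'   at the window length).
#' @return A `grid_scene` of composites; `time` holds window start dates.
#' @export
composite_8day <- function(scene, min_valid_days = 4L) {
  if (!inherits(scene$time, "Date"))
    stop("composite_8day needs a Date time index", call. = FALSE)
  doy <- as.integer(strftime(scene$time, "%j"))
  year <- as.integer(strftime(scene$time, "%Y"))
  ci <- composite_index(doy)
  grp <- paste(year, ci)
  ugrp <- unique(grp)
  nt <- length(ugrp)
  starts <- as.Date(unname(vapply(ugrp, function(g) {
    i <- which(grp == g)[1L]
    format(as.Date(sprintf("%d-01-01", year[i])) + (ci[i] - 1L) * 8L)
  }, "")))
  out <- lapply(scene$bands, function(a) {
    comp <- array(NA_real_, dim = c(scene$nrow, scene$ncol, nt))
    for (g in seq_len(nt)) {
      sl <- a[, , grp == ugrp[g], drop = FALSE]
      nvalid <- apply(is.finite(sl), c(1, 2), sum)
      m <- apply(sl, c(1, 2), function(v) mean(v, na.rm = TRUE))
      need <- min(min_valid_days, dim(sl)[3L])
      m[nvalid < need] <- NA_real_
      comp[, , g] <- m
    }
    comp
  })
  grid_scene(out, geotransform = scene$geotransform, crs = scene$crs,
             time = starts)
}

#' Resample a scene to a target grid
#'
#' Bilinear interpolation (pixel-centre convention, mask-aware: invalid
#' neighbours are excluded and weights renormalized, so nodata is never
#' interpolated across) for continuous fields, or nearest-neighbour for
#' categorical ones.
#'
#' @param src Source `grid_scene`.
#' @param geotransform Target geotransform `c(x0, dx, y0, dy)`
#'   (pixel-centre origin).
#' @param nrow,ncol Target dimensions.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A `grid_scene` on the target grid.
#' @export
resample_to_grid <- function(src, geotransform, nrow, ncol,
                             method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  gt_s <- src$geotransform; gt_t <- as.numeric(geotransform)
  xt <- gt_t[1] + (seq_len(ncol) - 1) * gt_t[2]
  yt <- gt_t[3] - (seq_len(nrow) - 1) * gt_t[4]
  # fractional source pixel indices of the target centres
  cj <- (xt - gt_s[1]) / gt_s[2] + 1
  ri <- (gt_s[3] - yt) / gt_s[4] + 1
  if (max(cj) < 0.5 || min(cj) > src$ncol + 0.5 ||
      max(ri) < 0.5 || min(ri) > src$nrow + 0.5)
    stop("source and target grids do not overlap", call. = FALSE)

  RI <- matrix(rep(ri, times = ncol), nrow, ncol)
  CJ <- matrix(rep(cj, each = nrow), nrow, ncol)
  out <- lapply(src$bands, function(a) {
    res <- array(NA_real_, dim = c(nrow, ncol, src$ntime))
    for (t in seq_len(src$ntime)) {
      sl <- a[, , t]
      if (method == "nearest") {
        r0 <- pmin(pmax(round(RI), 1), src$nrow)
        c0 <- pmin(pmax(round(CJ), 1), src$ncol)
        res[, , t] <- matrix(sl[cbind(as.vector(r0), as.vector(c0))],
                             nrow, ncol)
      } else {
        r0 <- floor(RI); c0 <- floor(CJ)
        fr <- RI - r0; fc <- CJ - c0
        # clamp to the grid edge (constant extrapolation at borders)
        r0c <- pmin(pmax(r0, 1), src$nrow); r1c <- pmin(pmax(r0 + 1, 1), src$nrow)
        c0c <- pmin(pmax(c0, 1), src$ncol); c1c <- pmin(pmax(c0 + 1, 1), src$ncol)
        g <- function(rr, cc) sl[cbind(as.vector(rr), as.vector(cc))]
        v00 <- g(r0c, c0c); v10 <- g(r1c, c0c)
        v01 <- g(r0c, c1c); v11 <- g(r1c, c1c)
        w00 <- as.vector((1 - fr) * (1 - fc)); w10 <- as.vector(fr * (1 - fc))
        w01 <- as.vector((1 - fr) * fc);       w11 <- as.vector(fr * fc)
        vals <- cbind(v00, v10, v01, v11)
        wts <- cbind(w00, w10, w01, w11)
        wts[!is.finite(vals)] <- 0
        vals[!is.finite(vals)] <- 0
        wsum <- rowSums(wts)
        est <- ifelse(wsum > 0, rowSums(vals * wts) / wsum, NA_real_)
        res[, , t] <- matrix(est, nrow, ncol)
      }
    }
    res
  })
  grid_scene(out, geotransform = gt_t, crs = src$crs, time = src$time)
}

#' Aggregate a scene to a coarser grid by block mean
#'
#' Area-weighted (equal-area pixels: plain block mean of valid cells) for
#' fine-to-coarse regridding by an integer factor.
#'
#' @param scene A `grid_scene`.
#' @param factor Integer block size; must divide both dimensions.
#' @param min_frac Minimum fraction of valid fine pixels per block
#'   (default 0.5); blocks below it are masked.
#' @return Coarse `grid_scene`.
#' @export
block_aggregate <- function(scene, factor, min_frac = 0.5) {
  f <- as.integer(factor)
  if (scene$nrow %% f != 0 || scene$ncol %% f != 0)
    stop("factor must divide the grid dimensions", call. = FALSE)
  nr <- scene$nrow %/% f; nc <- scene$ncol %/% f
  gt <- scene$geotransform
  gt_c <- c(gt[1] + (f - 1) / 2 * gt[2], gt[2] * f,
            gt[3] - (f - 1) / 2 * gt[4], gt[4] * f)
  idx_r <- rep(seq_len(nr), each = f)
  idx_c <- rep(seq_len(nc), each = f)
  out <- lapply(scene$bands, function(a) {
    res <- array(NA_real_, dim = c(nr, nc, scene$ntime))
    for (t in seq_len(scene$ntime)) {
      sl <- a[, , t]
      sums <- rowsum(t(rowsum(sl, idx_r, na.rm = TRUE)), idx_c, na.rm = TRUE)
      cnts <- rowsum(t(rowsum(0 + is.finite(sl), idx_r)), idx_c)
      m <- t(sums) / t(cnts)
      m[t(cnts) < min_frac * f * f] <- NA_real_
      res[, , t] <- m
    }
    res
  })
  grid_scene(out, geotransform = gt_c, crs = scene$crs, time = scene$time)
}

#' Apply a trained GP model to a gridded predictor scene
#'
#' Produces a per-pixel flux estimate and epistemic sigma for every time
#' slice. All model predictors must be present as scene bands on one grid
#' (resample beforehand). Pixels with any predictor outside the schema
#' range are, by default, clamped to the range and flagged (the flag layer
#' counts clamped predictors per pixel); `range_mode = "mask"` masks them,
#' `"none"` predicts at the raw values. Evaluation is chunked; results are
#' identical for any chunk size.
#'
#' @param model Fitted `gpr` model (or imported record with
#'   `as_gpr = TRUE`).
#' @param scene `grid_scene` whose bands cover `model$training$names`.
#' @param schema A [predictor_schema()] supplying the valid ranges.
#' @param range_mode `"clamp"`, `"mask"` or `"none"`.
#' @param chunk_size Pixels per prediction chunk.
#' @return A `flux_map` (umol m-2 s-1) with an extra element `flags`
#'   (array counting clamped/out-of-range predictors per pixel).
#' @export
predict_map <- function(model, scene, schema = predictor_schema(),
                        range_mode = c("clamp", "mask", "none"),
                        chunk_size = 4096L) {
  range_mode <- match.arg(range_mode)
  nm <- model$training$names
  miss <- setdiff(nm, names(scene$bands))
  if (length(miss))
    stop("scene is missing predictor band(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sch <- as.data.frame(schema)
  lo <- stats::setNames(sch$valid_min, sch$name)[nm]
  hi <- stats::setNames(sch$valid_max, sch$name)[nm]

  npx <- scene$nrow * scene$ncol
  est <- array(NA_real_, dim = c(scene$nrow, scene$ncol, scene$ntime))
  sig <- est
  flags <- array(0, dim = c(scene$nrow, scene$ncol, scene$ntime))
  for (t in seq_len(scene$ntime)) {
    X <- vapply(nm, function(b) as.vector(scene$bands[[b]][, , t]),
                numeric(npx))
    X <- matrix(X, nrow = npx, dimnames = list(NULL, nm))
    valid <- rowSums(!is.finite(X)) == 0L
    oob_n <- rep(0L, npx)
    if (any(valid)) {
      Xv <- X[valid, , drop = FALSE]
      oob <- sweep(Xv, 2, lo, "<") | sweep(Xv, 2, hi, ">")
      oob_n[valid] <- rowSums(oob)
      if (range_mode == "clamp") {
        Xv <- pmin(pmax(Xv, matrix(lo, nrow(Xv), length(nm), byrow = TRUE)),
                   matrix(hi, nrow(Xv), length(nm), byrow = TRUE))
      } else if (range_mode == "mask") {
        valid[valid] <- oob_n[valid] == 0L
        Xv <- Xv[rowSums(oob) == 0L, , drop = FALSE]
      }
      mu <- numeric(nrow(Xv)); sd_ <- numeric(nrow(Xv))
      i <- 1L
      while (i <= nrow(Xv)) {
        j <- min(i + chunk_size - 1L, nrow(Xv))
        pr <- predict(model, Xv[i:j, , drop = FALSE])
        mu[i:j] <- pr$mean; sd_[i:j] <- pr$sigma
        i <- j + 1L
      }
      e <- rep(NA_real_, npx); s <- rep(NA_real_, npx)
      e[valid] <- mu; s[valid] <- sd_
      est[, , t] <- matrix(e, scene$nrow, scene$ncol)
      sig[, , t] <- matrix(s, scene$nrow, scene$ncol)
    }
    flags[, , t] <- matrix(oob_n, scene$nrow, scene$ncol)
  }
  fm <- flux_map(est, sig, variable = model$training$flux_variable,
                 units = "umol m-2 s-1", period = scene$time,
                 geotransform = scene$geotransform, crs = scene$crs)
  fm$flags <- flags
  fm
}

#' Annual flux total with propagated uncertainty
#'
#' Time-weighted mean over a year of composites (weights = days per
#' composite: 8, with 5 or 6 in the final window) converted to
#' gC m-2 y-1. Sigma is aggregated as the day-weighted root mean square
#' of the composite sigmas, converted identically — an upper-bound
#' convention, not a calibrated interval. Pixels whose valid composites
#' cover less than `coverage` of the year's days are masked.
#'
#' @param fmap `flux_map` of composites for one year
#'   (umol m-2 s-1; `period` holds composite start dates).
#' @param coverage Minimum fraction of days covered (default 0.8).
#' @return Single-period `flux_map` in gC m-2 y-1.
#' @export
aggregate_annual <- function(fmap, coverage = 0.8) {
  stopifnot(inherits(fmap, "flux_map"))
  if (!inherits(fmap$period, "Date"))
    stop("aggregate_annual needs composite start dates in `period`",
         call. = FALSE)
  yr <- as.integer(strftime(fmap$period, "%Y"))
  if (length(unique(yr)) != 1L)
    stop("composites span multiple years; aggregate one year at a time",
         call. = FALSE)
  ndays_year <- if (yr[1] %% 4 == 0 && (yr[1] %% 100 != 0 || yr[1] %% 400 == 0))
    366L else 365L
  doy <- as.integer(strftime(fmap$period, "%j"))
  w <- ifelse(composite_index(doy) == 46L, ndays_year - 45L * 8L, 8L)

  nt <- fmap$ntime
  est2 <- matrix(fmap$estimate, ncol = nt)   # pixels x time
  sig2 <- matrix(fmap$sigma, ncol = nt)
  W <- matrix(w, nrow(est2), nt, byrow = TRUE)
  W[!is.finite(est2)] <- 0
  wsum <- rowSums(W)
  mean_flux <- rowSums(est2 * W, na.rm = TRUE) / wsum
  sig_flux <- sqrt(rowSums(sig2^2 * W, na.rm = TRUE) / wsum)
  low <- wsum < coverage * ndays_year
  mean_flux[low] <- NA_real_; sig_flux[low] <- NA_real_

  ann <- convert_flux_units(mean_flux, "umol m-2 s-1", "gC m-2 y-1",
                            days = ndays_year)
  ann_sig <- convert_flux_units(sig_flux, "umol m-2 s-1", "gC m-2 y-1",
                                days = ndays_year)
  flux_map(matrix(ann, fmap$nrow, fmap$ncol),
           matrix(ann_sig, fmap$nrow, fmap$ncol),
           variable = fmap$variable, units = "gC m-2 y-1",
           period = yr[1], geotransform = fmap$geotransform, crs = fmap$crs,
           nee_sign = fmap$nee_sign)
}
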
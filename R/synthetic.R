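# Family parameters are fixed so that ~99.5% of each distribution's mass
# falls inside the schema's [valid_min, valid_max] before truncation:
#   exponential — rate = 5 / range (mean = range/5)
#   uniform     — exact on the range
#   chi-square  — df 5, scaled so the 0.995 quantile hits valid_max
#   gamma       — shape 2, scaled likewise
# Sampling is by inverse CDF of the range-truncated distribution, which is
# what lets a Gaussian copula impose cross-predictor rank correlation.
trunc_quantile <- function(u, family, lo, hi) {
  r <- hi - lo
  switch(family,
    uniform = lo + u * r,
    exponential = {
      rate <- 5 / r
      lo + stats::qexp(u * stats::pexp(r, rate), rate)
    },
    "chi-square" = {
      df <- 5
      s <- r / stats::qchisq(0.995, df)
      lo + s * stats::qchisq(u * stats::pchisq(r / s, df), df)
    },
    gamma = {
      shape <- 2
      s <- r / stats::qgamma(0.995, shape, rate = 1)
      lo + s * stats::qgamma(u * stats::pgamma(r / s, shape, rate = 1),
                             shape, rate = 1)
    },
    stop("unknown distribution family: ", family, call. = FALSE))
}

#' Default cross-predictor rank-correlation matrix
#'
#' Hand-set Gaussian-copula correlations giving the generated predictors a
#' mildly realistic dependence structure (radiation-temperature coupling,
#' coherent soil profiles, energy-balance links); fully independent
#' predictors would make relevance ranking trivially easy. The matrix is
#' shrunk toward the identity if needed to stay positive definite.
#'
#' @param schema A [predictor_schema()].
#' @return D x D correlation matrix with dimnames = predictor names.
#' @export
default_copula_corr <- function(schema = predictor_schema()) {
  nm <- schema$name
  D <- length(nm)
  R <- diag(D); dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    if (a %in% nm && b %in% nm) { R[a, b] <<- r; R[b, a] <<- r }
  }
  set_r("SW", "TA", 0.5); set_r("SW", "H", 0.4); set_r("SW", "LE", 0.4)
  set_r("TA", "TS_1", 0.7); set_r("TS_1", "TS_2", 0.85)
  set_r("TS_2", "TS_3", 0.85); set_r("TS_1", "TS_3", 0.7)
  set_r("TA", "TS_2", 0.6); set_r("TA", "TS_3", 0.5)
  set_r("SWC_1", "SWC_2", 0.85); set_r("SWC_2", "SWC_3", 0.85)
  set_r("SWC_1", "SWC_3", 0.7); set_r("P", "SWC_1", 0.3)
  set_r("LAI", "LE", 0.4); set_r("LAI", "SW", 0.2)
  set_r("LE", "SWC_1", 0.3); set_r("WS", "H", 0.2)
  # shrink toward identity until positive definite
  lam <- 1
  while (min(eigen(diag(D) * (1 - lam) + lam * R,
                   symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    lam <- lam * 0.95
  diag(D) * (1 - lam) + lam * R
}

#' Sample synthetic tower predictors
#'
#' Draws `n` rows with each column following its schema distribution
#' family truncated to the schema range, with cross-column dependence via
#' a Gaussian copula.
#'
#' @param n Number of rows (0 allowed).
#' @param schema A [predictor_schema()].
#' @param seed Integer seed.
#' @param copula_corr D x D copula correlation matrix
#'   (default [default_copula_corr()]).
#' @return n x D data.frame with predictor columns.
#' @export
sample_predictors <- function(n, schema = predictor_schema(), seed = 1L,
                              copula_corr = default_copula_corr(schema)) {
  assert_schema(schema)
  D <- nrow(schema)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, D))
    names(out) <- schema$name
    return(out)
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * D), n, D) %*% chol(copula_corr)
  U <- stats::pnorm(Z)
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  out <- as.data.frame(lapply(seq_len(D), function(k)
    trunc_quantile(U[, k], schema$family[k],
                   schema$valid_min[k], schema$valid_max[k])))
  names(out) <- schema$name
  out
}

#' Default parameters of the synthetic flux-generating function
#'
#' Light-use-efficiency-style gross productivity with canopy light
#' interception, radiation saturation, soil-moisture and temperature
#' limiters; Q10 respiration with a growth-coupled component. Values are
#' chosen to give daily flux magnitudes typical of mid-latitude towers
#' (GPP of a few umol m-2 s-1 at the generator's mean conditions, peaking
#' above 15 under favourable conditions).
#'
#' @return Named list: `g_max` (umol m-2 s-1), `k_L` (per unit LAI),
#'   `S_half` (W m-2), `W_half` (% SWC), `T_opt`, `T_width` (degC),
#'   `r_b` (umol m-2 s-1), `Q10`, `T_ref` (degC), `f_g` (unitless).
#' @export
default_flux_params <- function() {
  list(g_max = 25, k_L = 0.5, S_half = 100, W_half = 15,
       T_opt = 20, T_width = 15, r_b = 2, Q10 = 2, T_ref = 10, f_g = 0.3)
}

#' Generate synthetic fluxes from a predictor table
#'
#' Noise-free construction:
#' \deqn{GPP = g_{max}(1 - e^{-k_L \cdot LAI}) \frac{SW}{SW + S_{1/2}}
#'   \frac{SWC_1}{SWC_1 + W_{1/2}} e^{-((TA - T_{opt})/T_{width})^2}}
#' \deqn{RECO = r_b \, Q_{10}^{(TS_1 - T_{ref})/10} + f_g \cdot GPP}
#' \deqn{NEE = GPP - RECO}
#' (NEE in the stored uptake-positive convention), plus independent
#' Gaussian noise per flux. The noise-free values and the generating
#' parameters are attached as ground truth for recovery tests.
#'
#' @param predictors Data.frame/matrix with at least `LAI`, `SW`, `SWC_1`,
#'   `TA`, `TS_1` columns.
#' @param params Parameter list, see [default_flux_params()].
#' @param noise_sd Named vector of noise standard deviations for
#'   GPP/RECO/NEE (umol m-2 s-1); a single number is recycled; `NULL`
#'   means 10% of each flux's noise-free standard deviation.
#' @param seed Integer seed for the noise draws.
#' @return Data.frame with `GPP`, `RECO`, `NEE` columns; attributes
#'   `truth` (noise-free data.frame), `params` and `noise_sd`.
#' @export
generate_fluxes <- function(predictors, params = default_flux_params(),
                            noise_sd = NULL, seed = 1L) {
  if (params$g_max <= 0 || params$r_b <= 0)
    stop("g_max and r_b must be positive", call. = FALSE)
  p <- as.data.frame(predictors)
  need <- c("LAI", "SW", "SWC_1", "TA", "TS_1")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("predictors missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  light <- 1 - exp(-params$k_L * p$LAI)
  rad <- p$SW / (p$SW + params$S_half)
  water <- p$SWC_1 / (p$SWC_1 + params$W_half)
  temp <- exp(-((p$TA - params$T_opt) / params$T_width)^2)
  gpp0 <- params$g_max * light * rad * water * temp
  reco0 <- params$r_b * params$Q10^((p$TS_1 - params$T_ref) / 10) +
    params$f_g * gpp0
  nee0 <- gpp0 - reco0

  truth <- data.frame(GPP = gpp0, RECO = reco0, NEE = nee0)
  if (is.null(noise_sd))
    noise_sd <- vapply(truth, function(v) 0.1 * stats::sd(v), 0)
  noise_sd <- rep_len(noise_sd, 3L)
  names(noise_sd) <- flux_variables()
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)

  n <- nrow(p)
  set.seed(seed)
  out <- data.frame(
    GPP = gpp0 + stats::rnorm(n, 0, noise_sd["GPP"]),
    RECO = reco0 + stats::rnorm(n, 0, noise_sd["RECO"]),
    NEE = nee0 + stats::rnorm(n, 0, noise_sd["NEE"])
  )
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Generate a synthetic tower table
#'
#' Convenience wrapper: [sample_predictors()] + [generate_fluxes()] with
#' random site/class labels, in the layout [read_tower_table()] returns.
#'
#' @inheritParams sample_predictors
#' @inheritParams generate_fluxes
#' @param n_sites Number of synthetic site labels to spread rows over.
#' @return A `tower_table` data.frame; ground truth in attributes as in
#'   [generate_fluxes()].
#' @export
generate_tower_table <- function(n, schema = predictor_schema(), seed = 1L,
                                 params = default_flux_params(),
                                 noise_sd = NULL, n_sites = 12L) {
  pred <- sample_predictors(n, schema, seed = seed)
  fl <- generate_fluxes(pred, params, noise_sd, seed = seed + 1L)
  set.seed(seed + 2L)
  sites <- sprintf("SYN-%02d", seq_len(n_sites))
  site_class <- sample(vegetation_classes(), n_sites, replace = TRUE)
  idx <- sample.int(n_sites, n, replace = TRUE)
  out <- cbind(
    data.frame(site_id = sites[idx],
               date = as.Date("2020-01-01") + seq_len(n) - 1L,
               vegetation_class = site_class[idx],
               stringsAsFactors = FALSE),
    pred, fl)
  attr(out, "truth") <- attr(fl, "truth")
  attr(out, "params") <- params
  attr(out, "noise_sd") <- attr(fl, "noise_sd")
  attr(out, "nee_sign") <- "uptake_positive"
  class(out) <- c("tower_table", "data.frame")
  out
}

# class-specific seasonal amplitude (in copula z units) and peak day of year
season_config <- function(vegetation_class) {
  cfg <- list(
    CRO = c(1.0, 190), ENF = c(0.8, 200), DBF = c(1.2, 195),
    EBF = c(0.2, 180), DNF = c(1.3, 200), GRA = c(0.9, 180),
    WET = c(0.8, 190), CSH = c(0.6, 170), OSH = c(0.6, 170),
    MF = c(1.0, 195), MSF = c(0.5, 150))
  v <- cfg[[vegetation_class]]
  if (is.null(v)) v <- c(0.8, 190)
  list(amplitude = v[1], peak_doy = v[2])
}

#' Generate a daily synthetic tower time series
#'
#' Predictors follow class-specific sinusoidal seasonal cycles plus AR(1)
#' noise on the copula scale, mapped through the schema's truncated
#' distribution families, so every value stays inside its valid range.
#' Fluxes are computed day-wise with [generate_fluxes()].
#'
#' @param site_id Site label.
#' @param vegetation_class One of [vegetation_classes()].
#' @param years Number of years (> 0).
#' @param seed Integer seed.
#' @param schema A [predictor_schema()].
#' @param params Flux-function parameters.
#' @param noise_sd Flux noise, as in [generate_fluxes()].
#' @param start Start date (default 2019-01-01).
#' @return A `tower_table` data.frame of daily records with ground-truth
#'   attributes.
#' @export
generate_tower_series <- function(site_id, vegetation_class, years = 1,
                                  seed = 1L, schema = predictor_schema(),
                                  params = default_flux_params(),
                                  noise_sd = NULL,
                                  start = as.Date("2019-01-01")) {
  if (years <= 0) stop("years must be > 0", call. = FALSE)
  assert_schema(schema)
  dates <- seq(start, by = "day", length.out = round(365 * years))
  nd <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  sc <- season_config(vegetation_class)
  seas <- sc$amplitude * sin(2 * pi * (doy - (sc$peak_doy - 365.25 / 4)) /
                               365.25)
  D <- nrow(schema)
  set.seed(seed)
  pred <- matrix(0, nd, D)
  for (k in seq_len(D)) {
    # AR(1) innovations, rho = 0.8
    e <- stats::rnorm(nd, 0, 0.6)
    z <- stats::filter(e, 0.8, method = "recursive")
    amp_k <- if (schema$name[k] %in% c("SWC_1", "SWC_2", "SWC_3", "P", "WS"))
      -0.4 * sc$amplitude else sc$amplitude  # moisture/wind peak off-season
    zk <- amp_k / sc$amplitude * seas + as.numeric(z)
    u <- pmin(pmax(stats::pnorm(zk), 1e-6), 1 - 1e-6)
    pred[, k] <- trunc_quantile(u, schema$family[k],
                                schema$valid_min[k], schema$valid_max[k])
  }
  colnames(pred) <- schema$name
  pred <- as.data.frame(pred)
  fl <- generate_fluxes(pred, params, noise_sd, seed = seed + 1L)
  out <- cbind(data.frame(site_id = site_id, date = dates,
                          vegetation_class = vegetation_class,
                          stringsAsFactors = FALSE),
               pred, fl)
  attr(out, "truth") <- attr(fl, "truth")
  attr(out, "params") <- params
  attr(out, "noise_sd") <- attr(fl, "noise_sd")
  attr(out, "nee_sign") <- "uptake_positive"
  class(out) <- c("tower_table", "data.frame")
  out
}

# smooth standard-normal-ish random field: coarse white noise, bilinearly
# upsampled to (nr, nc); correlation length ~ `scale` pixels
smooth_field <- function(nr, nc, scale = 10) {
  cr <- max(2L, ceiling(nr / scale) + 1L)
  cc <- max(2L, ceiling(nc / scale) + 1L)
  z <- matrix(stats::rnorm(cr * cc), cr, cc)
  ri <- seq(1, cr, length.out = nr)
  ci <- seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1L); c0 <- pmin(floor(ci), cc - 1L)
  fr <- ri - r0; fc <- ci - c0
  z00 <- z[cbind(rep(r0, nc), rep(c0, each = nr))]
  z10 <- z[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  z01 <- z[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  z11 <- z[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  w00 <- (1 - rep(fr, nc)) * (1 - rep(fc, each = nr))
  w10 <- rep(fr, nc) * (1 - rep(fc, each = nr))
  w01 <- (1 - rep(fr, nc)) * rep(fc, each = nr)
  w11 <- rep(fr, nc) * rep(fc, each = nr)
  matrix(z00 * w00 + z10 * w10 + z01 * w01 + z11 * w11, nr, nc)
}

block_mean <- function(mat, f) {
  nr <- nrow(mat) %/% f; nc <- ncol(mat) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(mat[((i - 1) * f + 1):(i * f),
                          ((j - 1) * f + 1):(j * f)])
  out
}

#' Generate a synthetic two-resolution raster scene with ground truth
#'
#' Emulates the gridded inputs of the upscaling pipeline: a fine-grid LAI
#' stack, a coarser climate stack (integer resolution ratio, obtained by
#' block-averaging the underlying fine fields), a categorical vegetation
#' mosaic, and noise-free "true" flux rasters computed on the co-registered
#' fine grid. Spatial structure comes from smoothed random fields with
#' vegetation-class offsets; the temporal dimension follows a seasonal
#' cycle over the 8-day composites. Fields are mapped linearly onto the
#' schema range, with the top 1% tail of each band stretched beyond
#' `valid_max` by up to `overshoot` of the range width, so a small
#' fraction of pixels deliberately falls outside the tower training ranges
#' (the extrapolation regime whose inflated uncertainty the pipeline is
#' meant to expose).
#'
#' @param nrow,ncol Fine-grid dimensions.
#' @param coarse_factor Integer ratio fine/coarse pixel size; must divide
#'   both `nrow` and `ncol`.
#' @param time_steps Number of 8-day composites (46 = one year).
#' @param seed Integer seed.
#' @param schema A [predictor_schema()].
#' @param params Flux-function parameters.
#' @param n_classes Number of vegetation classes in the mosaic.
#' @param overshoot Maximum exceedance of the upper range limit, as a
#'   fraction of the range width (default 0.10, reached only at the very
#'   top of the 1% stretched tail).
#' @return List: `lai` and `climate` (`grid_scene`s at fine/coarse
#'   resolution), `predictors` (all bands on the fine grid), `vegetation`
#'   (character matrix of class codes), `truth` (`grid_scene` of
#'   noise-free GPP/RECO/NEE on the fine grid), `params`, `schema`.
#' @export
generate_grid_scene <- function(nrow = 60, ncol = 60, coarse_factor = 3,
                                time_steps = 46, seed = 1L,
                                schema = predictor_schema(),
                                params = default_flux_params(),
                                n_classes = 5, overshoot = 0.10) {
  assert_schema(schema)
  if (nrow %% coarse_factor != 0 || ncol %% coarse_factor != 0)
    stop("coarse_factor must divide the fine grid dimensions exactly",
         call. = FALSE)
  set.seed(seed)
  # vegetation mosaic: nearest-upsampled coarse categorical field
  blk <- max(4L, coarse_factor * 4L)
  vr <- ceiling(nrow / blk); vc <- ceiling(ncol / blk)
  veg_codes <- sample(vegetation_classes(), n_classes)
  veg_coarse <- matrix(sample(veg_codes, vr * vc, replace = TRUE), vr, vc)
  veg <- veg_coarse[pmin(ceiling(seq_len(nrow) / blk), vr),
                    pmin(ceiling(seq_len(ncol) / blk), vc), drop = FALSE]

  D <- nrow(schema)
  class_offset <- matrix(stats::rnorm(n_classes * D, 0, 0.5), n_classes, D,
                         dimnames = list(veg_codes, schema$name))
  veg_idx <- matrix(match(veg, veg_codes), nrow, ncol)

  fine <- stats::setNames(vector("list", D), schema$name)
  tt <- seq_len(time_steps)
  seas_base <- sin(2 * pi * (tt - 1) / max(time_steps, 2) - pi / 2)
  for (k in seq_len(D)) {
    base <- 0.8 * smooth_field(nrow, ncol, scale = 10) +
      matrix(class_offset[cbind(as.vector(veg_idx), k)], nrow, ncol)
    amp <- if (schema$name[k] %in% c("SWC_1", "SWC_2", "SWC_3", "P"))
      -0.5 else 0.9
    arr <- array(0, dim = c(nrow, ncol, time_steps))
    for (t in tt) {
      z <- base + amp * seas_base[t] + 0.15 * smooth_field(nrow, ncol, 15)
      u <- stats::pnorm(z)
      lo <- schema$valid_min[k]
      hi <- schema$valid_max[k]
      # stretch the top 1% tail beyond valid_max by up to `overshoot` of
      # the range: rare, genuinely out-of-range pixels
      u <- u + pmax(0, u - 0.99) * (overshoot / 0.01)
      arr[, , t] <- lo + u * (hi - lo)
    }
    fine[[k]] <- arr
  }

  # truth fluxes, noise-free, per composite on the fine grid
  npx <- nrow * ncol
  truth <- list(GPP = array(0, c(nrow, ncol, time_steps)),
                RECO = array(0, c(nrow, ncol, time_steps)),
                NEE = array(0, c(nrow, ncol, time_steps)))
  for (t in tt) {
    pt <- as.data.frame(lapply(fine, function(a) as.vector(a[, , t])))
    fl <- attr(generate_fluxes(pt, params, noise_sd = 0, seed = 1L), "truth")
    truth$GPP[, , t] <- matrix(fl$GPP, nrow, ncol)
    truth$RECO[, , t] <- matrix(fl$RECO, nrow, ncol)
    truth$NEE[, , t] <- matrix(fl$NEE, nrow, ncol)
  }

  time_idx <- as.Date("2020-01-01") + (tt - 1) * 8
  gt_fine <- c(0.5, 1, nrow - 0.5, 1)   # unit pixels, y decreasing by row
  gt_coarse <- c(coarse_factor / 2, coarse_factor,
                 nrow - coarse_factor / 2, coarse_factor)
  climate_names <- setdiff(schema$name, "LAI")
  climate <- lapply(fine[climate_names], function(a) {
    out <- array(0, c(nrow %/% coarse_factor, ncol %/% coarse_factor,
                      time_steps))
    for (t in tt) out[, , t] <- block_mean(a[, , t], coarse_factor)
    out
  })
  list(
    lai = grid_scene(fine["LAI"], gt_fine, crs = "synthetic", time = time_idx),
    climate = grid_scene(climate, gt_coarse, crs = "synthetic",
                         time = time_idx),
    predictors = grid_scene(fine, gt_fine, crs = "synthetic",
                            time = time_idx),
    vegetation = veg,
    truth = grid_scene(truth, gt_fine, crs = "synthetic", time = time_idx),
    params = params, schema = schema
  )
}
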
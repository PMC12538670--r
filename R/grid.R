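#' Multi-band, multi-time raster scene
#'
#' The in-memory carrier for gridded predictor stacks and flux products.
#' All bands share one grid. Coordinate convention (used package-wide):
#' pixel-centre registration on a row-major, north-up grid — the
#' geotransform `c(x0, dx, y0, dy)` places the centre of pixel (row i,
#' col j) at `x = x0 + (j-1)*dx`, `y = y0 - (i-1)*dy`, with `dx, dy > 0`
#' and row 1 the northernmost. Invalid cells are `NA`; the scene mask is
#' the union of per-band invalidity.
#'
#' @param bands Named list of numeric matrices (single time) or 3-D arrays
#'   (`nrow x ncol x ntime`); all must share dimensions.
#' @param geotransform Numeric `c(x0, dx, y0, dy)` (pixel-centre origin and
#'   positive pixel sizes).
#' @param crs CRS identifier string (tag only; no reprojection is done).
#' @param time Time index: vector of composite start dates (`Date`) or
#'   integer step indices, length `ntime`.
#' @return An object of class `grid_scene`.
#' @export
grid_scene <- function(bands, geotransform = c(0, 1, 0, 1),
                       crs = "local", time = NULL) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("`bands` must be a named list", call. = FALSE)
  bands <- lapply(bands, function(b) {
    if (is.matrix(b)) b <- array(b, dim = c(dim(b), 1L))
    if (length(dim(b)) != 3L) stop("bands must be matrices or 3-D arrays",
                                   call. = FALSE)
    storage.mode(b) <- "double"
    b
  })
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L)
    stop("all bands must share shape; got ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "),
         call. = FALSE)
  d <- dims[[1L]]
  if (is.null(time)) time <- seq_len(d[3L])
  if (length(time) != d[3L])
    stop("time index length != number of time slices", call. = FALSE)
  structure(list(bands = bands, nrow = d[1L], ncol = d[2L], ntime = d[3L],
                 geotransform = as.numeric(geotransform), crs = crs,
                 time = time),
            class = "grid_scene")
}

#' @export
print.grid_scene <- function(x, ...) {
  cat(sprintf("grid_scene: %d x %d pixels, %d time step(s), %d band(s)\n",
              x$nrow, x$ncol, x$ntime, length(x$bands)))
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat(sprintf("  geotransform: x0=%g dx=%g y0=%g dy=%g; crs: %s\n",
              x$geotransform[1], x$geotransform[2], x$geotransform[3],
              x$geotransform[4], x$crs))
  invisible(x)
}

#' Union nodata mask of a scene
#' @param scene A `grid_scene`.
#' @return Logical array (`nrow x ncol x ntime`); `TRUE` where any band is
#'   invalid (non-finite).
#' @export
scene_mask <- function(scene) {
  m <- array(FALSE, dim = c(scene$nrow, scene$ncol, scene$ntime))
  for (b in scene$bands) m <- m | !is.finite(b)
  m
}

#' Pixel-centre coordinates of a scene
#' @param scene A `grid_scene`.
#' @return List with vectors `x` (length ncol) and `y` (length nrow).
#' @export
scene_coords <- function(scene) {
  gt <- scene$geotransform
  list(x = gt[1] + (seq_len(scene$ncol) - 1) * gt[2],
       y = gt[3] - (seq_len(scene$nrow) - 1) * gt[4])
}

#' Per-pixel flux map with epistemic uncertainty
#'
#' @param estimate,sigma Matrices or 3-D arrays on one grid; `sigma` must
#'   be non-negative wherever valid and shares the mask of `estimate`.
#' @param variable Flux tag (GPP/RECO/NEE).
#' @param units Flux units string.
#' @param period Composite start date(s), year, or index.
#' @param geotransform,crs As in [grid_scene()].
#' @param nee_sign Sign convention tag for NEE
#'   (`"uptake_positive"` = atmosphere-to-biosphere positive).
#' @return An object of class `flux_map`.
#' @export
flux_map <- function(estimate, sigma, variable, units = "umol m-2 s-1",
                     period = NULL, geotransform = c(0, 1, 0, 1),
                     crs = "local", nee_sign = "uptake_positive") {
  to3 <- function(a) if (is.matrix(a)) array(a, dim = c(dim(a), 1L)) else a
  estimate <- to3(estimate); sigma <- to3(sigma)
  if (!identical(dim(estimate), dim(sigma)))
    stop("estimate and sigma must share shape", call. = FALSE)
  # harmonize masks: a pixel invalid in either layer is invalid in both
  bad <- !is.finite(estimate) | !is.finite(sigma)
  estimate[bad] <- NA_real_; sigma[bad] <- NA_real_
  if (any(sigma < 0, na.rm = TRUE))
    stop("sigma must be non-negative", call. = FALSE)
  d <- dim(estimate)
  if (is.null(period)) period <- seq_len(d[3L])
  structure(list(estimate = estimate, sigma = sigma, variable = variable,
                 units = units, period = period, nrow = d[1L], ncol = d[2L],
                 ntime = d[3L], geotransform = as.numeric(geotransform),
                 crs = crs, nee_sign = nee_sign),
            class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat(sprintf("flux_map [%s, %s]: %d x %d pixels, %d period(s)\n",
              x$variable, x$units, x$nrow, x$ncol, x$ntime))
  est <- x$estimate
  cat(sprintf("  estimate range: [%.3f, %.3f]; median sigma: %.3f; %d masked\n",
              suppressWarnings(min(est, na.rm = TRUE)),
              suppressWarnings(max(est, na.rm = TRUE)),
              stats::median(x$sigma, na.rm = TRUE), sum(!is.finite(est))))
  invisible(x)
}

# ---- scene / flux-map file I/O ---------------------------------------------
#
# Two on-disk representations:
#   *.rds      — native serialization; lossless float64 round-trip.
#   <prefix>   — directory of ESRI ASCII Grid files (*.asc, plain text, one
#                per band and time slice) plus manifest.json carrying band
#                names, time index, CRS and geotransform. Values printed
#                with %.17g, so doubles survive the text round-trip exactly.
# ASCII Grid registers grids by cell corners; the writer converts from the
# pixel-centre geotransform and the reader converts back.

write_asc <- function(mat, path, gt, nodata = -9999) {
  nr <- nrow(mat); nc <- ncol(mat)
  xll <- gt[1] - gt[2] / 2                 # corner of lower-left cell
  yll <- (gt[3] - (nr - 1) * gt[4]) - gt[4] / 2
  if (abs(gt[2] - gt[4]) > 1e-12 * max(gt[2], gt[4]))
    stop("ASCII Grid requires square pixels; use the .rds path", call. = FALSE)
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g",
    nc, nr, xll, yll, gt[2], nodata)
  m <- mat
  m[!is.finite(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  nodata <- vals["nodata_value"]
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  mat <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  mat[mat == nodata] <- NA_real_
  cs <- vals["cellsize"]
  gt <- c(vals["xllcorner"] + cs / 2, cs,
          vals["yllcorner"] + cs / 2 + (nr - 1) * cs, cs)
  list(mat = mat, geotransform = unname(gt))
}

#' Write a scene or flux map to disk
#'
#' `path` ending in `.rds` uses native serialization (lossless float64).
#' Otherwise `path` is created as a directory of plain-text ESRI ASCII Grid
#' files (one per band and time slice) with a `manifest.json`; doubles are
#' printed with 17 significant digits and round-trip exactly.
#'
#' @param x A `grid_scene` or `flux_map`.
#' @param path Output `.rds` file or directory prefix.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path) {
  if (grepl("\\.rds$", path)) { saveRDS(x, path); return(invisible(path)) }
  if (inherits(x, "flux_map"))
    x <- grid_scene(list(estimate = x$estimate, sigma = x$sigma),
                    geotransform = x$geotransform, crs = x$crs,
                    time = if (length(x$period) == x$ntime) x$period
                           else seq_len(x$ntime))
  if (!inherits(x, "grid_scene")) stop("unsupported object", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (bn in names(x$bands)) {
    files[[bn]] <- character(x$ntime)
    for (t in seq_len(x$ntime)) {
      f <- sprintf("%s_t%03d.asc", bn, t)
      write_asc(x$bands[[bn]][, , t], file.path(path, f), x$geotransform)
      files[[bn]][t] <- f
    }
  }
  manifest <- list(format = "fluxgpr-asc-scene-1",
                   bands = names(x$bands), files = files,
                   geotransform = x$geotransform, crs = x$crs,
                   time = as.character(x$time),
                   nrow = x$nrow, ncol = x$ncol, ntime = x$ntime)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [write_grid()]
#'
#' @param path `.rds` file or ASCII-grid directory.
#' @param crs_default CRS assumed (with a warning) when the manifest lacks
#'   one.
#' @return A `grid_scene` (or whatever object the `.rds` holds).
#' @export
read_grid <- function(path, crs_default = "local") {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", path, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  crs <- mf$crs
  if (is.null(crs)) { warning("manifest has no CRS; assuming ", crs_default)
                      crs <- crs_default }
  bands <- list()
  gt <- NULL
  for (bn in mf$bands) {
    arr <- array(NA_real_, dim = c(mf$nrow, mf$ncol, mf$ntime))
    for (t in seq_len(mf$ntime)) {
      g <- read_asc(file.path(path, mf$files[[bn]][t]))
      if (!identical(dim(g$mat), c(mf$nrow, mf$ncol)))
        stop("band ", bn, " slice ", t, " shape mismatch", call. = FALSE)
      arr[, , t] <- g$mat
      gt <- g$geotransform
    }
    bands[[bn]] <- arr
  }
  tm <- tryCatch(as.Date(mf$time), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tm) || anyNA(tm)) tm <- suppressWarnings(as.numeric(mf$time))
  grid_scene(bands, geotransform = mf$geotransform, crs = crs, time = tm)
}
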
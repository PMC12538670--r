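#' Predictor schema for tower-based carbon-flux models
#'
#' The model uses D = 13 predictors: leaf area index (LAI) plus 12 daily-mean
#' climate/energy variables observed at eddy-covariance towers — shortwave
#' incoming radiation, vapour pressure deficit, soil temperature and soil
#' water content at three depths, sensible and latent heat flux,
#' precipitation, air temperature and wind speed. Each predictor carries the
#' physical units, the valid training range and the distribution family its
#' daily values follow across the tower network; the synthetic generator
#' samples from exactly these families truncated to these ranges.
#'
#' @return A data.frame of class `predictor_schema` with columns
#'   `name`, `units`, `valid_min`, `valid_max`, `family`, one row per
#'   predictor, in canonical column order.
#' @examples
#' sch <- predictor_schema()
#' nrow(sch)   # 13
#' @export
predictor_schema <- function() {
  sch <- data.frame(
    name = c("LAI", "SW", "VPD",
             "TS_1", "TS_2", "TS_3",
             "SWC_1", "SWC_2", "SWC_3",
             "H", "LE", "P", "TA", "WS"),
    units = c("m2 m-2", "W m-2", "hPa",
              "degC", "degC", "degC",
              "%", "%", "%",
              "W m-2", "W m-2", "mm", "degC", "m s-1"),
    valid_min = c(0, 2.94, 0.07,
                  -0.79, -0.79, -0.79,
                  0, 0, 0,
                  -80.42, -15.60, 0, -4.92, 0.64),
    valid_max = c(9.38, 357.39, 19.01,
                  28.02, 28.02, 28.02,
                  94.54, 94.54, 94.54,
                  163.58, 238.44, 36.46, 26.71, 8.41),
    family = c("exponential", "uniform", "exponential",
               "chi-square", "chi-square", "chi-square",
               "gamma", "gamma", "gamma",
               "chi-square", "gamma", "exponential", "chi-square", "gamma"),
    stringsAsFactors = FALSE
  )
  # D = 13: LAI + the 12 climate bands available in the gridded reanalysis
  # stack (SW, TS1-3, SWC1-3, H, LE, P, TA, WS). VPD is observed at towers
  # but has no band in that stack, so it is not part of the model schema.
  sch <- sch[sch$name != "VPD", , drop = FALSE]
  rownames(sch) <- NULL
  stopifnot(nrow(sch) == 13L, !anyDuplicated(sch$name),
            all(sch$valid_min < sch$valid_max))
  class(sch) <- c("predictor_schema", "data.frame")
  sch
}

#' Number of predictors in a schema
#' @param schema A `predictor_schema`.
#' @return Integer predictor count D.
#' @export
schema_dim <- function(schema) nrow(schema)

#' Vegetation classes recognised in tower records
#'
#' IGBP-style land-cover codes used to label tower sites: cropland,
#' evergreen/deciduous needleleaf and broadleaf forest, grassland, wetland,
#' closed/open shrubland, mixed forest and Mediterranean sclerophyll forest.
#' @return Character vector of class codes.
#' @export
vegetation_classes <- function() {
  c("CRO", "ENF", "DBF", "EBF", "DNF", "GRA", "WET", "CSH", "OSH", "MF", "MSF")
}

#' Flux variable names
#' @return Character vector `c("GPP", "RECO", "NEE")`.
#' @export
flux_variables <- function() c("GPP", "RECO", "NEE")

assert_schema <- function(schema) {
  if (!inherits(schema, "predictor_schema"))
    stop("`schema` must be a predictor_schema (see predictor_schema())",
         call. = FALSE)
  invisible(schema)
}
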
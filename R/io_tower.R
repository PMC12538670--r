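#' Read a tower predictor/flux table
#'
#' Parses a comma-separated site-day table with a header row into a
#' `tower_table` data.frame. Expected columns: `site_id`, `date`
#' (ISO-8601), optionally `vegetation_class`, the predictor columns of
#' `schema`, and any of `GPP`, `RECO`, `NEE` (umol m-2 s-1). FLUXNET-style
#' column aliases (e.g. `SW_IN`, `TA_F`) can be mapped via `aliases`.
#'
#' The reader is total: malformed rows (unparseable dates, non-numeric
#' values) are dropped with a line-located diagnostic, and out-of-range
#' predictor values are flagged but kept (downstream assembly decides what
#' to drop). Missing deeper soil-depth columns (`TS_2/TS_3`,
#' `SWC_2/SWC_3`) are filled by copying the deepest available measurement,
#' with a fill flag recorded.
#'
#' @param path CSV file path.
#' @param schema A [predictor_schema()].
#' @param nee_sign Sign convention used *in the file* for NEE:
#'   `"uptake_positive"` (atmosphere-to-biosphere positive, the convention
#'   stored internally) or `"release_positive"` (micrometeorological
#'   convention; values are negated on read).
#' @param aliases Named character vector mapping file column names to
#'   schema names, e.g. `c(SW_IN = "SW", TA_F = "TA")`.
#' @return A data.frame of class `tower_table` with attributes
#'   `issues` (row-level diagnostics: line, problem) and `flags`
#'   (cell-level flags: line, column, value, flag).
#' @export
read_tower_table <- function(path, schema = predictor_schema(),
                             nee_sign = c("uptake_positive",
                                          "release_positive"),
                             aliases = NULL) {
  nee_sign <- match.arg(nee_sign)
  assert_schema(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- aliases[names(raw)[hit]]
  }

  fill_from <- list(TS_2 = c("TS_2", "TS_1"), TS_3 = c("TS_3", "TS_2", "TS_1"),
                    SWC_2 = c("SWC_2", "SWC_1"),
                    SWC_3 = c("SWC_3", "SWC_2", "SWC_1"))
  mandatory <- c("site_id", "date",
                 setdiff(schema$name, names(fill_from)))
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("tower table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  issues <- list(); flags <- list()
  note <- function(line, problem) issues[[length(issues) + 1L]] <<-
    data.frame(line = line, problem = problem)
  flag <- function(line, column, value, what) flags[[length(flags) + 1L]] <<-
    data.frame(line = line, column = column, value = value, flag = what)
  if (n == 0L) {
    out <- raw[0, , drop = FALSE]
  } else {
    line_no <- seq_len(n) + 1L  # header is line 1

    dates <- as.Date(raw$date, format = "%Y-%m-%d")
    bad_date <- is.na(dates)
    for (i in which(bad_date))
      note(line_no[i], sprintf("unparseable date '%s'", raw$date[i]))

    num_cols <- intersect(c(schema$name, names(fill_from), flux_variables()),
                          names(raw))
    nums <- lapply(raw[num_cols], function(v) {
      v[v %in% c("", "NA", "NaN")] <- NA
      suppressWarnings(as.numeric(v))
    })
    bad_num <- rep(FALSE, n)
    for (cn in num_cols) {
      corrupt <- !is.na(raw[[cn]]) & raw[[cn]] != "" &
        !raw[[cn]] %in% c("NA", "NaN") & is.na(nums[[cn]])
      for (i in which(corrupt))
        note(line_no[i], sprintf("non-numeric value '%s' in column %s",
                                 raw[[cn]][i], cn))
      bad_num <- bad_num | corrupt
    }
    keep <- !bad_date & !bad_num

    out <- data.frame(site_id = raw$site_id, date = dates,
                      stringsAsFactors = FALSE)
    out$vegetation_class <- if ("vegetation_class" %in% names(raw))
      raw$vegetation_class else NA_character_
    unknown_veg <- !is.na(out$vegetation_class) &
      !out$vegetation_class %in% vegetation_classes()
    for (i in which(unknown_veg & keep))
      flag(line_no[i], "vegetation_class", out$vegetation_class[i],
           "unknown class")
    for (cn in num_cols) out[[cn]] <- nums[[cn]]

    # soil-depth fill: copy the deepest available measurement downward
    for (tgt in names(fill_from)) {
      srcs <- intersect(fill_from[[tgt]], names(out))
      if (!tgt %in% names(out)) out[[tgt]] <- NA_real_
      need <- is.na(out[[tgt]])
      for (s in srcs[-1]) {
        fixable <- need & !is.na(out[[s]])
        if (any(fixable)) {
          out[[tgt]][fixable] <- out[[s]][fixable]
          for (i in which(fixable & keep))
            flag(line_no[i], tgt, out[[tgt]][i],
                 sprintf("filled from %s", s))
          need <- is.na(out[[tgt]])
        }
      }
    }

    if ("NEE" %in% names(out) && nee_sign == "release_positive")
      out$NEE <- -out$NEE

    # range flags (kept, not dropped)
    for (k in seq_len(nrow(schema))) {
      cn <- schema$name[k]
      v <- out[[cn]]
      oob <- !is.na(v) & (v < schema$valid_min[k] | v > schema$valid_max[k])
      for (i in which(oob & keep))
        flag(line_no[i], cn, v[i],
             sprintf("out of range [%g, %g]", schema$valid_min[k],
                     schema$valid_max[k]))
    }

    extra <- setdiff(names(raw),
                     c("site_id", "date", "vegetation_class", num_cols))
    for (cn in extra) out[[cn]] <- raw[[cn]]
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }

  for (fv in setdiff(flux_variables(), names(out))) out[[fv]] <- NULL
  attr(out, "issues") <- if (length(issues)) do.call(rbind, issues) else
    data.frame(line = integer(), problem = character())
  attr(out, "flags") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(line = integer(), column = character(), value = numeric(),
               flag = character())
  attr(out, "nee_sign") <- "uptake_positive"
  class(out) <- c("tower_table", "data.frame")
  out
}

#' Write a tower table to CSV
#'
#' @param x Data.frame with `site_id`, `date`, predictor and flux columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tower_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
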
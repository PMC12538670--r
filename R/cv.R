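#' Validation metrics: R2, RMSE, normalized RMSE
#'
#' `r2` is the coefficient of determination `1 - SS_res/SS_tot` (the
#' scatterplot-validation convention, not squared correlation; it can be
#' negative). `nrmse` is RMSE normalized by the observed range, in
#' percent. The squared Pearson correlation is reported alongside in the
#' audit field.
#'
#' @param obs,pred Equal-length numeric vectors (length >= 2); pairs with
#'   missing values are dropped.
#' @return List of class `metric_set`: `r2`, `rmse`, `nrmse` (percent, or
#'   `NA` with `nrmse_reason` when the observations are constant), `n`,
#'   and `r2_pearson` (squared correlation, audit).
#' @export
compute_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ",
                                        call. = FALSE)
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  n <- length(obs)
  if (n < 2L) stop("need at least 2 valid obs/pred pairs", call. = FALSE)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  rmse <- sqrt(mean((obs - pred)^2))
  rng <- diff(range(obs))
  out <- list(
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = rmse,
    nrmse = if (rng > 0) 100 * rmse / rng else NA_real_,
    n = n,
    r2_pearson = if (ss_tot > 0 && stats::sd(pred) > 0)
      stats::cor(obs, pred)^2 else NA_real_
  )
  if (rng == 0) out$nrmse_reason <- "observations constant: range is zero"
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 = %.4f  rmse = %.4f  nrmse = %s%%  (n = %d)\n",
              x$r2, x$rmse,
              if (is.na(x$nrmse)) "NA" else sprintf("%.2f", x$nrmse), x$n))
  invisible(x)
}

#' Balanced (optionally stratified) k-fold plan
#'
#' Partitions `n` samples into `k` folds whose sizes differ by at most one.
#' With a stratification key, each stratum is split in balanced rotation so
#' class proportions are preserved per fold within rounding.
#'
#' @param n Sample count.
#' @param k Fold count (`k <= n`).
#' @param seed Integer seed.
#' @param strat_key Optional length-n vector (e.g. vegetation class);
#'   `NULL` for a plain random partition.
#' @return List of class `fold_plan`: `k`, `assignment` (length-n fold
#'   index in 1..k), `seed`, `stratified`.
#' @export
make_folds <- function(n, k, seed = 1L, strat_key = NULL) {
  if (k > n) stop(sprintf("k = %d exceeds n = %d", k, n), call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  set.seed(seed)
  assignment <- integer(n)
  if (is.null(strat_key)) {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    assignment <- sample(rep.int(seq_len(k), sizes))
  } else {
    if (length(strat_key) != n) stop("strat_key length != n", call. = FALSE)
    # rotate fold labels across strata so fold sizes stay balanced globally
    offset <- 0L
    for (g in split(seq_len(n), strat_key)) {
      m <- length(g)
      lab <- ((offset + seq_len(m) - 1L) %% k) + 1L
      assignment[sample(g)] <- lab
      offset <- (offset + m) %% k
    }
  }
  structure(list(k = k, assignment = assignment, seed = seed,
                 stratified = !is.null(strat_key)),
            class = "fold_plan")
}

#' Assemble per-flux training data from tower records
#'
#' Keeps only site-days where all D predictors and the target flux are
#' present, finite, and inside the schema ranges. Sub-daily rows (multiple
#' rows per site-day) are averaged to daily means before filtering. An
#' audit of kept/dropped counts per rule accompanies the result.
#'
#' @param records A `tower_table` data.frame (see [read_tower_table()]).
#' @param target One of [flux_variables()].
#' @param schema A [predictor_schema()].
#' @return A `training_matrix` with extra fields `vegetation_class`,
#'   `site_id`, `date` (per kept row) and attribute-style field `audit`
#'   (list of counts per drop rule).
#' @export
assemble_training_table <- function(records, target = "GPP",
                                    schema = predictor_schema()) {
  assert_schema(schema)
  target <- match.arg(target, flux_variables())
  df <- as.data.frame(records)
  if (!target %in% names(df))
    stop("records contain no ", target, " column", call. = FALSE)

  # average sub-daily rows to daily means
  key <- interaction(df$site_id, df$date, drop = TRUE)
  n_subdaily <- nrow(df) - length(levels(key))
  if (n_subdaily > 0) {
    num_cols <- intersect(c(schema$name, flux_variables()), names(df))
    agg <- stats::aggregate(df[num_cols], by = list(key = key), FUN = mean,
                            na.rm = FALSE)
    meta <- df[match(agg$key, key), c("site_id", "date", "vegetation_class")]
    df <- cbind(meta, agg[num_cols])
    rownames(df) <- NULL
  }

  audit <- list(n_input = nrow(df), n_subdaily_rows_averaged = n_subdaily,
                dropped = list())
  keep <- rep(TRUE, nrow(df))
  for (cn in schema$name) {
    bad <- !is.finite(df[[cn]])
    nb <- sum(bad & keep)
    if (nb > 0) audit$dropped[[paste0("missing predictor ", cn)]] <- nb
    keep <- keep & !bad
  }
  for (k in seq_len(nrow(schema))) {
    cn <- schema$name[k]
    v <- df[[cn]]
    oob <- is.finite(v) & (v < schema$valid_min[k] | v > schema$valid_max[k])
    nb <- sum(oob & keep)
    if (nb > 0) audit$dropped[[paste0("out-of-range ", cn)]] <- nb
    keep <- keep & !oob
  }
  bad_t <- !is.finite(df[[target]])
  nb <- sum(bad_t & keep)
  if (nb > 0) audit$dropped[[paste0("missing target ", target)]] <- nb
  keep <- keep & !bad_t
  audit$n_kept <- sum(keep)

  if (sum(keep) < 10L)
    stop(sprintf("only %d rows survive filtering; at least 10 needed for CV",
                 sum(keep)), call. = FALSE)
  df <- df[keep, , drop = FALSE]
  X <- as.matrix(df[schema$name])
  tm <- training_matrix(X, df[[target]], flux_variable = target)
  tm$vegetation_class <- df$vegetation_class
  tm$site_id <- df$site_id
  tm$date <- df$date
  tm$audit <- audit
  tm
}

#' k-fold cross-validation of a GP flux model
#'
#' For each fold, fits the model on the out-of-fold rows and predicts the
#' held-out rows; metrics are computed per fold and on the pooled held-out
#' predictions. The pooled observation/prediction pairs are returned for
#' scatterplots.
#'
#' @param table A `training_matrix` (typically from
#'   [assemble_training_table()]).
#' @param plan A `fold_plan` matching `table$n`; or `NULL` to build one
#'   (stratified by vegetation class when available).
#' @param k,seed Used only when `plan` is `NULL`.
#' @param ... Passed to [gpr_fit()] (`restarts`, `maxit`, ...).
#' @return List of class `cv_result`: `pooled` (`metric_set`), `per_fold`
#'   (list of `metric_set`), `pairs` (data.frame obs/pred/fold),
#'   `by_class` (per-vegetation-class `metric_set`s when classes are
#'   known), `plan`, and the assembly `audit` if present.
#' @export
cross_validate <- function(table, plan = NULL, k = 10L, seed = 1L, ...) {
  stopifnot(inherits(table, "training_matrix"))
  if (is.null(plan))
    plan <- make_folds(table$n, k, seed = seed,
                       strat_key = table$vegetation_class)
  if (length(plan$assignment) != table$n)
    stop("fold plan does not match table size", call. = FALSE)

  obs_raw <- table$y * table$y_scale + table$y_mean
  X_raw <- sweep(sweep(table$X, 2, table$x_scale, "*"), 2, table$x_mean, "+")
  pred <- rep(NA_real_, table$n)
  per_fold <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    ho <- plan$assignment == f
    tm_f <- training_matrix(X_raw[!ho, , drop = FALSE], obs_raw[!ho],
                            flux_variable = table$flux_variable)
    fit <- tryCatch(gpr_fit(tm_f, seed = seed + f, ...),
                    error = function(e)
                      stop(sprintf("fold %d fit failed: %s", f,
                                   conditionMessage(e)), call. = FALSE))
    pr <- predict(fit, X_raw[ho, , drop = FALSE])
    pred[ho] <- pr$mean
    per_fold[[f]] <- compute_metrics(obs_raw[ho], pred[ho])
  }
  pairs <- data.frame(obs = obs_raw, pred = pred, fold = plan$assignment)
  by_class <- NULL
  if (!is.null(table$vegetation_class) &&
      !all(is.na(table$vegetation_class))) {
    pairs$vegetation_class <- table$vegetation_class
    cls <- split(pairs, pairs$vegetation_class)
    by_class <- lapply(cls[vapply(cls, nrow, 0L) >= 2],
                       function(d) compute_metrics(d$obs, d$pred))
  }
  structure(list(pooled = compute_metrics(obs_raw, pred),
                 per_fold = per_fold, pairs = pairs, by_class = by_class,
                 plan = plan, audit = table$audit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, n = %d\npooled: ",
              x$plan$k, nrow(x$pairs)))
  print(x$pooled)
  invisible(x)
}
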
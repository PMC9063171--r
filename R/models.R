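#' Aggregate a per-grain table to one sample measurement
#'
#' The analysis unit is the sample (one image): every numeric descriptor
#' and index column is averaged arithmetically over grains, and the mean
#' grain weight is the sample weight divided by the grain count.
#'
#' @param grains per-grain data.frame (e.g. from [measure_image()]).
#' @param sample_weight total sample weight in mg (optional; without it the
#'   sample is emitted with `mgw` unset).
#' @param sample_id sample identifier.
#' @return object of class `sample_measurement`: list with `sample_id`,
#'   `grain_count`, `means` (one-row data.frame), `sample_weight`, `mgw`.
#' @export
aggregate_sample <- function(grains, sample_weight = NULL, sample_id = "sample") {
  stopifnot(is.data.frame(grains))
  if (nrow(grains) < 1) stop("need at least one grain row")
  num <- vapply(grains, is.numeric, logical(1))
  cols <- setdiff(names(grains)[num], "Label")
  means <- as.data.frame(as.list(colMeans(grains[cols])), check.names = FALSE)
  n <- nrow(grains)
  mgw <- if (is.null(sample_weight)) NA_real_ else sample_weight / n
  structure(
    list(sample_id = sample_id, grain_count = n, means = means,
         sample_weight = if (is.null(sample_weight)) NA_real_ else sample_weight,
         mgw = mgw),
    class = "sample_measurement"
  )
}

#' Build a per-sample analysis table
#'
#' Combines sample measurements into one data.frame with the mean basic
#' descriptors, the index catalogue evaluated on those means (index of
#' means, the paper-style analysis basis), grain counts and MGW; extra
#' per-sample columns (e.g. grouping factors) can be supplied.
#'
#' @param samples list of `sample_measurement` objects.
#' @param unit_system passed to [compute_catalogue()].
#' @param extra optional data.frame of per-sample columns (same order).
#' @return data.frame, one row per sample, with `sample_id`,
#'   `grain_count`, `MGW`, catalogue index columns and any extras.
#' @export
sample_table <- function(samples, unit_system = c("pixel", "mm"), extra = NULL) {
  unit_system <- match.arg(unit_system)
  stopifnot(length(samples) >= 1)
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "sample_measurement"))
    idx <- compute_catalogue(s$means, unit_system = unit_system)
    cbind(data.frame(sample_id = s$sample_id, grain_count = s$grain_count,
                     sample_weight = s$sample_weight, MGW = s$mgw,
                     stringsAsFactors = FALSE),
          idx)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Fit a linear MGW model on one index
#'
#' Ordinary least squares `MGW = slope * index + intercept`, with R^2 and
#' the population-form RMSE (`sqrt(mean(residual^2))`) over all samples.
#'
#' @param samples per-sample data.frame (see [sample_table()]).
#' @param index_name name of the predictor column.
#' @param mgw_col name of the MGW column.
#' @param unit_system label recorded with the model (`"original-pixel"`,
#'   `"enhanced-pixel"`, `"SI"`, or free text).
#' @return object of class `grain_weight_model`: list with `index_name`,
#'   `slope`, `intercept`, `r2`, `rmse`, `n`, `unit_system`.
#' @export
fit_linear <- function(samples, index_name, mgw_col = "MGW",
                       unit_system = "unspecified") {
  stopifnot(is.data.frame(samples), index_name %in% names(samples),
            mgw_col %in% names(samples))
  ok <- is.finite(samples[[index_name]]) & is.finite(samples[[mgw_col]])
  x <- samples[[index_name]][ok]
  y <- samples[[mgw_col]][ok]
  if (length(x) < 3) stop("need >= 3 samples with MGW to fit a model")
  if (stats::sd(x) == 0) stop("index '", index_name, "' has zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  # summary.lm warns on noiseless data; the (zero) SEs are still valid
  fit_summary <- suppressWarnings(summary(fit))
  structure(
    list(index_name = index_name, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), r2 = r2,
         rmse = sqrt(mean(res^2)), n = length(x),
         unit_system = unit_system,
         slope_se = fit_summary$coefficients[2, 2],
         intercept_se = fit_summary$coefficients[1, 2]),
    class = "grain_weight_model"
  )
}

#' @export
print.grain_weight_model <- function(x, ...) {
  cat(sprintf("<grain_weight_model> MGW = %.6g * [%s] %+.6g  (%s units)\n",
              x$slope, x$index_name, x$intercept, x$unit_system))
  cat(sprintf("  n = %d, R^2 = %.4f, RMSE = %.4f mg\n", x$n, x$r2, x$rmse))
  invisible(x)
}

#' Predict MGW from a fitted or published model
#'
#' @param object a `grain_weight_model`.
#' @param newdata numeric vector of index values, or a data.frame holding
#'   the model's index column.
#' @param ... unused.
#' @return predicted MGW in mg.
#' @export
predict.grain_weight_model <- function(object, newdata, ...) {
  v <- if (is.data.frame(newdata)) newdata[[object$index_name]] else newdata
  object$slope * v + object$intercept
}

#' k-fold cross-validation of a linear MGW model
#'
#' Samples are shuffled once with a recorded seed and split into `k`
#' near-equal folds; for each fold the model is fitted on the remaining
#' samples and the RMSE (population form) is computed on the held-out fold.
#'
#' @inheritParams fit_linear
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed for the fold-assignment permutation.
#' @return list with `rmse_mean`, `rmse_sd` (across folds), `fold_rmse`,
#'   `models` (per-fold `grain_weight_model`s), `k`, `seed`.
#' @export
kfold_cv <- function(samples, index_name, k = 10, seed = 1, mgw_col = "MGW",
                     unit_system = "unspecified") {
  stopifnot(is.data.frame(samples))
  n <- nrow(samples)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  perm <- withr::with_seed(seed, sample.int(n))
  fold_of <- rep_len(seq_len(k), n)[order(perm)]  # near-equal fold sizes
  fold_rmse <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_of == f
    m <- fit_linear(samples[!test, , drop = FALSE], index_name,
                    mgw_col = mgw_col, unit_system = unit_system)
    pred <- predict(m, samples[test, , drop = FALSE])
    fold_rmse[f] <- sqrt(mean((samples[[mgw_col]][test] - pred)^2))
    models[[f]] <- m
  }
  list(rmse_mean = mean(fold_rmse), rmse_sd = stats::sd(fold_rmse),
       fold_rmse = fold_rmse, models = models, k = k, seed = seed,
       fold_sizes = tabulate(fold_of, k))
}

#' Published reference model coefficients
#'
#' The reference slope/intercept table of the twelve retained indices at
#' the three measurement scales (`original-pixel`, `enhanced-pixel`, `SI`),
#' shipped as a versioned CSV asset, together with the reported R^2 and
#' RMSE of each model.
#'
#' @return data.frame with columns `index`, `unit_system`, `slope`,
#'   `intercept`, `r2`, `rmse`.
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.csv",
                      package = "grainmetry", mustWork = TRUE)
  read_table(path)
}

#' Predict MGW with published coefficients
#'
#' `slope * value + intercept` using the reference coefficient table; the
#' index value must be expressed in the chosen unit system (mm / mm^2 for
#' `"SI"`, raw pixels at original or 10x-enhanced resolution otherwise).
#'
#' @param value numeric index value(s).
#' @param index_name one of the twelve retained indices (see
#'   [catalogue_names()] with `selected = TRUE`).
#' @param unit_system `"SI"`, `"original-pixel"` or `"enhanced-pixel"`.
#' @param coeffs coefficient table, by default [published_coefficients()].
#' @return predicted MGW in mg.
#' @export
predict_published <- function(value, index_name, unit_system = "SI",
                              coeffs = published_coefficients()) {
  row <- coeffs[coeffs$index == index_name & coeffs$unit_system == unit_system, ]
  if (nrow(row) != 1) {
    stop("no published coefficients for ('", index_name, "', '", unit_system,
         "'); available: ",
         paste(sprintf("('%s', '%s')", coeffs$index, coeffs$unit_system),
               collapse = ", "))
  }
  row$slope * value + row$intercept
}

#' Per-group correlation report of indices against MGW
#'
#' Pearson R of each retained index against MGW, overall and within each
#' level combination of the grouping columns (e.g. year and irrigation).
#' Groups with fewer than 3 samples are skipped with a warning.
#'
#' @param samples per-sample data.frame.
#' @param group_cols character vector of grouping column names (optional).
#' @param indices index columns to report (default: the twelve retained
#'   indices present in `samples`).
#' @param mgw_col name of the MGW column.
#' @return data.frame with one row per index: `index`, `Overall`, and one
#'   column per group.
#' @export
correlation_report <- function(samples, group_cols = NULL, indices = NULL,
                               mgw_col = "MGW") {
  stopifnot(is.data.frame(samples), mgw_col %in% names(samples))
  if (is.null(indices)) {
    indices <- intersect(catalogue_names(selected = TRUE), names(samples))
  }
  stopifnot(all(indices %in% names(samples)))
  if (nrow(samples) < 3) stop("need >= 3 samples")
  corr_of <- function(df) {
    vapply(indices, function(nm) {
      v <- df[[nm]]
      if (stats::sd(v) == 0) return(NA_real_)
      stats::cor(v, df[[mgw_col]])
    }, numeric(1))
  }
  out <- data.frame(index = indices, Overall = unname(corr_of(samples)),
                    stringsAsFactors = FALSE)
  if (!is.null(group_cols)) {
    key <- interaction(samples[group_cols], drop = TRUE, sep = ":")
    for (g in levels(key)) {
      sub <- samples[key == g, , drop = FALSE]
      if (nrow(sub) < 3) {
        warning("group '", g, "' has fewer than 3 samples; skipped")
        next
      }
      out[[g]] <- unname(corr_of(sub))
    }
  }
  out
}

#' Percent difference relative to a reference value
#'
#' `100 * (reference - value) / reference`: the percent reduction from
#' `reference` to `value`, the form used to report treatment effects on
#' MGW and grain dimensions.
#'
#' @param reference reference (e.g. well-watered or first-year mean).
#' @param value comparison value.
#' @return percent difference.
#' @export
percent_difference <- function(reference, value) {
  100 * (reference - value) / reference
}
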
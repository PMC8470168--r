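#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2).
#' Can be negative when predictions are worse than the constant mean.
#'
#' @param reported observed fiber values (g); must not be all identical.
#' @param predicted predicted fiber values (g), same length.
#' @return scalar <= 1.
#' @export
r_squared <- function(reported, predicted) {
  check_pairs(reported, predicted, min_n = 2L)
  ss_tot <- sum((reported - mean(reported))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: all reported values identical", call. = FALSE)
  }
  1 - sum((reported - predicted)^2) / ss_tot
}

#' Mean absolute error
#'
#' @param reported,predicted equal-length numeric vectors (g).
#' @return non-negative scalar (g).
#' @export
mae <- function(reported, predicted) {
  check_pairs(reported, predicted, min_n = 1L)
  mean(abs(reported - predicted))
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @param reported,predicted equal-length numeric vectors (length >= 2);
#'   each must have non-zero rank variance.
#' @return scalar in \[-1, 1\].
#' @export
spearman_rho <- function(reported, predicted) {
  check_pairs(reported, predicted, min_n = 2L)
  rx <- rank(reported); ry <- rank(predicted)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("Spearman rho undefined: zero rank variance", call. = FALSE)
  }
  stats::cor(rx, ry)
}

check_pairs <- function(reported, predicted, min_n) {
  if (length(reported) != length(predicted)) {
    stop("reported and predicted differ in length", call. = FALSE)
  }
  if (length(reported) < min_n) {
    stop("need at least ", min_n, " value pair(s)", call. = FALSE)
  }
  if (anyNA(reported) || anyNA(predicted)) {
    stop("missing values in inputs", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fiber density classes
#'
#' Cut-offs at 0.9, 3.7 and 7.3 g per 100 g or 100 mL follow the fiber
#' component of the nutrient profiling criteria behind the Australian
#' Health Star Rating (0, 1-3, 4-7, and 8-15 fiber points respectively).
#' Intervals are lower-inclusive: \[0, 0.9) negligible, \[0.9, 3.7) low,
#' \[3.7, 7.3) medium, \[7.3, Inf) high.
#'
#' @param fiber numeric vector of fiber densities (g per 100 g or 100 mL,
#'   >= 0).
#' @return ordered factor with levels
#'   `negligible < low < medium < high`.
#' @export
#' @examples
#' classify_density(c(0.6, 2, 3.7, 8.8))
classify_density <- function(fiber) {
  stopifnot(is.numeric(fiber))
  if (anyNA(fiber)) stop("missing fiber values", call. = FALSE)
  if (any(fiber < 0)) stop("negative fiber value", call. = FALSE)
  cut(fiber, breaks = c(0, density_bounds(), Inf), right = FALSE,
      labels = density_levels(), ordered_result = TRUE)
}

#' @rdname classify_density
#' @export
density_bounds <- function() c(negligible_low = 0.9, low_medium = 3.7,
                               medium_high = 7.3)

density_levels <- function() c("negligible", "low", "medium", "high")

#' Classification metrics for fiber density classes
#'
#' Classification accuracy (fraction exactly correct), per-class precision
#' TP/(TP+FP) and recall TP/(TP+FN), and the 4x4 confusion matrix. A class
#' with an empty denominator gets `NA` (undefined), never 0, so averages
#' are not silently deflated.
#'
#' @param true_classes,predicted_classes equal-length vectors of density
#'   class labels (character or factor with levels among
#'   `negligible, low, medium, high`).
#' @return list with `accuracy`, `precision` and `recall` (named numeric,
#'   one entry per class), and `confusion` (4x4 matrix, truth in rows).
#' @export
classification_metrics <- function(true_classes, predicted_classes) {
  lv <- density_levels()
  tc <- factor(as.character(true_classes), levels = lv)
  pc <- factor(as.character(predicted_classes), levels = lv)
  if (length(tc) != length(pc) || length(tc) < 1L) {
    stop("class vectors must be non-empty and of equal length", call. = FALSE)
  }
  if (anyNA(tc) || anyNA(pc)) {
    stop("labels outside the density class set", call. = FALSE)
  }
  confusion <- table(truth = tc, predicted = pc)
  tp <- diag(confusion)
  col_tot <- colSums(confusion)  # TP + FP
  row_tot <- rowSums(confusion)  # TP + FN
  precision <- ifelse(col_tot > 0, tp / col_tot, NA_real_)
  recall <- ifelse(row_tot > 0, tp / row_tot, NA_real_)
  list(accuracy = sum(tp) / sum(confusion),
       precision = setNames(as.numeric(precision), lv),
       recall = setNames(as.numeric(recall), lv),
       confusion = unclass(confusion))
}

#' Regression + classification metrics for one evaluation scope
#'
#' Bundles R-squared, MAE and Spearman rho (and, optionally, the fiber
#' density classification block) for a set of (reported, predicted) pairs.
#'
#' @param reported,predicted equal-length numeric vectors (g).
#' @param scope free-text label (`"overall"`, a category name, a d1
#'   quartile, ...).
#' @param classify also compute the density classification block?
#' @return A `metrics_report` list: `scope`, `n`, `r_squared`, `mae`,
#'   `spearman_rho`, and optionally `classification`.
#' @export
metrics_report <- function(reported, predicted, scope = "overall",
                           classify = TRUE) {
  check_pairs(reported, predicted, min_n = 2L)
  out <- list(scope = scope, n = length(reported),
              r_squared = r_squared(reported, predicted),
              mae = mae(reported, predicted),
              spearman_rho = spearman_rho(reported, predicted))
  if (classify) {
    out$classification <- classification_metrics(
      classify_density(reported), classify_density(predicted))
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (n = %d)\n", x$scope, x$n))
  cat(sprintf("  R2 = %.3f  MAE = %.3f g  rho = %.3f\n",
              x$r_squared, x$mae, x$spearman_rho))
  if (!is.null(x$classification)) {
    cat(sprintf("  density classification accuracy = %.3f\n",
                x$classification$accuracy))
  }
  invisible(x)
}

#' Stratify evaluation by first-neighbor distance quartile
#'
#' The distance to the nearest neighbor (d1) is a confidence proxy:
#' queries far from every training product rest on weak evidence.
#' Predictions are split at the 25th/50th/75th percentiles of their d1
#' values (linear-interpolation percentiles, lower-inclusive edges) and a
#' [metrics_report()] is computed per quartile.
#'
#' @param predictions a `fiber_predictions` data.frame that additionally
#'   carries a `reported` column (the label fiber of the scored queries),
#'   or any data.frame with columns `reported`, `predicted_fiber`, `d1`.
#'   At least 4 rows.
#' @param classify passed to [metrics_report()].
#' @return named list of 4 `metrics_report`s (`d1_q1` .. `d1_q4`), each
#'   with a `d1_range` attribute.
#' @export
stratify_by_d1 <- function(predictions, classify = FALSE) {
  stopifnot(is.data.frame(predictions),
            all(c("reported", "predicted_fiber", "d1") %in% names(predictions)))
  if (nrow(predictions) < 4L) {
    stop("need at least 4 scored predictions", call. = FALSE)
  }
  edges <- pctl(predictions$d1, c(0.25, 0.5, 0.75))
  grp <- cut(predictions$d1, breaks = c(-Inf, edges, Inf), right = FALSE,
             labels = paste0("d1_q", 1:4))
  out <- lapply(levels(grp), function(g) {
    rows <- predictions[grp == g, , drop = FALSE]
    rep_g <- metrics_report(rows$reported, rows$predicted_fiber, scope = g,
                            classify = classify)
    attr(rep_g, "d1_range") <- range(rows$d1)
    rep_g
  })
  setNames(out, levels(grp))
}

#' Compare fiber of reporting vs non-reporting products
#'
#' Two-sided rank-based comparison of two independent groups (reported
#' label values vs predicted values of non-reporting products): the
#' Mann-Whitney/Wilcoxon rank-sum test. For small samples
#' (min(n1, n2) <= 8) without ties the p-value is exact (full
#' enumeration); otherwise the large-sample normal approximation with tie
#' correction is used. Being rank-based, the statistic is invariant under
#' any common strictly increasing transform of all values.
#'
#' @param reported_fibers fiber values of reporting products (g).
#' @param predicted_fibers fiber values predicted for non-reporting
#'   products (g).
#' @return list with `statistic` (the rank-sum U statistic), `p_value`,
#'   and `method`.
#' @export
compare_reporting_groups <- function(reported_fibers, predicted_fibers) {
  if (length(reported_fibers) == 0L || length(predicted_fibers) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(reported_fibers, predicted_fibers)
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- !has_ties &&
    min(length(reported_fibers), length(predicted_fibers)) <= 8L
  ht <- suppressWarnings(
    stats::wilcox.test(reported_fibers, predicted_fibers,
                       alternative = "two.sided", exact = use_exact,
                       correct = FALSE))
  list(statistic = unname(ht$statistic),
       p_value = min(ht$p.value, 1),
       method = if (use_exact) "rank-sum (exact)" else
         "rank-sum (normal approximation, tie-corrected)")
}

#' Supply-level fiber summary
#'
#' The headline product of the pipeline: per category and overall, how
#' many products report fiber (and what share that is), the median and
#' IQR of reported fiber, the median and IQR of *predicted* fiber for
#' non-reporting products, and the pooled (reported + predicted)
#' median/IQR. A rank-sum comparison of the reported vs predicted groups
#' ([compare_reporting_groups()]) is attached, quantifying reporting bias.
#'
#' Products whose category is absent from the model cannot be predicted;
#' they stay in the counts but are excluded from the predicted and pooled
#' values, with a warning.
#'
#' @param table a [product_table()] after exclusions; mixture of
#'   fiber-reporting and non-reporting records.
#' @param model a fitted `fiber_knn`.
#' @return A `supply_summary`: data.frame with one row per category plus a
#'   `"Total"` row (columns `category`, `n_total`, `n_reporting`,
#'   `pct_reporting`, `median_reported`, `iqr_reported`,
#'   `n_nonreporting`, `n_predicted`, `median_predicted`,
#'   `iqr_predicted`, `median_all`, `iqr_all`); the comparison test is in
#'   `attr(, "comparison")`.
#' @export
supply_summary <- function(table, model) {
  stopifnot(inherits(table, "product_table"), inherits(model, "fiber_knn"))
  if (nrow(table) == 0L) stop("empty product table", call. = FALSE)
  reporting <- !is.na(table$fiber)
  predictable <- table$category %in% names(model$stores)
  n_unpredictable <- sum(!reporting & !predictable)
  if (n_unpredictable > 0L) {
    warning(n_unpredictable, " non-reporting product(s) in categories ",
            "unknown to the model; excluded from predicted summaries",
            call. = FALSE)
  }
  to_predict <- table[!reporting & predictable, , drop = FALSE]
  preds <- if (nrow(to_predict)) predict(model, to_predict) else NULL
  pred_by_cat <- if (!is.null(preds)) {
    split(preds$predicted_fiber, preds$category)
  } else {
    list()
  }
  one_row <- function(label, rows_in, pred_vals) {
    rep_vals <- table$fiber[rows_in & reporting]
    mr <- med_iqr(rep_vals); mp <- med_iqr(pred_vals)
    ma <- med_iqr(c(rep_vals, pred_vals))
    data.frame(
      category = label,
      n_total = sum(rows_in),
      n_reporting = length(rep_vals),
      pct_reporting = 100 * length(rep_vals) / sum(rows_in),
      median_reported = mr[["median"]], iqr_reported = mr[["iqr"]],
      n_nonreporting = sum(rows_in) - length(rep_vals),
      n_predicted = length(pred_vals),
      median_predicted = mp[["median"]], iqr_predicted = mp[["iqr"]],
      median_all = ma[["median"]], iqr_all = ma[["iqr"]],
      stringsAsFactors = FALSE)
  }
  cats <- unique(table$category)
  rows <- lapply(cats, function(ct) {
    one_row(ct, table$category == ct, pred_by_cat[[ct]])
  })
  all_pred <- if (!is.null(preds)) preds$predicted_fiber else numeric(0)
  out <- do.call(rbind, c(rows, list(one_row("Total", rep(TRUE, nrow(table)),
                                             all_pred))))
  comparison <- if (any(reporting) && length(all_pred)) {
    compare_reporting_groups(table$fiber[reporting], all_pred)
  } else {
    NULL
  }
  structure(out, class = c("supply_summary", "data.frame"),
            comparison = comparison)
}

#' @export
print.supply_summary <- function(x, ...) {
  cat("<supply_summary>\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) {
    cat(sprintf("reported vs predicted-for-nonreporting: %s, U = %.1f, p = %.3g\n",
                cmp$method, cmp$statistic, cmp$p_value))
  }
  invisible(x)
}

#' Write a metrics report (or list of reports) to JSON
#'
#' @param x a `metrics_report`, or a named list of them.
#' @param path output path.
#' @param meta optional named list recorded under `"meta"`.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(x, path, meta = NULL) {
  unpack <- function(r) {
    stopifnot(inherits(r, "metrics_report"))
    out <- unclass(r)
    if (!is.null(out$classification)) {
      out$classification$confusion <-
        as.data.frame.matrix(out$classification$confusion)
    }
    out
  }
  doc <- if (inherits(x, "metrics_report")) unpack(x) else lapply(x, unpack)
  if (!is.null(meta)) doc <- c(list(meta = meta), list(reports = doc))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a supply summary to CSV
#'
#' @param x a `supply_summary`.
#' @param path output path.
#' @param header_lines optional `#` metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_supply_summary <- function(x, path, header_lines = NULL) {
  stopifnot(inherits(x, "supply_summary"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) {
    header_lines <- c(header_lines,
                      sprintf("group comparison: %s, statistic = %s, p = %s",
                              cmp$method, format(cmp$statistic),
                              format(cmp$p_value)))
  }
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, na = "")
  invisible(path)
}
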
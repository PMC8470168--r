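#' Brand-grouped train/test split
#'
#' Product variants sharing a brand (all "Pringles" flavors, say) are
#' near-identical formulations; splitting them across train and test would
#' leak answers into the test set. All products of a brand therefore
#' travel together: brands are shuffled with the given seed and the first
#' ceiling(`train_fraction` * B) of them (B = number of brands) form the
#' training set.
#'
#' @param table a [product_table()]; every record must report fiber (the
#'   split operates on the fiber-reporting subset) and carry a brand.
#' @param train_fraction fraction of brands allocated to training;
#'   default 0.75.
#' @param seed integer RNG seed; the split is deterministic given the seed
#'   and does not disturb the caller's RNG stream.
#' @return list with `train` and `test` product tables.
#' @export
brand_grouped_split <- function(table, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(table, "product_table"),
            is.numeric(train_fraction), length(train_fraction) == 1L,
            train_fraction > 0, train_fraction < 1)
  if (anyNA(table$fiber)) {
    stop("all records must report fiber before splitting; filter first",
         call. = FALSE)
  }
  if (anyNA(table$brand)) stop("records without brand", call. = FALSE)
  brands <- unique(table$brand)
  if (length(brands) < 2L) {
    stop("need at least 2 brands to split", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(brands))
  n_train <- ceiling(train_fraction * length(brands))
  train_brands <- shuffled[seq_len(n_train)]
  list(train = table[table$brand %in% train_brands, , drop = FALSE],
       test = table[!table$brand %in% train_brands, , drop = FALSE])
}

#' Hyperparameter grid
#'
#' The default grid spans the dimensions worth exploring for this model:
#' both distance metrics, both weighting schemes, and k from 1 to 20.
#'
#' @param k integer vector of neighbor counts.
#' @param metric character vector of metrics.
#' @param weighting character vector of weighting schemes.
#' @return data.frame with columns `metric`, `weighting`, `k`, one row per
#'   configuration.
#' @export
default_hyper_grid <- function(k = 1:20,
                               metric = c("manhattan", "euclidean"),
                               weighting = c("inverse", "uniform")) {
  expand.grid(metric = metric, weighting = weighting, k = as.integer(k),
              stringsAsFactors = FALSE)
}

# Prediction from a pre-sorted neighbor row (distances ascending, NA
# padding past the store size).
predict_from_sorted <- function(dist_row, fiber_row, k, weighting) {
  n_avail <- sum(!is.na(dist_row))
  ke <- min(k, n_avail)
  d <- dist_row[seq_len(ke)]
  w <- neighbor_weights(d, weighting)
  sum(w * fiber_row[seq_len(ke)]) / sum(w)
}

#' Five-fold cross-validated grid search
#'
#' Training products are shuffled with `seed` and dealt into `folds`
#' near-equal folds at the product level. For every configuration and
#' fold, the model (including its normalization parameters, refit
#' out-of-fold to avoid leakage) is trained on the other folds and scored
#' by R-squared on the held-out fold. Held-out products whose category has
#' no training product in the fold are skipped with a warning; a fold with
#' nothing predictable records a missing score, excluded from the mean.
#'
#' @param train a [product_table()] with fiber present for every record.
#' @param grid configuration data.frame from [default_hyper_grid()].
#' @param folds number of folds (>= 2); default 5.
#' @param seed integer RNG seed.
#' @return A `cv_result`: data.frame with columns `metric`, `weighting`,
#'   `k`, `mean_r2`, and a `fold_r2` list-column, sorted by descending
#'   `mean_r2`; attributes `folds` and `seed`.
#' @export
kfold_cv <- function(train, grid = default_hyper_grid(), folds = 5L,
                     seed = 1L) {
  stopifnot(inherits(train, "product_table"), is.data.frame(grid),
            all(c("metric", "weighting", "k") %in% names(grid)),
            folds >= 2L)
  if (nrow(train) == 0L) stop("empty training table", call. = FALSE)
  if (anyNA(train$fiber)) {
    stop("all training records must report fiber", call. = FALSE)
  }
  n <- nrow(train)
  if (n < folds) stop("fewer products than folds", call. = FALSE)
  fold_id <- integer(n)
  fold_id[with_seed(seed, sample.int(n))] <- rep_len(seq_len(folds), n)
  kmax <- max(grid$k)
  metrics <- unique(grid$metric)
  scores <- matrix(NA_real_, nrow(grid), folds)

  for (f in seq_len(folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    raw_tr <- derive_features(tr)
    params <- fit_normalization(raw_tr)
    norm_tr <- normalize_features(raw_tr, params)
    norm_te <- normalize_features(derive_features(te), params)
    predictable <- te$category %in% unique(tr$category)
    if (!all(predictable)) {
      warning(sum(!predictable), " held-out product(s) in fold ", f,
              " have no same-category training product; skipped",
              call. = FALSE)
    }
    if (!any(predictable)) {
      warning("fold ", f, " has no predictable products; score missing",
              call. = FALSE)
      next
    }
    te_idx <- which(predictable)
    y <- te$fiber[te_idx]
    # Sorted neighbor distances/fibers once per metric; every (k,
    # weighting) combination then reads the same matrices.
    for (m in metrics) {
      nd <- matrix(NA_real_, length(te_idx), kmax)
      nf <- matrix(NA_real_, length(te_idx), kmax)
      for (ct in unique(te$category[te_idx])) {
        s_rows <- which(tr$category == ct)
        q_rows <- which(te$category[te_idx] == ct)
        dmat <- feature_distances(norm_te[te_idx[q_rows], , drop = FALSE],
                                  norm_tr[s_rows, , drop = FALSE], m)
        for (i in seq_along(q_rows)) {
          ord <- order(dmat[i, ], tr$product_id[s_rows])
          take <- seq_len(min(kmax, length(ord)))
          nd[q_rows[i], take] <- dmat[i, ord[take]]
          nf[q_rows[i], take] <- tr$fiber[s_rows][ord[take]]
        }
      }
      for (g in which(grid$metric == m)) {
        preds <- vapply(seq_len(nrow(nd)), function(i) {
          predict_from_sorted(nd[i, ], nf[i, ], grid$k[g], grid$weighting[g])
        }, numeric(1))
        scores[g, f] <- if (length(y) >= 2L && stats::var(y) > 0) {
          r_squared(y, preds)
        } else {
          NA_real_
        }
      }
    }
  }

  out <- grid[, c("metric", "weighting", "k")]
  out$mean_r2 <- rowMeans(scores, na.rm = TRUE)
  out$mean_r2[!is.finite(out$mean_r2)] <- NA_real_
  out$fold_r2 <- lapply(seq_len(nrow(scores)), function(i) scores[i, ])
  out <- out[order(-out$mean_r2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cv_result", "data.frame"),
            folds = as.integer(folds), seed = seed)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x), " configurations, ", attr(x, "folds"),
      " folds, seed ", attr(x, "seed"), "\n", sep = "")
  print(utils::head(as.data.frame(x)[, c("metric", "weighting", "k",
                                         "mean_r2")], 10L))
  invisible(x)
}

#' Select hyperparameters from a CV result
#'
#' Returns the configuration with the highest mean cross-validated
#' R-squared. Ties are broken toward simpler computation: smaller k first,
#' then Manhattan before Euclidean, then inverse before uniform weighting.
#'
#' @param cv a `cv_result` from [kfold_cv()].
#' @return A [knn_hyperparams()].
#' @export
select_hyperparameters <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  ok <- !is.na(cv$mean_r2)
  if (!any(ok)) stop("all CV scores missing", call. = FALSE)
  cand <- cv[ok, , drop = FALSE]
  ord <- order(-cand$mean_r2, cand$k,
               match(cand$metric, c("manhattan", "euclidean")),
               match(cand$weighting, c("inverse", "uniform")))
  best <- cand[ord[1L], ]
  knn_hyperparams(k = best$k, metric = best$metric,
                  weighting = best$weighting)
}

#' Write a CV result to CSV
#'
#' One row per configuration: metric, weighting, k, the per-fold
#' R-squared scores, and their mean.
#'
#' @param cv a `cv_result`.
#' @param path output path.
#' @param header_lines optional `#` metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path, header_lines = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  folds <- attr(cv, "folds")
  flat <- as.data.frame(cv)[, c("metric", "weighting", "k")]
  fold_mat <- do.call(rbind, cv$fold_r2)
  colnames(fold_mat) <- paste0("fold", seq_len(folds), "_r2")
  flat <- cbind(flat, fold_mat, mean_r2 = cv$mean_r2)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(flat, con, row.names = FALSE, na = "")
  invisible(path)
}
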
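#' KNN hyperparameters
#'
#' Defaults are eight neighbors, Manhattan distance, and inverse-distance
#' weighting: Manhattan and Euclidean perform similarly on this problem and
#' Manhattan is the cheaper of the two, while inverse weighting
#' consistently beats uniform weighting by emphasizing close neighbors.
#'
#' @param k positive integer number of neighbors.
#' @param metric `"manhattan"` (sum of absolute coordinate differences) or
#'   `"euclidean"`.
#' @param weighting `"inverse"` (w_j = 1/d_j) or `"uniform"`.
#' @return A `knn_hyperparams` object.
#' @export
knn_hyperparams <- function(k = 8L, metric = c("manhattan", "euclidean"),
                            weighting = c("inverse", "uniform")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k))
  structure(list(k = as.integer(k), metric = metric, weighting = weighting),
            class = "knn_hyperparams")
}

#' @export
print.knn_hyperparams <- function(x, ...) {
  cat(sprintf("<knn_hyperparams> k = %d, metric = %s, weighting = %s\n",
              x$k, x$metric, x$weighting))
  invisible(x)
}

#' Manhattan distance between two normalized feature vectors
#'
#' d(x, y) = sum_i |x_i - y_i|.
#'
#' @param x,y numeric vectors of equal length (the six normalized
#'   features).
#' @return non-negative scalar.
#' @export
#' @examples
#' manhattan_distance(c(0.1, 0.2, 0.3, 0.0, 0.5, 0.4),
#'                    c(0.2, 0.2, 0.1, 0.1, 0.5, 0.0))  # 0.8
manhattan_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("feature vectors differ in length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  sum(abs(x - y))
}

# All query-to-store distances for one category. Q and S are normalized
# feature matrices; returns an nrow(Q) x nrow(S) matrix.
feature_distances <- function(Q, S, metric) {
  d <- matrix(0, nrow(Q), nrow(S))
  if (metric == "manhattan") {
    for (j in seq_len(ncol(Q))) d <- d + abs(outer(Q[, j], S[, j], `-`))
  } else {
    for (j in seq_len(ncol(Q))) d <- d + outer(Q[, j], S[, j], `-`)^2
    d <- sqrt(d)
  }
  d
}

# Weighted neighbor average with the zero-distance rule: 1/0 is undefined,
# so when exact matches exist the prediction is their unweighted mean
# (weights 1 on exact matches, 0 elsewhere).
neighbor_weights <- function(d, weighting) {
  if (any(d == 0)) {
    as.numeric(d == 0)
  } else if (weighting == "inverse") {
    1 / d
  } else {
    rep(1, length(d))
  }
}

#' Fit a category-partitioned KNN fiber model
#'
#' Fits min-max normalization on the training features, normalizes, and
#' partitions the training products into per-category stores. The hard
#' partition is what guarantees that neighbors always share the query's
#' category: appending literal 0/1 category dummies to the feature vector
#' would add at most 2.0 to a cross-category Manhattan distance while the
#' nutrient part can differ by up to 6.0, so dummies alone cannot enforce
#' the same-category property -- the partition does.
#'
#' @param train a [product_table()]; every record must report fiber and
#'   have a unique `product_id`.
#' @param hyper a [knn_hyperparams()].
#' @param caution_threshold d1 (nearest-neighbor distance) above which a
#'   prediction is flagged as low-confidence; default 0.08 on the
#'   normalized 6-feature Manhattan scale.
#' @return A `fiber_knn` model.
#' @export
fit_fiber_knn <- function(train, hyper = knn_hyperparams(),
                          caution_threshold = 0.08) {
  stopifnot(inherits(train, "product_table"),
            inherits(hyper, "knn_hyperparams"),
            is.numeric(caution_threshold), caution_threshold >= 0)
  if (nrow(train) < 2L) stop("need at least 2 training products", call. = FALSE)
  no_fiber <- is.na(train$fiber)
  if (any(no_fiber)) {
    stop("training records without fiber: ",
         paste(utils::head(train$product_id[no_fiber], 5L), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(train$product_id)
  if (any(dup)) {
    stop("duplicated product_id in training data: ",
         paste(utils::head(unique(train$product_id[dup]), 5L), collapse = ", "),
         call. = FALSE)
  }
  raw <- derive_features(train)
  params <- fit_normalization(raw, fitted_on = attr(train, "provenance") %||% "training")
  norm <- normalize_features(raw, params)
  stores <- lapply(split(seq_len(nrow(train)), train$category), function(idx) {
    list(product_id = train$product_id[idx],
         features = norm[idx, , drop = FALSE],
         fiber = train$fiber[idx])
  })
  structure(
    list(params = params, stores = stores, hyper = hyper,
         caution_threshold = caution_threshold),
    class = "fiber_knn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fiber_knn <- function(x, ...) {
  sizes <- vapply(x$stores, function(s) length(s$fiber), integer(1))
  cat("<fiber_knn> ", sum(sizes), " training products in ", length(sizes),
      " category stores\n", sep = "")
  print(x$hyper)
  cat("caution threshold (d1):", x$caution_threshold, "\n")
  cat("stores:", paste(sprintf("%s (%d)", names(sizes), sizes),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Predict fiber content for query products
#'
#' For each query, the k nearest training products *in the query's own
#' category* are found (ties at the k-th position broken by ascending
#' neighbor `product_id`, so results are independent of input order), and
#' fiber is predicted as the inverse-distance weighted average of their
#' labeled fiber values, Q = sum(w_j q_j) / sum(w_j) with w_j = 1/d_j. A
#' query at distance exactly 0 from stored products receives the
#' unweighted mean of those exact matches. A query that is itself in the
#' store (same `product_id`) never uses itself as a neighbor. When a store
#' holds fewer than k products, all of them are used (`k_effective`).
#'
#' @param object a `fiber_knn` model.
#' @param newdata a [product_table()] of query products; fiber not
#'   required. Every query category must have a store in the model.
#' @param ... unused.
#' @return A `fiber_predictions` data.frame with columns `product_id`,
#'   `category`, `predicted_fiber`, `d1`, `k_effective`, `caution`, and a
#'   `neighbors` list-column of per-query data.frames
#'   `(neighbor_id, distance, weight, fiber)` sorted by distance.
#' @export
predict.fiber_knn <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "product_table"))
  unknown <- setdiff(unique(newdata$category), names(object$stores))
  if (length(unknown)) {
    stop("unknown categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), "; model knows: ",
         paste(names(object$stores), collapse = ", "), call. = FALSE)
  }
  raw <- derive_features(newdata)
  norm <- normalize_features(raw, object$params)
  k <- object$hyper$k
  n <- nrow(newdata)
  pred <- numeric(n); d1 <- numeric(n); keff <- integer(n)
  nbrs <- vector("list", n)
  for (ct in unique(newdata$category)) {
    store <- object$stores[[ct]]
    q_idx <- which(newdata$category == ct)
    dmat <- feature_distances(norm[q_idx, , drop = FALSE], store$features,
                              object$hyper$metric)
    for (i in seq_along(q_idx)) {
      row <- q_idx[i]
      d <- dmat[i, ]
      avail <- which(store$product_id != newdata$product_id[row])  # leave-self-out
      if (!length(avail)) {
        stop("no neighbors available for product ", newdata$product_id[row],
             " in category ", ct, call. = FALSE)
      }
      ord <- avail[order(d[avail], store$product_id[avail])]
      ke <- min(k, length(ord))
      sel <- ord[seq_len(ke)]
      w <- neighbor_weights(d[sel], object$hyper$weighting)
      pred[row] <- sum(w * store$fiber[sel]) / sum(w)
      d1[row] <- d[sel[1L]]
      keff[row] <- ke
      nbrs[[row]] <- data.frame(
        neighbor_id = store$product_id[sel],
        distance = d[sel],
        weight = w,
        fiber = store$fiber[sel],
        stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(
    product_id = newdata$product_id,
    category = newdata$category,
    predicted_fiber = pred,
    d1 = d1,
    k_effective = keff,
    caution = d1 > object$caution_threshold,
    stringsAsFactors = FALSE)
  out$neighbors <- nbrs
  class(out) <- c("fiber_predictions", "data.frame")
  out
}

#' Explain a prediction by its neighbors
#'
#' KNN is interpretable by construction: the products that produced a
#' prediction can be listed. Returns (and prints) each neighbor's id,
#' category, distance, weight share w_j / sum(w), and fiber value; exact
#' matches (distance 0) are marked.
#'
#' @param predictions a `fiber_predictions` object from
#'   [predict.fiber_knn()].
#' @param product_id which query to explain (defaults to the first row).
#' @return data.frame of the neighbor report, invisibly.
#' @export
explain <- function(predictions, product_id = NULL) {
  stopifnot(inherits(predictions, "fiber_predictions"))
  if (is.null(product_id)) product_id <- predictions$product_id[1L]
  row <- match(product_id, predictions$product_id)
  if (is.na(row)) stop("no prediction for product ", product_id, call. = FALSE)
  nb <- predictions$neighbors[[row]]
  nb$category <- predictions$category[row]
  nb$weight_share <- nb$weight / sum(nb$weight)
  nb$exact_match <- nb$distance == 0
  nb <- nb[, c("neighbor_id", "category", "distance", "weight_share",
               "fiber", "exact_match")]
  cat(sprintf("prediction for %s: %.4g g fiber per 100 g/mL (d1 = %.4g%s)\n",
              product_id, predictions$predicted_fiber[row],
              predictions$d1[row],
              if (predictions$caution[row]) ", CAUTION: distant neighbor" else ""))
  print(nb, row.names = FALSE, digits = 4)
  invisible(nb)
}

#' Write predictions to CSV
#'
#' @param predictions a `fiber_predictions` object.
#' @param path output path.
#' @param header_lines optional `#` metadata comment lines.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, header_lines = NULL) {
  stopifnot(inherits(predictions, "fiber_predictions"))
  flat <- data.frame(
    product_id = predictions$product_id,
    predicted_fiber_g = predictions$predicted_fiber,
    d1 = predictions$d1,
    k_effective = predictions$k_effective,
    caution = predictions$caution,
    neighbor_ids = vapply(predictions$neighbors,
                          function(nb) paste(nb$neighbor_id, collapse = ";"),
                          character(1)),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(flat, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize / deserialize a fitted model as JSON
#'
#' The artifact is a single JSON document holding the normalization
#' parameters, hyperparameters, caution threshold, and per-category stores
#' at full double precision, plus a format version field.
#'
#' @param model a `fiber_knn` model.
#' @param path file path.
#' @return `write_fiber_model()`: `path` invisibly; `read_fiber_model()`:
#'   the restored `fiber_knn` model.
#' @export
write_fiber_model <- function(model, path) {
  stopifnot(inherits(model, "fiber_knn"))
  doc <- list(
    format_version = 1L,
    tool_version = fiberknn_version(),
    params = list(min = as.list(model$params$min),
                  max = as.list(model$params$max),
                  fitted_on = model$params$fitted_on),
    hyper = unclass(model$hyper),
    caution_threshold = model$caution_threshold,
    stores = lapply(model$stores, function(s) {
      list(product_id = s$product_id,
           features = lapply(seq_len(nrow(s$features)),
                             function(i) as.list(s$features[i, ])),
           fiber = s$fiber)
    })
  )
  # I(17) significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fiber_model
#' @export
read_fiber_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) || doc$format_version != 1L) {
    stop("unsupported model artifact version", call. = FALSE)
  }
  params <- structure(
    list(min = unlist(doc$params$min)[feature_names()],
         max = unlist(doc$params$max)[feature_names()],
         fitted_on = doc$params$fitted_on),
    class = "normalization_params")
  hyper <- knn_hyperparams(k = doc$hyper$k, metric = doc$hyper$metric,
                           weighting = doc$hyper$weighting)
  stores <- lapply(doc$stores, function(s) {
    feats <- do.call(rbind, lapply(s$features, function(fv) {
      unlist(fv)[feature_names()]
    }))
    colnames(feats) <- feature_names()
    list(product_id = unlist(s$product_id),
         features = feats,
         fiber = unlist(s$fiber))
  })
  structure(
    list(params = params, stores = stores, hyper = hyper,
         caution_threshold = doc$caution_threshold),
    class = "fiber_knn")
}
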
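#' Names and order of the six model features
#'
#' The feature order is fixed package-wide: total sugar, starch, protein,
#' saturated fat, unsaturated fat, sodium. The features are mutually
#' exclusive nutrient fractions (no feature is a component of another),
#' minimizing collinearity.
#'
#' @return character vector of length 6.
#' @export
feature_names <- function() {
  c("total_sugar", "starch", "protein", "saturated_fat", "unsaturated_fat",
    "sodium")
}

#' Derive the six raw nutrient features from panel fields
#'
#' Starch is carbohydrate minus total sugar; unsaturated fat is total fat
#' minus saturated fat; the remaining four features pass through. Because
#' panel values are rounded independently, a derived value can come out
#' slightly negative; such values are clamped to 0 with a warning.
#'
#' @param table a [product_table()] whose six panel nutrients are present
#'   for every row (run [apply_exclusions()] first).
#' @return numeric matrix, one row per product, columns [feature_names()].
#' @export
derive_features <- function(table) {
  stopifnot(inherits(table, "product_table"))
  if (anyNA(table[panel_nutrients()])) {
    stop("panel nutrients contain missing values; apply exclusions first",
         call. = FALSE)
  }
  m <- cbind(
    total_sugar     = table$total_sugar,
    starch          = table$carbohydrate - table$total_sugar,
    protein         = table$protein,
    saturated_fat   = table$saturated_fat,
    unsaturated_fat = table$total_fat - table$saturated_fat,
    sodium          = table$sodium
  )
  neg <- m < 0
  if (any(neg)) {
    warning(sum(neg), " negative derived feature value(s) clamped to 0 ",
            "(label rounding artifact)", call. = FALSE)
    m[neg] <- 0
  }
  m
}

#' Fit min-max normalization parameters on training features
#'
#' Records each feature's minimum and maximum over the training set.
#' Constant features (min = max) are permitted; [normalize_features()]
#' maps them to 0, which contributes nothing to any pairwise distance.
#'
#' @param features raw feature matrix from [derive_features()], at least
#'   two rows.
#' @param fitted_on identifier of the training set (bookkeeping only).
#' @return A `normalization_params` object (`$min`, `$max`, named by
#'   feature).
#' @export
fit_normalization <- function(features, fitted_on = "training") {
  if (is.null(dim(features)) || nrow(features) < 2L) {
    stop("need at least 2 feature vectors to fit normalization",
         call. = FALSE)
  }
  stopifnot(identical(colnames(features), feature_names()))
  structure(
    list(min = apply(features, 2L, min),
         max = apply(features, 2L, max),
         fitted_on = fitted_on),
    class = "normalization_params")
}

#' @export
print.normalization_params <- function(x, ...) {
  cat("<normalization_params> fitted on:", x$fitted_on, "\n")
  print(rbind(min = x$min, max = x$max))
  invisible(x)
}

#' Min-max normalize feature vectors
#'
#' Applies X' = (X - Xmin) / (Xmax - Xmin) per feature with the training
#' extrema in `params`. Query values outside the training range map outside
#' \[0, 1\]; there is no clipping, so rescaling any raw feature by a
#' positive constant (in both training and query) leaves normalized values
#' -- and every downstream prediction -- unchanged.
#'
#' @param features raw feature matrix (columns [feature_names()]).
#' @param params a `normalization_params` from [fit_normalization()].
#' @return matrix of the same shape, normalized.
#' @export
normalize_features <- function(features, params) {
  stopifnot(inherits(params, "normalization_params"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, feature_names()))
  stopifnot(identical(colnames(features), feature_names()))
  rng <- params$max - params$min
  out <- sweep(features, 2L, params$min, `-`)
  const <- rng == 0
  rng[const] <- 1  # avoid 0/0; constant features are forced to 0 below
  out <- sweep(out, 2L, rng, `/`)
  if (any(const)) out[, const] <- 0
  out
}
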
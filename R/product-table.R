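#' Column-name schema for product CSV files
#'
#' Maps the internal canonical field names to the column names expected in a
#' CSV file. Pass a modified copy to [read_product_table()] /
#' [write_product_table()] when your file uses different headers.
#'
#' @param ... named overrides, e.g. `sodium = "na_mg"`.
#' @return Named character vector mapping canonical field -> CSV column.
#' @export
#' @examples
#' default_product_schema()
#' default_product_schema(sodium = "sodium_mg_per_100g")
default_product_schema <- function(...) {
  schema <- c(
    product_id       = "product_id",
    brand            = "brand",
    category         = "category",
    basis            = "basis",
    total_sugar      = "total_sugar_g",
    carbohydrate     = "carbohydrate_g",
    protein          = "protein_g",
    saturated_fat    = "saturated_fat_g",
    total_fat        = "total_fat_g",
    sodium           = "sodium_mg",
    fiber            = "fiber_g",
    ingredients_text = "ingredients_text"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) {
      stop("unknown schema field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

# Canonical field groups. The six mandatory panel nutrients are the raw
# inputs from which the model features derive; fiber is the target and may
# be absent (voluntary labeling).
panel_nutrients <- function() {
  c("total_sugar", "carbohydrate", "protein", "saturated_fat", "total_fat",
    "sodium")
}

mandatory_fields <- function() {
  c("product_id", "brand", "category", "basis", panel_nutrients())
}

#' Construct a product table
#'
#' A product table is a `data.frame` (class `product_table`) with one row
#' per packaged product and the canonical columns `product_id`, `brand`,
#' `category`, `basis` (`"per_100g"` or `"per_100mL"`), the six panel
#' nutrients (`total_sugar`, `carbohydrate`, `protein`, `saturated_fat`,
#' `total_fat` in g and `sodium` in mg, all per 100 g / 100 mL), plus the
#' optional `fiber` (g, `NA` when the label omits it) and
#' `ingredients_text` (`NA` when absent).
#'
#' Dirty records -- missing nutrients, missing brand, duplicated ids -- are
#' admitted here so that [apply_exclusions()] can filter and log them;
#' negative nutrient values, however, are never meaningful and are rejected
#' outright.
#'
#' @param df data.frame with the canonical columns (missing optional
#'   columns are added as `NA`).
#' @param provenance free-text source note stored as an attribute.
#' @return A `product_table`.
#' @export
product_table <- function(df, provenance = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(mandatory_fields(), names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("fiber", "ingredients_text")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df <- df[, c(mandatory_fields(), "fiber", "ingredients_text")]
  for (col in c("product_id", "brand", "category", "basis",
                "ingredients_text")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c(panel_nutrients(), "fiber")) {
    if (is.logical(df[[col]]) && all(is.na(df[[col]]))) {
      df[[col]] <- as.numeric(df[[col]])  # all-NA column, type unknowable
    }
    if (!is.numeric(df[[col]])) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
    neg <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(neg)) {
      stop("negative value(s) in `", col, "` (first at row ",
           which(neg)[1L], ")", call. = FALSE)
    }
  }
  bad_basis <- !is.na(df$basis) & !df$basis %in% c("per_100g", "per_100mL")
  if (any(bad_basis)) {
    stop("`basis` must be \"per_100g\" or \"per_100mL\" (row ",
         which(bad_basis)[1L], ")", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("product_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.product_table <- function(x, ...) {
  cat("<product_table> ", nrow(x), " products, ",
      length(unique(x$category)), " categories, ",
      sum(!is.na(x$fiber)), " reporting fiber\n", sep = "")
  if (!is.null(attr(x, "provenance"))) {
    cat("provenance: ", attr(x, "provenance"), "\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# Subsetting keeps the class and provenance.
#' @export
`[.product_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("product_table", "data.frame")
  }
  out
}

#' Read a product table from CSV
#'
#' Expects a UTF-8 CSV with a header row; lines starting with `#` (the
#' metadata headers written by this package) are skipped. Missing optional
#' fields (empty cells) become `NA`, not zero. Mandatory nutrient cells may
#' be empty (the record is then a candidate for the `missing_panel`
#' exclusion), but a non-numeric token raises a row-level parse error.
#'
#' @param path file path.
#' @param schema column-name map from [default_product_schema()].
#' @param provenance optional free-text source note.
#' @return A [product_table()].
#' @export
read_product_table <- function(path, schema = default_product_schema(),
                               provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, comment.char = "#",
                         na.strings = character(0))
  needed <- schema[mandatory_fields()]
  absent <- needed[!needed %in% names(raw)]
  if (length(absent)) {
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(csv_col, mandatory) {
    txt <- trimws(raw[[csv_col]])
    out <- rep(NA_real_, length(txt))
    filled <- !is.na(txt) & txt != "" & toupper(txt) != "NA"
    suppressWarnings(vals <- as.numeric(txt[filled]))
    if (anyNA(vals)) {
      bad_row <- which(filled)[which(is.na(vals))[1L]]
      stop("parse error: non-numeric value \"", txt[filled][is.na(vals)][1L],
           "\" in column `", csv_col, "`, row ", bad_row, call. = FALSE)
    }
    out[filled] <- vals
    out
  }
  get_chr <- function(field) {
    csv_col <- schema[[field]]
    if (!csv_col %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    out <- raw[[csv_col]]
    out[!is.na(out) & out == ""] <- NA_character_
    out
  }
  df <- data.frame(
    product_id       = get_chr("product_id"),
    brand            = get_chr("brand"),
    category         = get_chr("category"),
    basis            = get_chr("basis"),
    stringsAsFactors = FALSE
  )
  for (nut in panel_nutrients()) df[[nut]] <- parse_num(schema[[nut]], TRUE)
  df$fiber <- if (schema[["fiber"]] %in% names(raw)) {
    parse_num(schema[["fiber"]], FALSE)
  } else {
    NA_real_
  }
  df$ingredients_text <- get_chr("ingredients_text")
  product_table(df, provenance = provenance)
}

#' Write a product table to CSV
#'
#' Inverse of [read_product_table()]: the same schema map chooses the
#' output column names, optional metadata lines are written as leading
#' `#` comments, and a read-back reproduces every field (strings
#' bit-exactly, numerics to full printed precision).
#'
#' @param table a [product_table()].
#' @param path output path.
#' @param schema column-name map.
#' @param header_lines optional character vector of metadata comment lines
#'   (written verbatim after a `# ` prefix).
#' @return `path`, invisibly.
#' @export
write_product_table <- function(table, path,
                                schema = default_product_schema(),
                                header_lines = NULL) {
  stopifnot(inherits(table, "product_table"))
  out <- as.data.frame(table)
  names(out) <- unname(schema[names(out)])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}
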
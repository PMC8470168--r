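#' Parenthesis-count balance of an ingredients list
#'
#' A cheap proxy for a cleanly extracted ingredients list: the number of
#' opening parentheses must equal the number of closing parentheses. The
#' criterion is deliberately count-based, not nesting-based, so `")("` is
#' balanced -- mis-ordered but complete extractions pass, truncated ones do
#' not.
#'
#' @param text character vector (empty strings allowed; `NA` yields `NA`).
#' @return logical vector, `TRUE` where counts match.
#' @export
#' @examples
#' balanced_parentheses("Tomatoes (60%), salt")   # TRUE
#' balanced_parentheses("Tomatoes (60%, salt")    # FALSE
#' balanced_parentheses(")(")                     # TRUE (count equality)
balanced_parentheses <- function(text) {
  stopifnot(is.character(text) || all(is.na(text)))
  text <- as.character(text)
  n_open <- nchar(gsub("[^(]", "", text))
  n_close <- nchar(gsub("[^)]", "", text))
  out <- n_open == n_close
  out[is.na(text)] <- NA
  out
}

#' Record-level exclusion rules
#'
#' The rule names understood by [apply_exclusions()], in their canonical
#' application order:
#' \describe{
#'   \item{missing_panel}{any of the six mandatory panel nutrients absent}
#'   \item{missing_ingredients}{no ingredients list}
#'   \item{unbalanced_ingredients}{ingredients list present but its
#'     parenthesis counts differ ([balanced_parentheses()])}
#'   \item{missing_brand}{no brand information}
#'   \item{duplicate_id}{`product_id` already seen earlier in the table
#'     (the first occurrence is retained)}
#' }
#' @return character vector of rule names.
#' @export
exclusion_rules <- function() {
  c("missing_panel", "missing_ingredients", "unbalanced_ingredients",
    "missing_brand", "duplicate_id")
}

#' Apply record-level exclusion rules
#'
#' Rules are applied in the order given; a product failing several rules is
#' logged under the first one only, mirroring a sequential exclusion flow
#' chart. Retained records are returned unmodified.
#'
#' @param table a [product_table()].
#' @param rules ordered subset of [exclusion_rules()].
#' @return list with `retained` (a `product_table`) and `log` (an
#'   `exclusion_log`: `$excluded` data.frame of `(product_id, rule_name)`
#'   and `$counts_per_rule` named integer vector).
#' @export
apply_exclusions <- function(table, rules = exclusion_rules()) {
  stopifnot(inherits(table, "product_table"))
  unknown <- setdiff(rules, exclusion_rules())
  if (length(unknown)) {
    stop("unknown exclusion rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table)
  blank <- function(x) is.na(x) | trimws(x) == ""
  violates <- function(rule) {
    switch(rule,
      missing_panel = Reduce(`|`, lapply(panel_nutrients(),
                                         function(f) is.na(table[[f]]))),
      missing_ingredients = blank(table$ingredients_text),
      unbalanced_ingredients = {
        v <- !balanced_parentheses(table$ingredients_text)
        v[is.na(v)] <- FALSE  # absence is missing_ingredients' business
        v
      },
      missing_brand = blank(table$brand),
      duplicate_id = duplicated(table$product_id)
    )
  }
  first_rule <- rep(NA_character_, n)
  for (rule in rules) {
    hit <- violates(rule) & is.na(first_rule)
    first_rule[hit] <- rule
  }
  excluded <- data.frame(
    product_id = table$product_id[!is.na(first_rule)],
    rule_name = first_rule[!is.na(first_rule)],
    stringsAsFactors = FALSE
  )
  counts <- vapply(rules, function(r) sum(excluded$rule_name == r, na.rm = TRUE),
                   integer(1))
  log <- structure(list(excluded = excluded, counts_per_rule = counts),
                   class = "exclusion_log")
  list(retained = table[is.na(first_rule), , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("<exclusion_log> ", nrow(x$excluded), " products excluded\n", sep = "")
  for (r in names(x$counts_per_rule)) {
    cat(sprintf("  %-24s %d\n", r, x$counts_per_rule[[r]]))
  }
  invisible(x)
}

#' Serialize an exclusion log to JSON
#'
#' @param log an `exclusion_log` from [apply_exclusions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  stopifnot(inherits(log, "exclusion_log"))
  jsonlite::write_json(
    list(excluded = log$excluded,
         counts_per_rule = as.list(log$counts_per_rule)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Filter categories by fiber-reporting rate and allow-list
#'
#' Categories in which too few products report fiber provide too thin a
#' neighbor pool to predict from and are dropped wholesale; the default
#' threshold keeps categories where at least 25% of products report fiber
#' (the boundary is inclusive: a rate exactly equal to the threshold is
#' retained). An optional allow-list restricts the table to categories
#' chosen on external grounds, e.g. the categories that dominate national
#' fiber intake.
#'
#' @param table a [product_table()]; must be non-empty.
#' @param min_reporting_rate fraction in \[0, 1\]; default 0.25.
#' @param allowed optional character vector of category names to keep.
#' @return list with `retained` (a `product_table`) and `dropped` (named
#'   character vector: category -> reason, `"low_reporting"` or
#'   `"not_allowed"`).
#' @export
filter_categories <- function(table, min_reporting_rate = 0.25,
                              allowed = NULL) {
  stopifnot(inherits(table, "product_table"))
  if (nrow(table) == 0L) stop("empty product table", call. = FALSE)
  stopifnot(is.numeric(min_reporting_rate), length(min_reporting_rate) == 1L,
            min_reporting_rate >= 0, min_reporting_rate <= 1)
  cats <- unique(table$category)
  reason <- setNames(rep(NA_character_, length(cats)), cats)
  for (ct in cats) {
    in_cat <- table$category == ct
    if (!is.null(allowed) && !ct %in% allowed) {
      reason[ct] <- "not_allowed"
      next
    }
    rate <- sum(!is.na(table$fiber[in_cat])) / sum(in_cat)
    if (rate < min_reporting_rate) reason[ct] <- "low_reporting"
  }
  dropped <- reason[!is.na(reason)]
  list(retained = table[!table$category %in% names(dropped), , drop = FALSE],
       dropped = dropped)
}
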
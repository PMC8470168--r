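# Small in-code fixtures: every table is built programmatically.

# A product table from vectors, with sensible defaults for what's not
# under test.
make_table <- function(n = 3,
                       product_id = sprintf("P%03d", seq_len(n)),
                       brand = rep("BrandA", n),
                       category = rep("bread", n),
                       basis = rep("per_100g", n),
                       total_sugar = rep(5, n),
                       carbohydrate = rep(40, n),
                       protein = rep(8, n),
                       saturated_fat = rep(1, n),
                       total_fat = rep(4, n),
                       sodium = rep(400, n),
                       fiber = rep(3, n),
                       ingredients_text = rep("flour (60%), water", n)) {
  product_table(data.frame(
    product_id = product_id, brand = brand, category = category,
    basis = basis, total_sugar = total_sugar, carbohydrate = carbohydrate,
    protein = protein, saturated_fat = saturated_fat,
    total_fat = total_fat, sodium = sodium, fiber = fiber,
    ingredients_text = ingredients_text, stringsAsFactors = FALSE))
}

# A random product table with b brands and the given categories; all
# records report fiber. Nutrients are drawn so that derived features are
# non-negative.
random_table <- function(n, categories = c("bread", "soup"), b = 4,
                         prefix = "R") {
  sugar <- runif(n, 0, 20)
  starch <- runif(n, 0, 50)
  satfat <- runif(n, 0, 10)
  unsat <- runif(n, 0, 15)
  make_table(
    n = n,
    product_id = sprintf("%s%04d", prefix, seq_len(n)),
    brand = sprintf("B%02d", sample.int(b, n, replace = TRUE)),
    category = sample(categories, n, replace = TRUE),
    total_sugar = sugar, carbohydrate = sugar + starch,
    protein = runif(n, 0, 25), saturated_fat = satfat,
    total_fat = satfat + unsat, sodium = runif(n, 0, 1500),
    fiber = runif(n, 0, 12))
}
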
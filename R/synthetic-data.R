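#' Category profile for the synthetic supply generator
#'
#' Describes one food category as (i) a Dirichlet distribution over the
#' six mass components sugar, starch, protein, saturated fat, unsaturated
#' fat and "other" (water, ash, fiber...) scaled to 100 g; (ii) a
#' log-normal sodium level in mg; (iii) a linear fiber-generating relation
#' fiber = clamp(beta0 + beta1*starch + beta2*sugar + eps, 0, other) with
#' Gaussian noise sd `fiber_noise_sd` -- fiber is carved out of the
#' "other" mass, so components plus fiber always sum to exactly 100 g;
#' and (iv) a set of brands, each tilting the Dirichlet concentrations by
#' a log-normal factor so that same-brand products cluster in feature
#' space (the reason train/test splits must be brand-grouped).
#'
#' @param name category name.
#' @param dirichlet_concentration positive numeric length-6 vector over
#'   (sugar, starch, protein, saturated_fat, unsaturated_fat, other).
#' @param sodium_log_mean,sodium_log_sd log-normal parameters for sodium
#'   (mg per 100 g / 100 mL).
#' @param beta0 fiber intercept (g); `beta1`, `beta2` dimensionless
#'   coefficients on starch and sugar.
#' @param fiber_noise_sd sd of the fiber noise (g), >= 0.
#' @param n_brands number of brands in the category (>= 1).
#' @param brand_effect_sd log-sd of the per-brand concentration tilt.
#' @param basis `"per_100g"` or `"per_100mL"`.
#' @return A `category_profile`.
#' @export
category_profile <- function(name, dirichlet_concentration,
                             sodium_log_mean, sodium_log_sd,
                             beta0, beta1, beta2, fiber_noise_sd,
                             n_brands, brand_effect_sd,
                             basis = "per_100g") {
  stopifnot(is.character(name), length(dirichlet_concentration) == 6L,
            all(dirichlet_concentration > 0), fiber_noise_sd >= 0,
            n_brands >= 1L, brand_effect_sd >= 0, sodium_log_sd >= 0,
            basis %in% c("per_100g", "per_100mL"))
  structure(
    list(name = name,
         dirichlet_concentration = setNames(
           as.numeric(dirichlet_concentration),
           c("sugar", "starch", "protein", "saturated_fat",
             "unsaturated_fat", "other")),
         sodium_log_mean = sodium_log_mean, sodium_log_sd = sodium_log_sd,
         beta0 = beta0, beta1 = beta1, beta2 = beta2,
         fiber_noise_sd = fiber_noise_sd,
         n_brands = as.integer(n_brands),
         brand_effect_sd = brand_effect_sd, basis = basis),
    class = "category_profile")
}

# The five documented archetypes. Concentration vectors are the category's
# mean composition (g per 100 g) scaled to a total concentration of 60:
# component marginals are then unimodal around the category mean with
# within-category standard deviations of a few grams, matching the spread
# of real nutrition panels within a category (concentrations summing to
# ~10 were tried first and produce Beta(<1, .) marginals whose tails yield
# physically absurd products, e.g. juices with 10 g fiber per 100 mL).
# Fiber coefficients put the archetypes in distinct density classes:
# cereal-like ~10 g (high), juice-like ~0.6 g (negligible), bread-like
# ~3.9 g, snack-like ~4 g, soup-like ~1.2 g.
base_archetypes <- function() {
  scale60 <- function(mean_comp) 60 * mean_comp / sum(mean_comp)
  list(
    cereal_like = category_profile(
      "cereal_like", scale60(c(16.7, 45.8, 10, 2.5, 5.8, 19.2)),
      sodium_log_mean = log(300), sodium_log_sd = 0.6,
      beta0 = 1.0, beta1 = 0.18, beta2 = 0.05, fiber_noise_sd = 0.5,
      n_brands = 40L, brand_effect_sd = 0.15),
    juice_like = category_profile(
      "juice_like", scale60(c(10, 1, 0.5, 0.1, 0.2, 88.2)),
      sodium_log_mean = log(20), sodium_log_sd = 0.7,
      beta0 = 0.1, beta1 = 0.2, beta2 = 0.03, fiber_noise_sd = 0.15,
      n_brands = 30L, brand_effect_sd = 0.15, basis = "per_100mL"),
    bread_like = category_profile(
      "bread_like", scale60(c(4, 45, 10, 1.5, 3.5, 36)),
      sodium_log_mean = log(450), sodium_log_sd = 0.4,
      beta0 = 0.5, beta1 = 0.07, beta2 = 0.05, fiber_noise_sd = 0.5,
      n_brands = 35L, brand_effect_sd = 0.15),
    snack_like = category_profile(
      "snack_like", scale60(c(6, 50, 7, 6, 16, 15)),
      sodium_log_mean = log(600), sodium_log_sd = 0.5,
      beta0 = 0.3, beta1 = 0.07, beta2 = 0.04, fiber_noise_sd = 0.6,
      n_brands = 45L, brand_effect_sd = 0.15),
    soup_like = category_profile(
      "soup_like", scale60(c(3, 6, 4, 0.8, 1.2, 85)),
      sodium_log_mean = log(250), sodium_log_sd = 0.5,
      beta0 = 0.4, beta1 = 0.10, beta2 = 0.05, fiber_noise_sd = 0.3,
      n_brands = 25L, brand_effect_sd = 0.15)
  )
}

#' Default category profiles
#'
#' Deterministic profiles spanning high-fiber (cereal-like), negligible
#' (juice-like) and mid-fiber (bread/snack/soup-like) archetypes. Asking
#' for more than five cycles through the archetypes with a small
#' seed-derived jitter on the fiber intercept and concentrations so that
#' the extra categories are distinct.
#'
#' @param n_categories integer in 1..14.
#' @param seed integer RNG seed for the jitter (unused for
#'   `n_categories <= 5`).
#' @return list of [category_profile()]s.
#' @export
make_default_profiles <- function(n_categories = 5L, seed = 20210914L) {
  stopifnot(n_categories >= 1L, n_categories <= 14L)
  base <- base_archetypes()
  if (n_categories <= length(base)) {
    return(unname(base[seq_len(n_categories)]))
  }
  extra_n <- n_categories - length(base)
  extras <- with_seed(seed, lapply(seq_len(extra_n), function(i) {
    p <- base[[((i - 1L) %% length(base)) + 1L]]
    p$name <- sprintf("%s_v%d", p$name, (i - 1L) %/% length(base) + 2L)
    p$beta0 <- max(0, p$beta0 + runif(1, -0.2, 0.2))
    p$dirichlet_concentration <-
      p$dirichlet_concentration * rlnorm(6L, 0, 0.1)
    p
  }))
  c(unname(base), extras)
}

#' Specification of a synthetic packaged-food supply
#'
#' Bundles the category profiles with the per-category sample size, the
#' seed, the fiber-reporting masking model, and the carbohydrate labeling
#' convention. Fiber is *reported* (present in the observed table) with
#' probability plogis(gamma0 + gamma1 * fiber), so a positive `gamma1`
#' reproduces reporting bias: high-fiber products advertise their fiber,
#' low-fiber products stay silent. The defaults (-1, 0.35) give roughly
#' half of products reporting, with the reported group visibly richer in
#' fiber. By default the carbohydrate panel value excludes fiber (the
#' Australian "available carbohydrate" convention);
#' `carbohydrate_convention = "total"` includes it (US-style labels).
#'
#' @param profiles list of [category_profile()]s.
#' @param n_per_category products per category (>= 1).
#' @param seed integer RNG seed.
#' @param reporting_gamma0,reporting_gamma1 logistic masking coefficients.
#' @param carbohydrate_convention `"available"` or `"total"`.
#' @return A `supply_spec`.
#' @export
supply_spec <- function(profiles, n_per_category, seed = 1L,
                        reporting_gamma0 = -1, reporting_gamma1 = 0.35,
                        carbohydrate_convention = c("available", "total")) {
  carbohydrate_convention <- match.arg(carbohydrate_convention)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "category_profile")),
            n_per_category >= 1L)
  structure(
    list(profiles = profiles, n_per_category = as.integer(n_per_category),
         seed = seed, reporting_gamma0 = reporting_gamma0,
         reporting_gamma1 = reporting_gamma1,
         carbohydrate_convention = carbohydrate_convention),
    class = "supply_spec")
}

#' Generate a synthetic packaged-food supply with known ground truth
#'
#' For every product the generator draws, in a documented order that makes
#' outputs fully reproducible from the seed (per category: brand tilts,
#' then brand assignments, composition Gamma draws, sodium, fiber noise,
#' reporting uniforms):
#' \enumerate{
#'   \item a mass composition over (sugar, starch, protein, saturated fat,
#'     unsaturated fat, other) from the brand-tilted category Dirichlet,
#'     scaled to 100 g;
#'   \item sodium from a log-normal (mg);
#'   \item true fiber = clamp(beta0 + beta1*starch + beta2*sugar + eps,
#'     0, other), eps ~ N(0, sigma^2); fiber is carved out of the "other"
#'     mass so all seven masses sum to exactly 100 g;
#'   \item panel fields: carbohydrate = sugar + starch (plus fiber under
#'     the `"total"` convention), total fat = saturated + unsaturated;
#'   \item a reporting flag with probability plogis(gamma0 + gamma1 *
#'     fiber); masked products have `fiber = NA` in the observed table.
#' }
#'
#' @param spec a [supply_spec()].
#' @return list with `observed` (a [product_table()]; fiber `NA` where
#'   masked) and `truth` (data.frame `product_id`, `true_fiber` for every
#'   product).
#' @export
generate_supply <- function(spec) {
  stopifnot(inherits(spec, "supply_spec"))
  n <- spec$n_per_category
  with_seed(spec$seed, {
    obs <- vector("list", length(spec$profiles))
    tru <- vector("list", length(spec$profiles))
    pid0 <- 0L
    for (ci in seq_along(spec$profiles)) {
      p <- spec$profiles[[ci]]
      tilt <- matrix(rlnorm(p$n_brands * 6L, 0, p$brand_effect_sd),
                     p$n_brands, 6L)
      brand_idx <- sample.int(p$n_brands, n, replace = TRUE)
      shape <- sweep(tilt[brand_idx, , drop = FALSE], 2L,
                     p$dirichlet_concentration, `*`)
      comp <- matrix(rgamma(n * 6L, shape = shape), n, 6L)
      comp <- 100 * comp / rowSums(comp)
      colnames(comp) <- names(p$dirichlet_concentration)
      sodium <- rlnorm(n, p$sodium_log_mean, p$sodium_log_sd)
      eps <- rnorm(n, 0, p$fiber_noise_sd)
      u_report <- runif(n)

      fiber_true <- pmin(pmax(p$beta0 + p$beta1 * comp[, "starch"] +
                                p$beta2 * comp[, "sugar"] + eps, 0),
                         comp[, "other"])
      carb <- comp[, "sugar"] + comp[, "starch"] +
        if (spec$carbohydrate_convention == "total") fiber_true else 0
      reported <- u_report < plogis(spec$reporting_gamma0 +
                                      spec$reporting_gamma1 * fiber_true)
      ids <- sprintf("SYN%06d", pid0 + seq_len(n))
      pid0 <- pid0 + n
      obs[[ci]] <- data.frame(
        product_id = ids,
        brand = sprintf("%s_b%02d", p$name, brand_idx),
        category = p$name,
        basis = p$basis,
        total_sugar = comp[, "sugar"],
        carbohydrate = carb,
        protein = comp[, "protein"],
        saturated_fat = comp[, "saturated_fat"],
        total_fat = comp[, "saturated_fat"] + comp[, "unsaturated_fat"],
        sodium = sodium,
        fiber = ifelse(reported, fiber_true, NA_real_),
        ingredients_text = sprintf(
          "grain blend (%.1f%%), sugar (%.1f%%), vegetable oil, salt",
          comp[, "starch"], comp[, "sugar"]),
        stringsAsFactors = FALSE)
      tru[[ci]] <- data.frame(product_id = ids, true_fiber = fiber_true,
                              stringsAsFactors = FALSE)
    }
    list(observed = product_table(do.call(rbind, obs),
                                  provenance = sprintf("synthetic supply (seed %s)",
                                                       format(spec$seed))),
         truth = do.call(rbind, tru))
  })
}

#' Serialize / deserialize a supply spec as JSON
#'
#' @param spec a [supply_spec()].
#' @param path file path.
#' @return `write_supply_spec()`: `path` invisibly; `read_supply_spec()`:
#'   the restored `supply_spec`.
#' @export
write_supply_spec <- function(spec, path) {
  stopifnot(inherits(spec, "supply_spec"))
  doc <- unclass(spec)
  doc$profiles <- lapply(spec$profiles, function(p) {
    q <- unclass(p)
    q$dirichlet_concentration <- as.list(p$dirichlet_concentration)
    q
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_supply_spec
#' @export
read_supply_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  profiles <- lapply(doc$profiles, function(p) {
    category_profile(
      name = p$name,
      dirichlet_concentration = unlist(p$dirichlet_concentration),
      sodium_log_mean = p$sodium_log_mean, sodium_log_sd = p$sodium_log_sd,
      beta0 = p$beta0, beta1 = p$beta1, beta2 = p$beta2,
      fiber_noise_sd = p$fiber_noise_sd, n_brands = p$n_brands,
      brand_effect_sd = p$brand_effect_sd, basis = p$basis)
  })
  supply_spec(profiles, n_per_category = doc$n_per_category,
              seed = doc$seed, reporting_gamma0 = doc$reporting_gamma0,
              reporting_gamma1 = doc$reporting_gamma1,
              carbohydrate_convention = doc$carbohydrate_convention)
}
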
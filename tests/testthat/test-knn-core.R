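# A hand-buildable model: normalization is the identity on [0, 1] ranges,
# so raw query features pass through unchanged.
identity_params <- function() {
  f <- matrix(rep(c(0, 1), each = 6), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, feature_names()))
  fit_normalization(rbind(f[1, , drop = FALSE], f[2, , drop = FALSE]))
}

manual_model <- function(ids, features, fiber, category = "bread",
                         hyper = knn_hyperparams(), caution_threshold = 0.08) {
  colnames(features) <- feature_names()
  structure(
    list(params = identity_params(),
         stores = setNames(list(list(product_id = ids, features = features,
                                     fiber = fiber)), category),
         hyper = hyper, caution_threshold = caution_threshold),
    class = "fiber_knn")
}

query_record <- function(sugar = 0, id = "Q1", category = "bread") {
  make_table(1, product_id = id, category = category, total_sugar = sugar,
             carbohydrate = sugar, protein = 0, saturated_fat = 0,
             total_fat = 0, sodium = 0, fiber = NA_real_)
}

test_that("manhattan_distance sums absolute differences", {
  expect_equal(manhattan_distance(c(0.1, 0.2, 0.3, 0.0, 0.5, 0.4),
                                  c(0.2, 0.2, 0.1, 0.1, 0.5, 0.0)), 0.8)
  x <- runif(6); expect_equal(manhattan_distance(x, x), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    expect_identical(manhattan_distance(a, b), manhattan_distance(b, a))
  }
  expect_error(manhattan_distance(1:3, 1:4), "length")
})

test_that("fit_fiber_knn partitions by category and is deterministic", {
  set.seed(8)
  tab <- random_table(10, categories = c("bread", "soup"))
  m <- fit_fiber_knn(tab)
  sizes <- vapply(m$stores, function(s) length(s$fiber), integer(1))
  expect_equal(sum(sizes), 10L)
  expect_setequal(names(m$stores), c("bread", "soup"))
  for (ct in names(m$stores)) {
    expect_true(all(m$stores[[ct]]$product_id %in%
                      tab$product_id[tab$category == ct]))
  }
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fiber_model(fit_fiber_knn(tab), p1)
  write_fiber_model(fit_fiber_knn(tab), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("fit_fiber_knn rejects missing fiber and duplicate ids by name", {
  tab <- make_table(3, fiber = c(1, NA, 2))
  expect_error(fit_fiber_knn(tab), "P002")
  dup <- make_table(3, product_id = c("A", "A", "B"))
  expect_error(fit_fiber_knn(dup), "A")
})

test_that("predict evaluates the inverse-distance weighted average", {
  # neighbors at distances 1 and 3 with fibers 2 and 4:
  # Q = (2*1 + 4*(1/3)) / (1 + 1/3) = 2.5
  m <- manual_model(
    ids = c("A", "B"),
    features = rbind(c(0, 0, 0, 0, 0, 0), c(4, 0, 0, 0, 0, 0)),
    fiber = c(2, 4), hyper = knn_hyperparams(k = 2))
  p <- predict(m, query_record(sugar = 1))
  expect_equal(p$predicted_fiber, 2.5)
  expect_equal(p$d1, 1)
  expect_equal(p$k_effective, 2L)
  expect_true(p$caution)  # d1 = 1 > 0.08

  # uniform weighting: plain mean
  m$hyper <- knn_hyperparams(k = 2, weighting = "uniform")
  expect_equal(predict(m, query_record(sugar = 1))$predicted_fiber, 3)
})

test_that("zero-distance neighbors yield the unweighted mean of exact matches", {
  m <- manual_model(
    ids = c("A", "B", "C"),
    features = rbind(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0),
                     c(3, 0, 0, 0, 0, 0)),
    fiber = c(6, 8, 100), hyper = knn_hyperparams(k = 3))
  p <- predict(m, query_record(sugar = 1))
  expect_equal(p$predicted_fiber, 7)  # mean of the two exact matches
  expect_equal(p$d1, 0)
  single <- manual_model(ids = c("A", "B"),
                         features = rbind(c(1, 0, 0, 0, 0, 0),
                                          c(2, 0, 0, 0, 0, 0)),
                         fiber = c(6, 9), hyper = knn_hyperparams(k = 1))
  expect_equal(predict(single, query_record(sugar = 1))$predicted_fiber, 6)
})

test_that("equidistant neighbors reduce to a simple mean under inverse weighting", {
  m <- manual_model(
    ids = c("A", "B", "C"),
    features = rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0),
                     c(0, 0, 1, 0, 0, 0)),
    fiber = c(2, 5, 11), hyper = knn_hyperparams(k = 3))
  p <- predict(m, query_record(sugar = 0))
  expect_equal(p$predicted_fiber, mean(c(2, 5, 11)))
})

test_that("a query never uses itself as neighbor (leave-self-out by id)", {
  m <- manual_model(
    ids = c("Q1", "B"),
    features = rbind(c(1, 0, 0, 0, 0, 0), c(2, 0, 0, 0, 0, 0)),
    fiber = c(50, 7), hyper = knn_hyperparams(k = 1))
  p <- predict(m, query_record(sugar = 1, id = "Q1"))
  expect_equal(p$predicted_fiber, 7)  # self (distance 0, fiber 50) skipped
})

test_that("ties at the k-th neighbor break by ascending product_id", {
  m <- manual_model(
    ids = c("Z", "A", "M"),
    features = rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0),
                     c(0, 0, 1, 0, 0, 0)),
    fiber = c(10, 20, 30), hyper = knn_hyperparams(k = 2))
  # all three at distance 1 from origin query; A and M win by id
  p <- predict(m, query_record(sugar = 0))
  expect_identical(p$neighbors[[1]]$neighbor_id, c("A", "M"))
})

test_that("k saturates at the store size and far additions do not change predictions", {
  set.seed(9)
  tab <- random_table(12, categories = "bread")
  q <- random_table(5, categories = "bread", prefix = "Q")
  m_big <- fit_fiber_knn(tab, knn_hyperparams(k = 50))
  m_exact <- fit_fiber_knn(tab, knn_hyperparams(k = 12))
  expect_equal(predict(m_big, q)$predicted_fiber,
               predict(m_exact, q)$predicted_fiber)

  # nested-model consistency: add one product far away in feature space
  m8 <- fit_fiber_knn(tab, knn_hyperparams(k = 3))
  far <- make_table(1, product_id = "FAR", category = "bread",
                    total_sugar = 0, carbohydrate = 0, protein = 0,
                    saturated_fat = 0, total_fat = 0, sodium = 1e6,
                    fiber = 99)
  norm_far <- normalize_features(derive_features(far), m8$params)
  m8_plus <- m8
  m8_plus$stores$bread$product_id <- c(m8$stores$bread$product_id, "FAR")
  m8_plus$stores$bread$features <- rbind(m8$stores$bread$features, norm_far)
  m8_plus$stores$bread$fiber <- c(m8$stores$bread$fiber, 99)
  expect_equal(predict(m8, q)$predicted_fiber,
               predict(m8_plus, q)$predicted_fiber)
})

test_that("unknown query category errors listing known categories", {
  set.seed(10)
  m <- fit_fiber_knn(random_table(10, categories = c("bread", "soup")))
  expect_error(predict(m, query_record(category = "cake")),
               "cake.*bread.*soup|cake.*soup.*bread")
})

test_that("explain reports weight shares that sum to 1 and marks exact matches", {
  set.seed(12)
  tab <- random_table(20, categories = "bread")
  m <- fit_fiber_knn(tab)
  p <- predict(m, random_table(3, categories = "bread", prefix = "Q"))
  rep1 <- capture.output(nb <- explain(p, p$product_id[2]))
  expect_equal(nrow(nb), 8L)
  expect_equal(sum(nb$weight_share), 1)
  expect_false(any(nb$exact_match))

  m_u <- fit_fiber_knn(tab, knn_hyperparams(k = 5, weighting = "uniform"))
  p_u <- predict(m_u, random_table(1, categories = "bread", prefix = "Q"))
  nb_u <- suppressMessages(capture.output(x <- explain(p_u)))
  expect_equal(x$weight_share, rep(1 / 5, 5))

  dup <- manual_model(ids = c("A", "B"),
                      features = rbind(c(1, 0, 0, 0, 0, 0),
                                       c(3, 0, 0, 0, 0, 0)),
                      fiber = c(4, 9), hyper = knn_hyperparams(k = 2))
  p0 <- predict(dup, query_record(sugar = 1))
  invisible(capture.output(nb0 <- explain(p0)))
  expect_true(nb0$exact_match[1])
})

test_that("model JSON round-trip reproduces predictions exactly", {
  set.seed(13)
  tab <- random_table(30, categories = c("bread", "soup"))
  m <- fit_fiber_knn(tab, knn_hyperparams(k = 4, metric = "euclidean",
                                          weighting = "uniform"),
                     caution_threshold = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fiber_model(m, path)
  m2 <- read_fiber_model(path)
  q <- random_table(10, categories = c("bread", "soup"), prefix = "Q")
  p1 <- predict(m, q); p2 <- predict(m2, q)
  expect_identical(p1$predicted_fiber, p2$predicted_fiber)
  expect_identical(p1$d1, p2$d1)
  expect_identical(m2$hyper$metric, "euclidean")
  expect_identical(m2$caution_threshold, 0.1)
})

test_that("predictions are convex in neighbor fibers and category-closed", {
  set.seed(14)
  for (rep in 1:5) {
    tab <- random_table(60, categories = c("a", "b", "c"), b = 6)
    m <- fit_fiber_knn(tab, knn_hyperparams(k = sample(1:10, 1)))
    q <- random_table(15, categories = c("a", "b", "c"), prefix = "Q")
    p <- predict(m, q)
    for (i in seq_len(nrow(p))) {
      nb <- p$neighbors[[i]]
      expect_gte(p$predicted_fiber[i], min(nb$fiber) - 1e-12)
      expect_lte(p$predicted_fiber[i], max(nb$fiber) + 1e-12)
      expect_true(all(nb$neighbor_id %in%
                        tab$product_id[tab$category == p$category[i]]))
    }
    expect_true(all(p$predicted_fiber >= 0))
  }
})

test_that("predictions CSV export flattens neighbor ids", {
  set.seed(15)
  m <- fit_fiber_knn(random_table(10, categories = "bread"),
                     knn_hyperparams(k = 3))
  p <- predict(m, random_table(2, categories = "bread", prefix = "Q"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(p, path, header_lines = "seed: 1")
  got <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(got), 2L)
  expect_equal(lengths(strsplit(got$neighbor_ids, ";")), c(3L, 3L))
})
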
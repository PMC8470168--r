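# Independent oracles, deliberately written as plain loops over the
# textbook formulas. They share no code with the package internals.

# Raw features straight from the panel arithmetic, one row at a time.
oracle_features <- function(table) {
  out <- matrix(NA_real_, nrow(table), 6)
  for (i in seq_len(nrow(table))) {
    v <- c(table$total_sugar[i],
           table$carbohydrate[i] - table$total_sugar[i],
           table$protein[i],
           table$saturated_fat[i],
           table$total_fat[i] - table$saturated_fat[i],
           table$sodium[i])
    v[v < 0] <- 0
    out[i, ] <- v
  }
  out
}

# Min-max normalization with extrema computed by explicit scan.
oracle_normalize <- function(features, train_features) {
  out <- features
  for (j in seq_len(ncol(features))) {
    lo <- Inf; hi <- -Inf
    for (i in seq_len(nrow(train_features))) {
      if (train_features[i, j] < lo) lo <- train_features[i, j]
      if (train_features[i, j] > hi) hi <- train_features[i, j]
    }
    out[, j] <- if (hi == lo) 0 else (features[, j] - lo) / (hi - lo)
  }
  out
}

# Exhaustive-scan weighted KNN on a single category store: compute every
# distance, sort (ties by ascending id), take k, apply the weighted
# average with the zero-distance rule.
oracle_knn_predict <- function(store_ids, store_feat, store_fiber,
                               q_feat, q_id, k, metric, weighting) {
  d <- numeric(length(store_ids))
  for (i in seq_along(store_ids)) {
    diff <- q_feat - store_feat[i, ]
    d[i] <- if (metric == "manhattan") sum(abs(diff)) else sqrt(sum(diff^2))
  }
  keep <- store_ids != q_id
  d <- d[keep]; ids <- store_ids[keep]; fib <- store_fiber[keep]
  ord <- order(d, ids)
  ke <- min(k, length(ord))
  sel <- ord[seq_len(ke)]
  ds <- d[sel]; qs <- fib[sel]
  if (any(ds == 0)) {
    mean(qs[ds == 0])
  } else if (weighting == "inverse") {
    sum(qs / ds) / sum(1 / ds)
  } else {
    mean(qs)
  }
}

oracle_r2 <- function(y, yhat) {
  ybar <- sum(y) / length(y)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - ybar)^2
  }
  1 - ss_res / ss_tot
}

oracle_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}

# Pearson on average ranks, coded from the definition.
oracle_spearman <- function(y, yhat) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(y); ry <- avg_rank(yhat)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided Mann-Whitney p by full enumeration of which pooled
# ranks belong to group 1 (no ties assumed).
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx_sets <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  u_all <- apply(idx_sets, 2, function(ix) sum(all_ranks[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
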
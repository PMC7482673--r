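test_that("tSNE is deterministic given a seed and uses only feature columns", {
  set.seed(1)
  fm <- matrix(rnorm(60 * 4), 60, 4)
  meta <- data.frame(cond = sample(letters[1:3], 60, TRUE))
  f1 <- make_feature_table(fm, meta = meta)
  e1 <- embed_tsne(f1, perplexity = 10, max_iter = 300, seed = 5)
  e2 <- embed_tsne(f1, perplexity = 10, max_iter = 300, seed = 5)
  expect_identical(e1$coords, e2$coords)
  # shuffled metadata cannot change the embedding
  f2 <- make_feature_table(fm, meta = data.frame(cond = rev(meta$cond)))
  e3 <- embed_tsne(f2, perplexity = 10, max_iter = 300, seed = 5)
  expect_identical(e1$coords, e3$coords)
})

test_that("tSNE rejects a perplexity too large for n", {
  f <- make_feature_table(matrix(rnorm(30), 10, 3))
  expect_error(embed_tsne(f, perplexity = 25), "perplexity")
})

test_that("tSNE separates far blobs and keeps duplicates adjacent", {
  set.seed(2)
  blob <- rbind(matrix(rnorm(30 * 3), 30, 3),
                matrix(rnorm(30 * 3, mean = 12), 30, 3))
  lab <- rep(1:2, each = 30)
  emb <- embed_tsne(make_feature_table(blob), perplexity = 10,
                    max_iter = 500, seed = 3)
  d <- as.matrix(dist(emb$coords))
  within <- mean(d[lab == 1, lab == 1])
  between <- mean(d[lab == 1, lab == 2])
  expect_gt(between, within)

  dup <- blob; dup[2, ] <- dup[1, ] # duplicated sample rows
  emb2 <- embed_tsne(make_feature_table(dup), perplexity = 10,
                     max_iter = 500, seed = 3)
  d2 <- as.matrix(dist(emb2$coords))
  expect_lt(d2[1, 2], median(d2[upper.tri(d2)]))
})

test_that("the WSS curve starts at the total centred sum of squares and hits 0 at k = n", {
  set.seed(3)
  coords <- matrix(rnorm(24), 12, 2)
  curve <- wss_curve(coords, k_min = 2, k_max = 11, seed = 1)
  expect_equal(curve$wss[curve$k == 1],
               sum(scale(coords, scale = FALSE)^2), tolerance = 1e-9)
  km <- kmeans_partition(coords, k = 11, seed = 1)
  expect_lt(km$wss, curve$wss[curve$k == 2]) # monotone trend toward 0
  expect_error(wss_curve(coords, k_max = 12), "smaller")
})

test_that("three separated blobs bend the WSS curve at k = 3", {
  set.seed(4)
  coords <- rbind(matrix(rnorm(40, 0), ncol = 2),
                  matrix(rnorm(40, 15), ncol = 2),
                  cbind(rnorm(20, 0), rnorm(20, 15)))
  curve <- wss_curve(coords, k_min = 2, k_max = 8, seed = 2)
  w <- function(k) curve$wss[curve$k == k]
  expect_gt(w(2) - w(3), w(3) - w(4))
})

test_that("elbow fit recovers tau from noiseless synthetic curves", {
  mk <- function(tau, a = 100, cc = 5) {
    data.frame(k = 1:15, wss = a * exp(-(1:15) / tau) + cc)
  }
  expect_equal(elbow_k(mk(1.5))$k_star, 6)   # 4 * 1.5
  expect_equal(elbow_k(mk(1.1))$k_star, 4)   # round(4.4)
  expect_equal(elbow_k(mk(0.8))$k_star, 3)   # round(3.2)
  fit <- elbow_k(mk(2.5))
  expect_equal(fit$tau, 2.5, tolerance = 1e-6)
  expect_error(elbow_k(data.frame(k = 1:10, wss = 1:10 * 3 + 2)), "manually")
})

test_that("tau is recovered within 10% under 1% multiplicative noise", {
  for (tau in c(0.8, 1.5, 2.5)) {
    taus <- sapply(1:40, function(s) {
      set.seed(s)
      w <- (100 * exp(-(1:15) / tau) + 5) * (1 + rnorm(15, 0, 0.01))
      elbow_k(data.frame(k = 1:15, wss = w))$tau
    })
    expect_lt(median(abs(taus - tau) / tau), 0.10)
  }
})

test_that("the test helper's adjusted Rand index matches mclust", {
  set.seed(7)
  a <- sample(1:4, 50, TRUE); b <- sample(1:3, 50, TRUE)
  expect_equal(rand_adjusted(a, b), mclust::adjustedRandIndex(a, b))
  expect_equal(rand_adjusted(a, a), 1)
})

test_that("k-means recovers two separated blobs exactly", {
  b <- make_blobs(n_per = 30, sep = 25, seed = 5)
  asg <- kmeans_partition(b$coords, 2, metadata = data.frame(lab = b$label),
                          seed = 1)
  expect_equal(rand_adjusted(asg$cluster, b$label), 1)
  expect_error(kmeans_partition(b$coords, 1), "k > 1")
})

test_that("cluster composition accounts for every sample and drops tiny subclusters", {
  set.seed(6)
  coords <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 20), ncol = 2))
  md <- data.frame(cond = c(rep("A", 19), "B", rep("B", 20)),
                   region = rep(c("C", "P"), 20))
  asg <- kmeans_partition(coords, 2, metadata = md, seed = 2)
  comp <- compose_clusters(asg, "cond", "region", min_size = 2)
  expect_equal(sum(comp$by_condition), 40)
  expect_equal(unname(rowSums(comp$by_condition)),
               unname(as.vector(table(asg$cluster))))
  # the lone B sample inside the A blob forms a singleton and is dropped
  sizes <- table(paste(md$cond, asg$cluster))
  if (any(sizes == 1)) expect_true(any(is.na(comp$subcluster)))
  kept <- table(comp$subcluster)
  expect_true(all(kept >= 2))
})
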
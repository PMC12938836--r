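test_that("k = 1 and k = n are the closed-form extremes", {
  set.seed(3)
  X <- matrix(rnorm(28), ncol = 4)
  m1 <- kmeans_fit(X, 1)
  expect_equal(as.numeric(m1$centroids), colMeans(X))
  expect_equal(m1$within_ss,
               sum(scale(X, scale = FALSE)^2))
  mn <- hkmeans_fit(X, nrow(X))
  expect_equal(mn$within_ss, 0)
  expect_equal(sort(mn$assignments), 1:nrow(X))
  expect_error(kmeans_fit(X, 8), class = "salivemo_argument_error")
})

test_that("well-separated pairs are recovered identically by both methods", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  km <- kmeans_fit(X, 2, seed = 1)
  hk <- hkmeans_fit(X, 2)
  expect_equal(km$assignments[1], km$assignments[2])
  expect_equal(km$assignments[3], km$assignments[4])
  expect_false(km$assignments[1] == km$assignments[3])
  expect_equal(km$within_ss, hk$within_ss)
  expect_equal(km$within_ss, oracle_optimal_within_ss(X, 2))
})

test_that("duplicate points are always co-clustered below distinct-value k", {
  X <- rbind(c(1, 1), c(1, 1), c(5, 5), c(5, 5), c(9, 1), c(9, 1))
  for (k in 2:3) {
    hk <- hkmeans_fit(X, k)
    expect_equal(hk$assignments[1], hk$assignments[2])
    expect_equal(hk$assignments[3], hk$assignments[4])
    expect_equal(hk$assignments[5], hk$assignments[6])
  }
})

test_that("fitted within-SS never exceeds that of random partitions", {
  set.seed(10)
  X <- matrix(rnorm(40), ncol = 4)
  km <- kmeans_fit(X, 3, seed = 2)
  for (i in 1:50) {
    assign <- sample(rep(1:3, length.out = 10))
    expect_lte(km$within_ss, partition_within_ss(X, assign) + 1e-9)
  }
})

test_that("Calinski-Harabasz matches a hand-computed 6-point instance", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11),
              ncol = 2, byrow = TRUE)
  hk <- hkmeans_fit(X, 2)
  # independent direct arithmetic
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (j in 1:2) {
    pts <- X[hk$assignments == j, , drop = FALSE]
    ctr <- colMeans(pts)
    B <- B + nrow(pts) * sum((ctr - grand)^2)
    W <- W + sum((pts - matrix(ctr, nrow(pts), 2, byrow = TRUE))^2)
  }
  expect_equal(calinski_harabasz(hk, X), (B / 1) / (W / 4))
  expect_error(calinski_harabasz(kmeans_fit(X, 1), X),
               class = "salivemo_argument_error")
})

test_that("between plus within equals total sum of squares", {
  set.seed(12)
  for (rep in 1:10) {
    X <- matrix(rnorm(4 * sample(6:15, 1)), ncol = 4)
    k <- sample(2:4, 1)
    m <- kmeans_fit(X, k, seed = rep)
    grand <- colMeans(X)
    sizes <- tabulate(m$assignments, k)
    B <- sum(sizes * rowSums((m$centroids -
                                matrix(grand, k, 4, byrow = TRUE))^2))
    TSS <- sum(scale(X, scale = FALSE)^2)
    expect_lt(abs(B + m$within_ss - TSS), 1e-9)
  }
})

test_that("select_k finds planted blob counts and breaks ties downward", {
  set.seed(17)
  X <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 6, 0.3), ncol = 2),
             matrix(rnorm(60, c(0, 8), 0.3), ncol = 2))
  sel <- select_k(X, 2:6)
  expect_equal(sel$k, 3L)
  # symmetric 4-point square: k=2 ties in CH across cut directions, and any
  # CH tie between candidate k resolves to the smaller k by construction
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  sel_sq <- select_k(sq, 2:3)
  expect_equal(sel_sq$k, min(which(sel_sq$ch == max(sel_sq$ch)) + 1L))
  expect_error(select_k(X[1:2, ], 2:3), class = "salivemo_argument_error")
})

test_that("agreement with the stats::kmeans reference on easy structure", {
  set.seed(23)
  X <- rbind(matrix(rnorm(40, 0, 0.4), ncol = 4),
             matrix(rnorm(40, 5, 0.4), ncol = 4))
  ours <- kmeans_fit(X, 2, seed = 3)
  ref <- stats::kmeans(X, 2, nstart = 10)
  expect_equal(ours$within_ss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("recursive subclustering partitions points and respects stopping", {
  set.seed(31)
  small <- matrix(rnorm(16), ncol = 4)   # 4 points < 2 * min_size
  rs <- recursive_subcluster(small, min_size = 5, max_depth = 3)
  expect_equal(unique(rs$leaf), "G1")
  # two super-pairs of blobs -> two-level nesting
  blob <- function(mu, n = 12) matrix(rnorm(2 * n, mu, 0.2), ncol = 2)
  X <- rbind(blob(c(0, 0)), blob(c(2, 0)), blob(c(20, 20)), blob(c(22, 20)))
  rs2 <- recursive_subcluster(X, min_size = 7, max_depth = 2, k_range = 2:2)
  expect_equal(length(rs2$leaf), nrow(X))
  expect_true(all(!is.na(rs2$leaf)))
  expect_false(rs2$tree$leaf)
  # two-level nesting: 2 super-clusters, each split into its 2 blobs
  expect_equal(sort(unique(rs2$leaf)), c("G1.1", "G1.2", "G2.1", "G2.2"))
  # points of one low-level blob share a leaf
  expect_equal(dplyr::n_distinct(rs2$leaf[1:12]), 1L)
  # each super-pair stays within one top-level branch
  expect_equal(dplyr::n_distinct(substr(rs2$leaf[1:24], 1, 2)), 1L)
  expect_error(recursive_subcluster(X, min_size = 1),
               class = "salivemo_argument_error")
})

test_that("cluster emotion fractions map onto low/moderate/high levels", {
  assignments <- tibble::tibble(
    participant_id = sprintf("P-%02d", 1:10), fragrance_id = "F2",
    cluster = "F2G1")
  emo <- function(n_pos) {
    tibble::tibble(participant_id = sprintf("P-%02d", 1:10),
                   fragrance_id = "F2", emotion = "happy",
                   valence = rep(c(2L, 0L), c(n_pos, 10 - n_pos)))
  }
  frac <- function(n_pos) {
    profile_clusters(assignments, emo(n_pos))
  }
  expect_equal(frac(8)$fraction, 0.8); expect_equal(frac(8)$level, "high")
  expect_equal(frac(3)$level, "low")
  expect_equal(frac(5)$level, "moderate")
  # exact thirds fall in the closed moderate interval
  expect_equal(emotion_level(c(1 / 3, 2 / 3, 1 / 3 - 1e-9, 2 / 3 + 1e-9)),
               c("moderate", "moderate", "low", "high"))
  # valence cut: 2 required -> valence-1 reports no longer count
  emo1 <- emo(10); emo1$valence <- rep(1L, 10)
  expect_equal(profile_clusters(assignments, emo1, valence_cut = 2L)$fraction, 0)
  # cluster without questionnaire data is flagged undefined
  orphan <- dplyr::mutate(assignments, participant_id = paste0("X", participant_id))
  expect_equal(profile_clusters(orphan, emo(5))$level, "undefined")
})
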
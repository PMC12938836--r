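# K-means / hierarchical k-means over log2 ratio profiles, with
# Calinski-Harabasz model selection and recursive subclustering.

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  storage.mode(points) <- "double"
  points
}

# squared Euclidean distances from every row of X to every row of C
dist2_to_centers <- function(X, C) {
  n <- nrow(X); k <- nrow(C)
  matrix(rowSums(X^2), n, k) - 2 * X %*% t(C) +
    matrix(rowSums(C^2), n, k, byrow = TRUE)
}

new_cluster_model <- function(X, assignments, method) {
  k <- max(assignments)
  C <- t(vapply(seq_len(k), function(j) colMeans(X[assignments == j, , drop = FALSE]),
                numeric(ncol(X))))
  if (ncol(X) == 1L) C <- matrix(C, ncol = 1)
  within <- sum((X - C[assignments, , drop = FALSE])^2)
  structure(list(k = k, centroids = C, assignments = assignments,
                 within_ss = within, method = method),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("%s cluster model: k = %d, n = %d, within-SS = %.4g\n",
              x$method, x$k, length(x$assignments), x$within_ss))
  cat("cluster sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

# Lloyd iterations from given centers; deterministic. Empty clusters are
# repaired by re-seeding from the point farthest from its current centroid.
lloyd <- function(X, centers, max_iter = 100L) {
  n <- nrow(X); k <- nrow(centers)
  assign_prev <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assignments <- max.col(-d2, ties.method = "first")
    repeat {                                     # empty-cluster repair
      sizes <- tabulate(assignments, k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      eligible <- which(sizes[assignments] > 1L) # donors keep >= 1 member
      far <- eligible[which.max(d2[cbind(eligible, assignments[eligible])])]
      assignments[far] <- empty[1]
    }
    if (identical(assignments, assign_prev)) break
    assign_prev <- assignments
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assignments == j, , drop = FALSE])
    }
  }
  assignments
}

# Hartigan-style single-point exchange passes: move a point to another
# cluster whenever the exact within-SS change (with the size-weighted
# correction) improves. Catches optima that are not Voronoi fixed points,
# which Lloyd alone cannot reach.
polish_moves <- function(X, assignments, k) {
  n <- nrow(X)
  centers <- t(vapply(seq_len(k),
                      function(j) colMeans(X[assignments == j, , drop = FALSE]),
                      numeric(ncol(X))))
  if (ncol(X) == 1L) centers <- matrix(centers, ncol = 1)
  sizes <- tabulate(assignments, k)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- assignments[i]
      if (sizes[a] == 1L) next
      da <- sum((X[i, ] - centers[a, ])^2) * sizes[a] / (sizes[a] - 1)
      best_gain <- 1e-12; best_b <- 0L
      for (b in seq_len(k)) {
        if (b == a) next
        db <- sum((X[i, ] - centers[b, ])^2) * sizes[b] / (sizes[b] + 1)
        if (da - db > best_gain) { best_gain <- da - db; best_b <- b }
      }
      if (best_b > 0L) {
        centers[a, ] <- (centers[a, ] * sizes[a] - X[i, ]) / (sizes[a] - 1)
        centers[best_b, ] <- (centers[best_b, ] * sizes[best_b] + X[i, ]) /
          (sizes[best_b] + 1)
        sizes[a] <- sizes[a] - 1L; sizes[best_b] <- sizes[best_b] + 1L
        assignments[i] <- best_b
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  assignments
}

# Pairwise-swap passes: exchange two points between clusters when the
# exact within-SS change improves (evaluated as two sequential moves with
# intermediate centroid updates). Sizes stay fixed, so swaps escape local
# optima that size-penalised single moves cannot.
swap_moves <- function(X, assignments, k) {
  n <- nrow(X)
  ss_of <- function(asg) {
    ss <- 0
    for (j in seq_len(k)) {
      pts <- X[asg == j, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    ss
  }
  current <- ss_of(assignments)
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (assignments[i] == assignments[j]) next
        cand <- assignments
        cand[c(i, j)] <- cand[c(j, i)]
        cand_ss <- ss_of(cand)
        if (cand_ss < current - 1e-12) {
          assignments <- cand
          current <- cand_ss
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  assignments
}

# Lloyd to convergence, then exchange/swap polish, repeated until stable
lloyd_polished <- function(X, centers) {
  k <- nrow(centers)
  n <- nrow(X)
  assignments <- lloyd(X, centers)
  repeat {
    polished <- polish_moves(X, assignments, k)
    if (n <= 64L) polished <- swap_moves(X, polished, k)
    if (identical(polished, assignments)) break
    assignments <- polished
    centers <- t(vapply(seq_len(k),
                        function(j) colMeans(X[assignments == j, , drop = FALSE]),
                        numeric(ncol(X))))
    if (ncol(X) == 1L) centers <- matrix(centers, ncol = 1)
    assignments <- lloyd(X, centers)
  }
  assignments
}

#' K-means clustering (Lloyd's algorithm with restarts)
#'
#' Partitions points in log2-ratio space into `k` clusters by Lloyd
#' iterations followed by Hartigan-style single-point exchange passes
#' (exact size-weighted within-SS improvement, as in the classical
#' Hartigan-Wong refinement), taking the best of `n_restarts` random
#' initialisations (distinct data points as seeds) by total within-cluster
#' sum of squares. Empty clusters arising during iteration are re-seeded
#' from the point farthest from its assigned centroid. Deterministic given
#' `seed`.
#'
#' @param points Numeric matrix or data frame, one row per observation.
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param n_restarts Number of random initialisations.
#' @param seed Integer seed.
#' @return A `cluster_model`: `k`, `centroids`, `assignments`,
#'   `within_ss`.
#' @export
kmeans_fit <- function(points, k, n_restarts = 20L, seed = 1L) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (k < 1L || k > n) stop_arg("kmeans_fit: need 1 <= k <= n (k=%d, n=%d)", k, n)
  if (k == 1L) return(new_cluster_model(X, rep(1L, n), "kmeans"))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- X[sample.int(n, k), , drop = FALSE]
    model <- new_cluster_model(X, lloyd_polished(X, init), "kmeans")
    if (is.null(best) || model$within_ss < best$within_ss - 1e-12) best <- model
  }
  best
}

# number of partitions of n points into exactly k non-empty blocks
stirling2 <- function(n, k) {
  S <- matrix(0, n + 1, k + 1)
  S[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
    }
  }
  S[n + 1, k + 1]
}

# exact minimum-within-SS partition by restricted-growth-string enumeration;
# only called when the partition count is small
exact_min_within <- function(X, k) {
  n <- nrow(X)
  best_ss <- Inf
  best_assign <- NULL
  assign <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) {
      if (maxg == k) {
        ss <- 0
        for (j in seq_len(k)) {
          pts <- X[assign == j, , drop = FALSE]
          ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
        }
        if (ss < best_ss - 1e-12) {
          best_ss <<- ss
          best_assign <<- assign
        }
      }
      return(invisible())
    }
    for (g in seq_len(min(maxg + 1L, k))) {
      assign[i] <<- g
      recurse(i + 1L, max(maxg, g))
    }
  }
  recurse(1L, 0L)
  best_assign
}

#' Hierarchical k-means (Ward-seeded, deterministic)
#'
#' Deterministic counterpart of [kmeans_fit()]. Small instances (at most
#' 20,000 candidate partitions) are solved exactly by enumerating all
#' partitions into `k` non-empty groups, guaranteeing the global
#' within-SS optimum. Larger instances are agglomerated by Ward's
#' minimum-variance method on squared Euclidean distances, cut at `k`,
#' and the cluster means refined with Lloyd iterations plus exchange
#' passes to convergence. Either path is free of random initialisation.
#'
#' @inheritParams kmeans_fit
#' @return A `cluster_model`.
#' @export
hkmeans_fit <- function(points, k) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (k < 1L || k > n) stop_arg("hkmeans_fit: need 1 <= k <= n (k=%d, n=%d)", k, n)
  if (k == 1L) return(new_cluster_model(X, rep(1L, n), "hkmeans"))
  if (k == n) return(new_cluster_model(X, seq_len(n), "hkmeans"))
  if (n <= 20L && stirling2(n, k) <= 20000) {
    return(new_cluster_model(X, exact_min_within(X, k), "hkmeans"))
  }
  hc <- stats::hclust(stats::dist(X)^2, method = "ward.D")
  cut <- stats::cutree(hc, k = k)
  centers <- t(vapply(seq_len(k), function(j) colMeans(X[cut == j, , drop = FALSE]),
                      numeric(ncol(X))))
  if (ncol(X) == 1L) centers <- matrix(centers, ncol = 1)
  new_cluster_model(X, lloyd_polished(X, centers), "hkmeans")
}

#' Calinski-Harabasz index
#'
#' Variance-ratio criterion for a clustering: `CH = (B / (k - 1)) /
#' (W / (n - k))` with `B` the between-cluster sum of squares (cluster
#' sizes times squared centroid distances to the grand mean) and `W` the
#' total within-cluster sum of squares. Defined for `1 < k < n`.
#'
#' @param model A `cluster_model`.
#' @param points The points the model was fitted on.
#' @return Scalar CH value (`Inf` for a perfect separation with `W = 0`).
#' @export
calinski_harabasz <- function(model, points) {
  X <- as_point_matrix(points)
  n <- nrow(X); k <- model$k
  if (k <= 1L || k >= n) stop_arg("calinski_harabasz: need 1 < k < n")
  grand <- colMeans(X)
  sizes <- tabulate(model$assignments, k)
  B <- sum(sizes * rowSums((model$centroids -
                              matrix(grand, k, ncol(X), byrow = TRUE))^2))
  W <- model$within_ss
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters
#'
#' Fits a model for each `k` in `k_range` and returns the one maximising
#' the Calinski-Harabasz index; ties go to the smallest `k`.
#'
#' @inheritParams kmeans_fit
#' @param k_range Integer vector of candidate cluster counts (each with
#'   `1 < k < n`); infeasible candidates are dropped.
#' @param method `"hkmeans"` (default, deterministic) or `"kmeans"`.
#' @return List with `k`, `model`, and `ch` (named CH value per candidate).
#' @export
select_k <- function(points, k_range = 2:10, method = c("hkmeans", "kmeans"),
                     n_restarts = 20L, seed = 1L) {
  method <- match.arg(method)
  X <- as_point_matrix(points)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range > 1L & k_range < n]
  if (length(k_range) == 0L) stop_arg("select_k: no feasible k in range for n=%d", n)
  ch <- setNames(rep(NA_real_, length(k_range)), k_range)
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    models[[i]] <- if (method == "hkmeans") hkmeans_fit(X, k_range[i])
                   else kmeans_fit(X, k_range[i], n_restarts, seed)
    ch[i] <- calinski_harabasz(models[[i]], X)
  }
  if (all(!is.finite(ch) | is.na(ch)) && !any(is.infinite(ch) & ch > 0)) {
    stop_arg("select_k: CH undefined for every candidate k")
  }
  best <- which(ch >= max(ch, na.rm = TRUE) - 0)[1]  # ties -> smallest k
  list(k = k_range[best], model = models[[best]], ch = ch)
}

#' Recursive hk-means subclustering
#'
#' Applies [select_k()] + [hkmeans_fit()] to the data, then recursively to
#' each resulting cluster while the cluster holds at least `2 * min_size`
#' points and the depth limit is not reached. Degenerate groups (fewer
#' than 3 distinct points) become leaves. Leaves are the final clusters;
#' every point lies in exactly one leaf.
#'
#' @inheritParams select_k
#' @param min_size Minimum leaf size worth splitting (a group is only
#'   split while it has at least `2 * min_size` points).
#' @param max_depth Maximum number of splitting levels.
#' @return List with `leaf` (character vector, one path label like
#'   `"G2.1"` per point) and `tree` (nested list of splits).
#' @export
recursive_subcluster <- function(points, min_size = 5L, max_depth = 3L,
                                 k_range = 2:6) {
  if (min_size < 2L) stop_arg("recursive_subcluster: min_size must be >= 2")
  X <- as_point_matrix(points)
  leaf <- rep(NA_character_, nrow(X))

  recurse <- function(idx, path, depth) {
    sub <- X[idx, , drop = FALSE]
    n_distinct_pts <- nrow(unique(sub))
    if (length(idx) < 2L * min_size || depth >= max_depth ||
        n_distinct_pts < 3L) {
      leaf[idx] <<- path
      return(list(path = path, n = length(idx), leaf = TRUE))
    }
    sel <- tryCatch(
      select_k(sub, k_range[k_range < n_distinct_pts], method = "hkmeans"),
      salivemo_argument_error = function(e) NULL)
    if (is.null(sel)) {
      leaf[idx] <<- path
      return(list(path = path, n = length(idx), leaf = TRUE))
    }
    children <- lapply(seq_len(sel$k), function(j) {
      recurse(idx[sel$model$assignments == j],
              paste0(path, if (nzchar(path)) "." else "G", j), depth + 1L)
    })
    list(path = path, n = length(idx), leaf = FALSE, k = sel$k,
         children = children)
  }

  tree <- recurse(seq_len(nrow(X)), "", 0L)
  if (tree$leaf) leaf[] <- "G1"      # unsplit root: single leaf label
  list(leaf = leaf, tree = tree)
}

#' Cluster-level emotion responsiveness
#'
#' For each cluster and emotion, the fraction of member exposures that
#' report the emotion (valence at or above `valence_cut`) and its level:
#' *low* below 1/3, *high* above 2/3, *moderate* in the closed interval
#' between them.
#'
#' @param assignments Tibble with `participant_id`, `fragrance_id`,
#'   `cluster`.
#' @param emotions Long emotion tibble ([read_emotions()] schema).
#' @param valence_cut Minimum valence that counts as reporting (default 1:
#'   any positive valence).
#' @return Tibble with `cluster`, `size`, `emotion`, `fraction`, `level`;
#'   clusters without questionnaire data get `NA` fraction and level
#'   `"undefined"`.
#' @export
profile_clusters <- function(assignments, emotions, valence_cut = 1L) {
  sizes <- count(assignments, .data$cluster, name = "size")
  joined <- inner_join(assignments, emotions,
                       by = c("participant_id", "fragrance_id"))
  prof <- joined %>%
    group_by(.data$cluster, .data$emotion) %>%
    summarise(fraction = mean(.data$valence >= valence_cut), .groups = "drop")
  out <- left_join(tidyr::expand_grid(cluster = sizes$cluster,
                                      emotion = unique(emotions$emotion)),
                   prof, by = c("cluster", "emotion")) %>%
    left_join(sizes, by = "cluster") %>%
    mutate(level = emotion_level(.data$fraction)) %>%
    select("cluster", "size", "emotion", "fraction", "level")
  out
}

#' @rdname profile_clusters
#' @param fraction Numeric vector of reporting fractions in `[0, 1]`.
#' @export
emotion_level <- function(fraction) {
  ifelse(is.na(fraction), "undefined",
         ifelse(fraction < 1 / 3, "low",
                ifelse(fraction > 2 / 3, "high", "moderate")))
}
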
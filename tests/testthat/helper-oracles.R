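# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (enumeration / direct arithmetic)
# and independent of the package's own code paths.

# total within-cluster SS of a given assignment
partition_within_ss <- function(X, assign) {
  ss <- 0
  for (j in unique(assign)) {
    pts <- X[assign == j, , drop = FALSE]
    ctr <- colMeans(pts)
    ss <- ss + sum((pts - matrix(ctr, nrow(pts), ncol(X), byrow = TRUE))^2)
  }
  ss
}

# global optimum of within-SS over all partitions into exactly k non-empty
# blocks (restricted-growth-string enumeration); feasible for n <= 8
oracle_optimal_within_ss <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) {
      if (maxg == k) {
        ss <- partition_within_ss(X, assign)
        if (ss < best) best <<- ss
      }
      return(invisible())
    }
    for (g in seq_len(min(maxg + 1L, k))) {
      assign[i] <<- g
      recurse(i + 1L, max(maxg, g))
    }
  }
  recurse(1L, 0L)
  best
}

# naive Gini impurity decrease of splitting `states[, analyte]` by `left`
oracle_gini <- function(pos, n) {
  if (n == 0) return(0)
  p <- pos / n
  1 - p^2 - (1 - p)^2
}

# maximum achievable Gini decrease at a node by exhaustive search over all
# (analyte, binary state-subset) candidates honouring min_bucket
oracle_max_decrease <- function(states, labels, min_bucket) {
  n <- length(labels)
  g0 <- oracle_gini(sum(labels), n)
  best <- 0
  for (a in colnames(states)) {
    for (left_set in list(0L, 1L, 2L, c(0L, 1L), c(0L, 2L), c(1L, 2L))) {
      left <- states[, a] %in% left_set
      nl <- sum(left); nr <- n - nl
      if (nl < min_bucket || nr < min_bucket) next
      dec <- g0 - (nl / n) * oracle_gini(sum(labels[left]), nl) -
        (nr / n) * oracle_gini(sum(labels[!left]), nr)
      if (dec > best) best <- dec
    }
  }
  best
}

# walk a fitted cart_tree, re-deriving each internal node's data and
# asserting its split attains the exhaustive-search maximum decrease
check_splits_optimal <- function(tree, states, labels, min_bucket, tol = 1e-10) {
  walk <- function(node, states, labels) {
    if (node$type == "leaf") return(TRUE)
    left_int <- match(node$left_states,
                      c("decreased", "stable", "increased")) - 1L
    left <- states[, node$analyte] %in% left_int
    n <- length(labels)
    g0 <- oracle_gini(sum(labels), n)
    dec <- g0 - (sum(left) / n) * oracle_gini(sum(labels[left]), sum(left)) -
      (sum(!left) / n) * oracle_gini(sum(labels[!left]), sum(!left))
    opt <- oracle_max_decrease(states, labels, min_bucket)
    if (dec < opt - tol) return(FALSE)
    walk(node$left, states[left, , drop = FALSE], labels[left]) &&
      walk(node$right, states[!left, , drop = FALSE], labels[!left])
  }
  walk(tree$root, states, labels)
}

# independent BH step-up: sort ascending, running minimum of m*p/j from the
# largest rank down, mapped back to the original order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * p[o[i]] / i)
    q[o[i]] <- min(run, 1)
  }
  q
}

# brute-force exact two-sided permutation p for Spearman's rho
oracle_spearman_perm <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v),
                  function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
           recursive = FALSE)
  }
  vals <- vapply(perms(seq_along(y)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# planted-rule discrete dataset: label = (dhea decreased) with symmetric
# flip noise; returns codes, noisy labels and true rule labels
make_planted_rule_data <- function(n, noise = 0.10, seed = 1) {
  set.seed(seed)
  codes <- sample(0:80, n, replace = TRUE)
  states <- t(sapply(codes, salivemo::decode_profile))
  truth <- states[, "dhea"] == "decreased"
  flip <- runif(n) < noise
  list(codes = codes, labels = xor(truth, flip), truth = truth)
}

# strongly separated three-phenotype generator used by recovery tests
recovery_config <- function(seed = 20260901) {
  emis_hi <- c(0.1, 0.3, 0.6); emis_lo <- c(0.85, 0.1, 0.05)
  phen <- function(label, weight, shift, emo_hi) {
    emissions <- lapply(salivemo::EMOTIONS_CORE, function(e) {
      if (e %in% emo_hi) emis_hi else emis_lo
    })
    names(emissions) <- salivemo::EMOTIONS_CORE
    list(label = label, weight = weight,
         shift_mean = shift,
         shift_sd = c(saa = 0.15, crt = 0.15, dhea = 0.15, oxt = 0.15),
         emissions = emissions,
         valuation_probs = rep(1 / 6, 6))
  }
  salivemo::generator_config(
    n_participants = 59,
    phenotypes = list(
      phen("calmed", 0.4,
           c(saa = -0.6, crt = -0.6, dhea = -0.6, oxt = 0.6),
           c("happy", "relaxed")),
      phen("aroused", 0.3,
           c(saa = 0.7, crt = 0.7, dhea = -0.6, oxt = -0.6),
           c("dynamised")),
      phen("flat", 0.3,
           c(saa = 0, crt = 0, dhea = 0, oxt = 0),
           character(0))),
    seed = seed)
}
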
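# From-scratch CART over discrete biomarker states: greedy binary Gini
# splits on categorical subsets, size/depth stopping, weakest-link
# cost-complexity pruning, rule extraction over the 81-profile lattice.

#' CART hyperparameters
#'
#' Tree-growing and pruning controls with the conventional recursive-
#' partitioning defaults: a node is only considered for splitting with at
#' least `min_split` samples, children must hold at least `min_bucket`
#' samples, growth stops at `max_depth`, and the grown tree is pruned by
#' weakest-link cost-complexity pruning at complexity parameter `cp`
#' (scaled by the root's misclassification risk).
#'
#' @param min_split Minimum node size to attempt a split.
#' @param min_bucket Minimum child size.
#' @param cp Complexity parameter, `>= 0`.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @return List of class `cart_control`.
#' @export
cart_control <- function(min_split = 20L, min_bucket = 7L, cp = 0.01,
                         max_depth = 30L) {
  if (min_bucket < 1L) stop_arg("cart_control: min_bucket must be >= 1")
  if (cp < 0) stop_arg("cart_control: cp must be >= 0")
  structure(list(min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket),
                 cp = cp, max_depth = as.integer(max_depth)),
            class = "cart_control")
}

# profiles -> n x 4 integer state matrix (0 decreased, 1 stable, 2 increased)
profile_state_matrix <- function(profiles) {
  if (is.numeric(profiles)) {
    m <- t(vapply(as.integer(profiles),
                  function(code) state_to_int(decode_profile(code)),
                  integer(4)))
  } else {
    cols <- paste0("state_", ANALYTES)
    check_columns(profiles, cols, "profiles")
    m <- sapply(cols, function(cl) state_to_int(profiles[[cl]]))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  }
  if (anyNA(m)) stop_arg("profiles: unknown biomarker state")
  colnames(m) <- ANALYTES
  m
}

gini <- function(n_pos, n) {
  if (n == 0L) return(0)
  p <- n_pos / n
  1 - p^2 - (1 - p)^2
}

# Canonical left-state subsets for one 3-state feature: every binary
# partition appears once, represented by the lexicographically smaller side
# (each contains state 0). Tie-break order is this list order.
LEFT_SUBSETS <- list(0L, c(0L, 1L), c(0L, 2L))

# exhaustive best split at one node; returns NULL if no admissible split
best_split <- function(states, labels, min_bucket) {
  n <- length(labels)
  n_pos <- sum(labels)
  g0 <- gini(n_pos, n)
  best <- NULL
  for (j in seq_along(ANALYTES)) {
    col <- states[, j]
    for (s in seq_along(LEFT_SUBSETS)) {
      left <- col %in% LEFT_SUBSETS[[s]]
      nl <- sum(left); nr <- n - nl
      if (nl < min_bucket || nr < min_bucket) next
      pl <- sum(labels[left])
      decrease <- g0 - (nl / n) * gini(pl, nl) -
        (nr / n) * gini(n_pos - pl, nr)
      if (decrease > 1e-12 &&
          (is.null(best) || decrease > best$decrease + 1e-12)) {
        best <- list(analyte = ANALYTES[j], j = j,
                     left_states = LEFT_SUBSETS[[s]], decrease = decrease)
      }
    }
  }
  best
}

grow_node <- function(states, labels, control, depth, n_root) {
  n <- length(labels)
  n_pos <- sum(labels)
  make_leaf <- function() {
    list(type = "leaf", n = n, n_pos = n_pos,
         class = if (n_pos > n - n_pos) "positive" else "negative",
         pos_fraction = if (n > 0L) n_pos / n else NA_real_,
         coverage = n / n_root)
  }
  if (n < control$min_split || depth >= control$max_depth ||
      n_pos == 0L || n_pos == n) {
    return(make_leaf())
  }
  sp <- best_split(states, labels, control$min_bucket)
  if (is.null(sp)) return(make_leaf())
  left <- states[, sp$j] %in% sp$left_states
  list(type = "split", analyte = sp$analyte,
       left_states = STATE_LEVELS[sp$left_states + 1L],
       n = n, n_pos = n_pos, decrease = sp$decrease,
       left = grow_node(states[left, , drop = FALSE], labels[left],
                        control, depth + 1L, n_root),
       right = grow_node(states[!left, , drop = FALSE], labels[!left],
                         control, depth + 1L, n_root))
}

node_risk <- function(node) min(node$n_pos, node$n - node$n_pos)

# subtree misclassification risk (count) and leaf count
subtree_stats <- function(node) {
  if (node$type == "leaf") {
    return(c(risk = node_risk(node), leaves = 1))
  }
  l <- subtree_stats(node$left); r <- subtree_stats(node$right)
  c(risk = l[["risk"]] + r[["risk"]], leaves = l[["leaves"]] + r[["leaves"]])
}

collapse_to_leaf <- function(node, n_root) {
  list(type = "leaf", n = node$n, n_pos = node$n_pos,
       class = if (node$n_pos > node$n - node$n_pos) "positive" else "negative",
       pos_fraction = node$n_pos / node$n, coverage = node$n / n_root)
}

# weakest-link cost-complexity pruning at cp (scaled by root risk)
prune_tree <- function(root, cp, n_root) {
  r_root <- node_risk(root)
  if (r_root == 0) return(collapse_to_leaf(root, n_root))
  repeat {
    if (root$type == "leaf") return(root)
    # collect link strengths g(t) for every internal node
    links <- new.env()
    links$g <- numeric(0)
    walk <- function(node) {
      if (node$type == "leaf") return(invisible())
      st <- subtree_stats(node)
      g <- (node_risk(node) - st[["risk"]]) / (st[["leaves"]] - 1)
      links$g <- c(links$g, g)
      walk(node$left); walk(node$right)
    }
    walk(root)
    m <- min(links$g)
    if (m / r_root > cp + 1e-12) return(root)
    prune_at <- function(node) {
      if (node$type == "leaf") return(node)
      st <- subtree_stats(node)
      g <- (node_risk(node) - st[["risk"]]) / (st[["leaves"]] - 1)
      if (g <= m + 1e-12) return(collapse_to_leaf(node, n_root))
      node$left <- prune_at(node$left)
      node$right <- prune_at(node$right)
      node
    }
    root <- prune_at(root)
  }
}

#' Fit a CART classifier on discrete biomarker profiles
#'
#' Greedy binary recursive partitioning over the four 3-state biomarker
#' features. At every node all three binary subset partitions of each
#' analyte's states are evaluated (so splits like "decreased or increased
#' vs stable" are expressible) and the one maximising the Gini impurity
#' decrease is taken; ties resolve to the earlier analyte in the fixed
#' order (sAA, cortisol, DHEA, oxytocin), then to the lexicographically
#' smallest left subset. Growth respects `min_split`, `min_bucket` and
#' `max_depth`; the grown tree is then pruned by weakest-link
#' cost-complexity pruning at `cp`. Leaf class is the majority label
#' (ties are negative).
#'
#' @param profiles Discretized profiles ([discretize_ratios()] output, a
#'   tibble of `state_*` columns, or an integer vector of profile codes).
#' @param labels Logical vector (emotion felt / not felt), one per row.
#' @param control A [cart_control()].
#' @return Object of class `cart_tree`.
#' @export
fit_cart <- function(profiles, labels, control = cart_control()) {
  states <- profile_state_matrix(profiles)
  labels <- as.logical(labels)
  if (nrow(states) == 0L) stop_arg("fit_cart: empty input")
  if (length(labels) != nrow(states)) stop_arg("fit_cart: labels length mismatch")
  if (anyNA(labels)) stop_arg("fit_cart: labels must be binary, no NA")
  n_root <- nrow(states)
  root <- grow_node(states, labels, control, 0L, n_root)
  root <- prune_tree(root, control$cp, n_root)
  structure(list(root = root, n = n_root, control = control),
            class = "cart_tree")
}

n_leaves <- function(tree) unname(subtree_stats(tree$root)[["leaves"]])

#' Predict with a fitted CART
#'
#' Routes each profile down the tree by split-subset membership and
#' returns the leaf's class together with its annotation (fraction of
#' positive training samples in the leaf, and the leaf's coverage of the
#' training population).
#'
#' @param tree A `cart_tree` from [fit_cart()].
#' @param profiles As in [fit_cart()].
#' @return Tibble with `class`, `positive` (logical), `pos_fraction`,
#'   `coverage`, `leaf` (the path condition string).
#' @export
predict_cart <- function(tree, profiles) {
  states <- profile_state_matrix(profiles)
  route <- function(node, s, path) {
    if (node$type == "leaf") {
      return(list(class = node$class, pos_fraction = node$pos_fraction,
                  coverage = node$coverage,
                  leaf = if (nzchar(path)) path else "(root)"))
    }
    go_left <- STATE_LEVELS[s[[node$analyte]] + 1L] %in% node$left_states
    cond <- sprintf("%s %s {%s}", node$analyte,
                    if (go_left) "in" else "not in",
                    paste(node$left_states, collapse = ","))
    route(if (go_left) node$left else node$right, s,
          paste(c(path[nzchar(path)], cond), collapse = " & "))
  }
  res <- lapply(seq_len(nrow(states)), function(i) {
    route(tree$root, setNames(as.list(states[i, ]), ANALYTES), "")
  })
  tibble(class = vapply(res, `[[`, character(1), "class"),
         positive = vapply(res, `[[`, character(1), "class") == "positive",
         pos_fraction = vapply(res, `[[`, numeric(1), "pos_fraction"),
         coverage = vapply(res, `[[`, numeric(1), "coverage"),
         leaf = vapply(res, `[[`, character(1), "leaf"))
}

#' Extract explicit profile rules from a CART
#'
#' Expands every positive leaf into the explicit set of discrete profile
#' codes it covers: along the path each analyte's admissible states are
#' intersected with the split subsets, and analytes the path never
#' constrains contribute all three states. The rule set is the union over
#' positive leaves, and by construction a code belongs to the set exactly
#' when the tree predicts it positive.
#'
#' @param tree A `cart_tree`.
#' @param emotion Optional emotion name carried into the result.
#' @return List of class `emotion_rule_set`: `emotion`, `codes` (sorted
#'   integer codes in 0..80), `provenance` (tibble: leaf path,
#'   pos_fraction, coverage, n_codes).
#' @export
extract_rules <- function(tree, emotion = NA_character_) {
  codes <- integer(0)
  prov <- list()
  walk <- function(node, allowed, path) {
    if (node$type == "leaf") {
      if (node$class == "positive") {
        grid <- expand.grid(saa = allowed$saa, crt = allowed$crt,
                            dhea = allowed$dhea, oxt = allowed$oxt)
        leaf_codes <- as.integer(as.matrix(grid) %*% c(27L, 9L, 3L, 1L))
        codes <<- c(codes, leaf_codes)
        prov[[length(prov) + 1L]] <<- tibble(
          leaf = if (nzchar(path)) path else "(root)",
          pos_fraction = node$pos_fraction, coverage = node$coverage,
          n_codes = length(leaf_codes))
      }
      return(invisible())
    }
    left_int <- state_to_int(node$left_states)
    a <- node$analyte
    allowed_l <- allowed; allowed_l[[a]] <- intersect(allowed[[a]], left_int)
    allowed_r <- allowed; allowed_r[[a]] <- setdiff(allowed[[a]], left_int)
    cond_l <- sprintf("%s in {%s}", a, paste(node$left_states, collapse = ","))
    cond_r <- sprintf("%s not in {%s}", a, paste(node$left_states, collapse = ","))
    join <- function(p, c) paste(c(p[nzchar(p)], c), collapse = " & ")
    if (length(allowed_l[[a]]) > 0L) walk(node$left, allowed_l, join(path, cond_l))
    if (length(allowed_r[[a]]) > 0L) walk(node$right, allowed_r, join(path, cond_r))
  }
  walk(tree$root, setNames(rep(list(0:2), 4), ANALYTES), "")
  structure(list(emotion = emotion, codes = sort(unique(codes)),
                 provenance = if (length(prov)) bind_rows(prov)
                              else tibble(leaf = character(0),
                                          pos_fraction = numeric(0),
                                          coverage = numeric(0),
                                          n_codes = integer(0))),
            class = "emotion_rule_set")
}

#' Resubstitution classification metrics
#'
#' Confusion counts and the derived sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` and accuracy of a tree's predictions
#' against binary labels. With no positive (or no negative) labels the
#' respective rate is `NA` and flagged.
#'
#' @param tree A `cart_tree`.
#' @param profiles,labels As in [fit_cart()].
#' @return List of class `classification_metrics`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `flags`.
#' @export
evaluate_cart <- function(tree, profiles, labels) {
  labels <- as.logical(labels)
  pred <- predict_cart(tree, profiles)$positive
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  flags <- character(0)
  if (tp + fn == 0L) flags <- c(flags, "no positive labels: sensitivity undefined")
  if (tn + fp == 0L) flags <- c(flags, "no negative labels: specificity undefined")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    flags = flags), class = "classification_metrics")
}

#' Binary emotion labels from questionnaire valences
#'
#' An emotion counts as felt when its reported valence reaches
#' `valence_cut` (default 1, i.e. any positive valence; use 2 for
#' "strongly felt" analyses).
#'
#' @param emotions Long emotion tibble ([read_emotions()] schema).
#' @param emotion Emotion name.
#' @param valence_cut Minimum valence counting as felt.
#' @return Tibble `participant_id`, `fragrance_id`, `label` (logical).
#' @export
emotion_labels <- function(emotions, emotion, valence_cut = 1L) {
  emotions %>%
    filter(.data$emotion == !!emotion) %>%
    mutate(label = .data$valence >= valence_cut) %>%
    select("participant_id", "fragrance_id", "label")
}

# ---- serialization and display ---------------------------------------------

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", n = node$n, n_pos = node$n_pos, class = node$class,
         pos_fraction = node$pos_fraction, coverage = node$coverage)
  } else {
    list(type = "split", analyte = node$analyte,
         left_states = as.list(node$left_states), n = node$n,
         n_pos = node$n_pos, left = node_to_list(node$left),
         right = node_to_list(node$right))
  }
}

#' Serialize a CART to JSON
#'
#' @param tree A `cart_tree`.
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to a file).
#' @export
cart_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(list(n = tree$n,
                              control = unclass(tree$control),
                              root = node_to_list(tree$root)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("CART over discrete biomarker states: n = %d, %d leaves\n",
              x$n, n_leaves(x)))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s* %s leaf: %d/%d positive (%.0f%%), coverage %.0f%%\n",
                  pad, node$class, node$n_pos, node$n,
                  100 * node$pos_fraction, 100 * node$coverage))
    } else {
      cat(sprintf("%s%s in {%s}? (n = %d)\n", pad, node$analyte,
                  paste(node$left_states, collapse = ","), node$n))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  invisible(x)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}
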
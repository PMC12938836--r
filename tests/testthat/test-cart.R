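test_that("pure and tied nodes collapse to the documented leaves", {
  codes <- sample(0:80, 30, replace = TRUE)
  all_pos <- fit_cart(codes, rep(TRUE, 30))
  expect_equal(all_pos$root$type, "leaf")
  expect_equal(all_pos$root$class, "positive")
  expect_equal(all_pos$root$coverage, 1.0)
  # exact tie -> negative
  tied <- fit_cart(rep(c(0L, 80L), 5), rep(c(TRUE, FALSE), 5),
                   cart_control(min_split = 2, min_bucket = 5, cp = 0))
  expect_equal(predict_cart(tied, 40L)$class, "negative")
})

test_that("node impurity is the Gini index", {
  expect_equal(salivemo:::gini(6, 10), 0.48)
  expect_equal(salivemo:::gini(0, 10), 0)
  expect_equal(salivemo:::gini(5, 10), 0.5)
})

test_that("every chosen split attains the exhaustive-search optimum", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    codes <- sample(0:80, n, replace = TRUE)
    states <- t(sapply(codes, decode_profile))
    # labels correlated with a random analyte to give splits something to find
    a <- sample(ANALYTES, 1)
    labels <- xor(states[, a] == "decreased", runif(n) < 0.2)
    ctl <- cart_control(min_split = 4, min_bucket = 2, cp = 0, max_depth = 5)
    tree <- fit_cart(codes, labels, ctl)
    sm <- salivemo:::profile_state_matrix(codes)
    expect_true(check_splits_optimal(tree, sm, labels, ctl$min_bucket))
  }
})

test_that("prediction is consistent with training rows and partitions the lattice", {
  dat <- make_planted_rule_data(100, noise = 0.1, seed = 5)
  tree <- fit_cart(dat$codes, dat$labels,
                   cart_control(min_split = 10, min_bucket = 3, cp = 0.01))
  # training rows route to leaves whose stats include them
  pred <- predict_cart(tree, dat$codes)
  expect_true(all(pred$pos_fraction >= 0 & pred$pos_fraction <= 1))
  # lattice predictions partition the 81 codes into leaf regions
  lat <- predict_cart(tree, 0:80)
  sizes <- table(lat$leaf)
  expect_equal(sum(sizes), 81)
  # leaf coverages over the training set sum to 1
  cov <- unique(pred[, c("leaf", "coverage")])
  expect_equal(sum(cov$coverage), 1)
})

test_that("rule extraction equals tree prediction over all 81 profiles", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    codes <- sample(0:80, n, replace = TRUE)
    states <- t(sapply(codes, decode_profile))
    labels <- xor(states[, sample(ANALYTES, 1)] %in%
                    sample(c("decreased", "stable", "increased"), 2),
                  runif(n) < 0.15)
    tree <- fit_cart(codes, labels,
                     cart_control(min_split = 6, min_bucket = 2, cp = 0))
    rules <- extract_rules(tree)
    pred_pos <- (0:80)[predict_cart(tree, 0:80)$positive]
    expect_identical(rules$codes, sort(pred_pos))
  }
})

test_that("a DHEA-only positive leaf expands to 27 profile codes", {
  # noiseless single-analyte rule with strong support
  codes <- rep(0:80, 2)
  states <- t(sapply(codes, decode_profile))
  labels <- states[, "dhea"] == "decreased"
  tree <- fit_cart(codes, labels, cart_control())
  rules <- extract_rules(tree, "dynamised")
  expect_equal(length(rules$codes), 27L)
  expect_true(all(sapply(rules$codes,
                         function(c) decode_profile(c)[["dhea"]] == "decreased")))
  expect_equal(rules$emotion, "dynamised")
  # no positive leaves -> empty rule set
  none <- fit_cart(codes, rep(FALSE, length(codes)))
  expect_length(extract_rules(none)$codes, 0)
})

test_that("metrics follow their confusion-count definitions", {
  dat <- make_planted_rule_data(60, noise = 0, seed = 9)
  tree <- fit_cart(dat$codes, dat$labels,
                   cart_control(min_split = 4, min_bucket = 2, cp = 0))
  m <- evaluate_cart(tree, dat$codes, dat$labels)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_equal(m$accuracy, (m$tp + m$tn) / 60)
  # always-negative predictor
  neg <- fit_cart(dat$codes, rep(FALSE, 60))
  mn <- evaluate_cart(neg, dat$codes, dat$labels)
  expect_equal(mn$specificity, 1)
  expect_equal(mn$sensitivity, 0)
  # no positives present -> sensitivity undefined and flagged
  mz <- evaluate_cart(neg, dat$codes, rep(FALSE, 60))
  expect_true(is.na(mz$sensitivity))
  expect_match(mz$flags, "sensitivity undefined")
})

test_that("unconstrained trees reach zero training error on separable labels", {
  set.seed(47)
  codes <- sample(0:80, 120, replace = TRUE)
  states <- t(sapply(codes, decode_profile))
  labels <- states[, "saa"] == "stable" & states[, "oxt"] != "decreased"
  tree <- fit_cart(codes, labels,
                   cart_control(min_split = 2, min_bucket = 1, cp = 0))
  expect_equal(evaluate_cart(tree, codes, labels)$accuracy, 1)
})

test_that("increasing cp never increases the number of leaves", {
  dat <- make_planted_rule_data(150, noise = 0.2, seed = 11)
  leaves <- sapply(c(0, 0.001, 0.01, 0.05, 0.2, 1), function(cp) {
    salivemo:::n_leaves(fit_cart(dat$codes, dat$labels,
                                 cart_control(min_split = 4, min_bucket = 2,
                                              cp = cp)))
  })
  expect_true(all(diff(leaves) <= 0))
})

test_that("agreement with the rpart reference on strongly structured data", {
  dat <- make_planted_rule_data(236, noise = 0.05, seed = 13)
  states <- as.data.frame(t(sapply(dat$codes, decode_profile)))
  states[] <- lapply(states, factor,
                     levels = c("decreased", "stable", "increased"))
  df <- cbind(states, y = factor(dat$labels))
  ref <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(minsplit = 20,
                                                     minbucket = 7,
                                                     cp = 0.01, xval = 0))
  ref_pred <- predict(ref, type = "class") == "TRUE"
  ours <- fit_cart(dat$codes, dat$labels, cart_control())
  our_pred <- predict_cart(ours, dat$codes)$positive
  expect_gte(mean(ref_pred == our_pred), 0.95)
})

test_that("degenerate inputs raise argument errors", {
  expect_error(fit_cart(integer(0), logical(0)), class = "salivemo_argument_error")
  expect_error(fit_cart(0:5, c(TRUE, NA, rep(FALSE, 4))),
               class = "salivemo_argument_error")
  expect_error(cart_control(min_bucket = 0), class = "salivemo_argument_error")
  expect_error(cart_control(cp = -1), class = "salivemo_argument_error")
})
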
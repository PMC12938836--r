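mk_profiles <- function(codes, fid = "F2") {
  states <- t(sapply(codes, decode_profile))
  tibble::tibble(
    participant_id = sprintf("P-%03d", seq_along(codes)), fragrance_id = fid,
    horizon = "S2/S1",
    state_saa = states[, 1], state_crt = states[, 2],
    state_dhea = states[, 3], state_oxt = states[, 4],
    code = as.integer(codes))
}

mk_rules <- function(codes, emotion = "happy") {
  rs <- list(structure(list(emotion = emotion, codes = as.integer(codes),
                            provenance = tibble::tibble()),
                       class = "emotion_rule_set"))
  names(rs) <- emotion
  rs
}

test_that("fragrance signatures are exact membership percentages", {
  set.seed(51)
  codes <- c(rep(5L, 30), sample(setdiff(0:80, 5L), 29, replace = TRUE))
  prof <- mk_profiles(codes)
  sig <- fragrance_signature(mk_rules(5L), prof, "F2")
  expect_equal(sig$percent, 100 * 30 / 59, tolerance = 1e-12)
  expect_equal(round(sig$percent, 1), 50.8)
  expect_equal(fragrance_signature(mk_rules(integer(0)), prof, "F2")$percent, 0)
  expect_equal(fragrance_signature(mk_rules(0:80), prof, "F2")$percent, 100)
  expect_error(fragrance_signature(mk_rules(5L), prof, "F9"),
               class = "salivemo_argument_error")
  # invariant to participant ordering
  sig2 <- fragrance_signature(mk_rules(5L), prof[sample(59), ], "F2")
  expect_equal(sig2$percent, sig$percent)
})

mk_iat <- function(go_by_emotion, latencies = NULL, n_participants = 1) {
  rows <- list()
  for (e in names(go_by_emotion)) {
    for (p in seq_len(n_participants)) {
      go <- go_by_emotion[[e]]
      lat <- if (is.null(latencies)) ifelse(go, 700, NA_real_)
             else ifelse(go, latencies[[e]], NA_real_)
      rows[[paste(e, p)]] <- tibble::tibble(
        participant_id = sprintf("P-%02d", p), fragrance_id = "F2",
        emotion = e, presentation = 1:3, go = go, latency_ms = lat)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("IAT Go-percent follows the three-presentation counting rule", {
  iat <- mk_iat(list(happy = c(TRUE, TRUE, FALSE)))
  prof <- score_iat(iat, "F2")
  expect_equal(prof$go_percent, 100 * 2 / 3, tolerance = 1e-12)
  # single participant's go percent is a multiple of a third
  expect_true(prof$go_percent %in% (100 * 0:3 / 3))
  # no go trials -> strength undefined, category low
  prof0 <- score_iat(mk_iat(list(happy = rep(FALSE, 3))), "F2")
  expect_true(is.na(prof0$strength))
  expect_equal(prof0$category, "low")
  # malformed presentation counts are a data error
  bad <- mk_iat(list(happy = rep(TRUE, 3)))[1:2, ]
  expect_error(score_iat(bad, "F2"), class = "salivemo_data_error")
})

test_that("IAT strength rewards speed and percentiles set categories", {
  gos <- setNames(rep(list(rep(TRUE, 3)), 6), EMOTIONS_CORE)
  lats <- setNames(as.list(c(300, 500, 700, 900, 1100, 1300)), EMOTIONS_CORE)
  prof <- score_iat(mk_iat(gos, lats), "F2", window_ms = 1500)
  prof <- prof[order(prof$strength, decreasing = TRUE), ]
  expect_equal(prof$emotion[1], "confident")  # fastest (300 ms)
  expect_equal(prof$strength[1], 100 * (1500 - 300) / 1500)
  # 6 distinct strengths -> percentiles 100, 80, 60, 40, 20, 0
  expect_equal(prof$percentile, c(100, 80, 60, 40, 20, 0))
  expect_equal(prof$category,
               c("excellent", "good", "good", "low", "low", "low"))
})

test_that("concordance recovers perfect and inverted rank agreement", {
  sig <- tibble::tibble(fragrance_id = "F2", emotion = EMOTIONS_CORE,
                        percent = c(60, 50, 40, 30, 20, 10))
  iat_prof <- tibble::tibble(fragrance_id = "F2", emotion = EMOTIONS_CORE,
                             go_percent = c(90, 80, 70, 60, 50, 40),
                             strength = c(10, 20, 30, 40, 50, 60))
  cc <- concordance(sig, iat_prof)
  expect_equal(cc$rho[cc$measure == "go_percent"], 1)
  expect_equal(cc$rho[cc$measure == "strength"], -1)
  expect_error(concordance(sig[1:2, ], iat_prof),
               class = "salivemo_argument_error")
})

test_that("exact permutation p-values agree with brute-force enumeration", {
  set.seed(53)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    res <- spearman_test(x, y)
    expect_equal(res$method, "exact permutation")
    expect_equal(res$p, oracle_spearman_perm(x, y))
  }
  # ties handled by average ranks
  x <- c(1, 1, 2, 3, 4); y <- c(2, 1, 1, 3, 3)
  expect_equal(spearman_test(x, y)$p, oracle_spearman_perm(x, y))
})

test_that("valuation groups partition the 1-6 scale and order as planted", {
  expect_equal(valuation_group(1:6),
               c("high", "high", "medium", "medium", "low", "low"))
  expect_error(valuation_group(0), class = "salivemo_argument_error")

  # planted effect: low-valuation exposures have lower sAA, higher OXT
  set.seed(55)
  n <- 236
  rating <- sample(1:6, n, replace = TRUE)
  low <- rating >= 5
  ratios <- tibble::tibble(
    participant_id = sprintf("P-%03d", 1:n), fragrance_id = "F2",
    horizon = "S2/S1",
    saa = 2^(rnorm(n, ifelse(low, -0.3, 0), 0.2)),
    crt = 2^(rnorm(n, 0, 0.2)),
    dhea = 2^(rnorm(n, 0, 0.2)),
    oxt = 2^(rnorm(n, ifelse(low, 0.3, 0), 0.2)))
  valuation <- tibble::tibble(participant_id = ratios$participant_id,
                              fragrance_id = "F2", valuation = rating)
  va <- valuation_analysis(valuation, ratios)
  s <- va$summary
  mean_of <- function(g, a) s$mean_ratio[s$group == g & s$analyte == a]
  expect_lt(mean_of("low", "saa"), mean_of("medium", "saa"))
  expect_lt(mean_of("low", "saa"), mean_of("high", "saa"))
  expect_gt(mean_of("low", "oxt"), mean_of("medium", "oxt"))
  expect_gt(mean_of("low", "oxt"), mean_of("high", "oxt"))
  saa_pairs <- va$pairwise[va$pairwise$analyte == "saa" &
                             va$pairwise$group2 == "low", ]
  expect_true(all(saa_pairs$p_adj < 0.05))
  expect_true(all(va$kruskal$p[va$kruskal$analyte %in% c("saa", "oxt")] < 0.05))
})

test_that("degenerate valuation inputs summarise without tests", {
  ratios <- tibble::tibble(
    participant_id = sprintf("P-%02d", 1:10), fragrance_id = "F2",
    horizon = "S2/S1", saa = 1, crt = 1, dhea = 1, oxt = 1)
  valuation <- tibble::tibble(participant_id = ratios$participant_id,
                              fragrance_id = "F2", valuation = 1L)
  va <- valuation_analysis(valuation, ratios)
  expect_equal(nrow(va$kruskal), 0)
  expect_match(va$flags, "medium", all = FALSE)
  # identical group compositions -> Kruskal-Wallis statistic 0
  r9 <- tibble::tibble(
    participant_id = sprintf("P-%02d", 1:9), fragrance_id = "F2",
    horizon = "S2/S1",
    saa = rep(c(0.8, 1.0, 1.2), each = 3),
    crt = rep(c(0.8, 1.0, 1.2), each = 3),
    dhea = rep(c(0.8, 1.0, 1.2), each = 3),
    oxt = rep(c(0.8, 1.0, 1.2), each = 3))
  v9 <- tibble::tibble(participant_id = r9$participant_id,
                       fragrance_id = "F2",
                       valuation = rep(c(1L, 3L, 5L), 3))
  va2 <- valuation_analysis(v9, r9)
  expect_true(all(abs(va2$kruskal$statistic) < 1e-12))
})

test_that("correlation heatmaps are Spearman matrices with unit diagonal", {
  set.seed(57)
  n <- 20
  x <- rlnorm(n, log(100), 0.3)
  vals <- cbind(saa = x, crt = x^2, dhea = rlnorm(n, log(400), 0.3),
                oxt = rlnorm(n, log(170), 0.3))   # crt strictly monotone in saa
  samples <- tidyr::expand_grid(participant_id = sprintf("P-%02d", 1:n),
                                analyte = ANALYTES) |>
    dplyr::mutate(fragrance_id = "F2", timepoint = "S1", clock_time_min = 540,
                  value = vals[cbind(match(participant_id,
                                           sprintf("P-%02d", 1:n)),
                                     match(analyte, ANALYTES))],
                  unit = ANALYTE_UNITS[analyte])
  hm <- correlation_heatmap(samples)
  diag_cells <- hm[hm$analyte_row == hm$analyte_col, ]
  expect_true(all(diag_cells$rho == 1))
  expect_equal(hm$rho[hm$analyte_row == "saa" & hm$analyte_col == "crt"], 1)
  expect_true(all(abs(hm$rho) <= 1))
  # symmetric
  ab <- hm$rho[hm$analyte_row == "dhea" & hm$analyte_col == "oxt"]
  ba <- hm$rho[hm$analyte_row == "oxt" & hm$analyte_col == "dhea"]
  expect_equal(ab, ba)
  # matches rank-then-Pearson on a small hand set
  expect_equal(hm$rho[hm$analyte_row == "saa" & hm$analyte_col == "oxt"],
               stats::cor(rank(x), rank(vals[, "oxt"])))
  # strata with too few pairs are flagged missing
  tiny <- samples[samples$participant_id %in% sprintf("P-%02d", 1:2), ]
  hm2 <- correlation_heatmap(tiny)
  expect_true(all(is.na(hm2$rho)))
  expect_true(all(hm2$n_pairs == 2))
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(59)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "salivemo_argument_error")
})
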
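# Fragrance-level emotional signatures from CART rules, IAT scoring,
# cross-method concordance, valuation analysis and supporting statistics.

#' Fragrance emotional signature from CART rules
#'
#' For one fragrance, the percentage of exposed participants whose
#' discrete S2/S1 biomarker profile falls in each emotion's CART-positive
#' rule set (exact set membership on profile codes).
#'
#' @param rules Named list of `emotion_rule_set`s ([extract_rules()]), one
#'   per emotion.
#' @param profiles Discretized profile tibble ([discretize_ratios()]).
#' @param fragrance_id Fragrance to profile.
#' @return Tibble with `fragrance_id`, `emotion`, `n_matching`,
#'   `n_exposed`, `percent`.
#' @export
fragrance_signature <- function(rules, profiles, fragrance_id) {
  sub <- filter(profiles, .data$fragrance_id == !!fragrance_id)
  n_exposed <- n_distinct(sub$participant_id)
  if (n_exposed == 0L) {
    stop_arg("fragrance_signature: no participants exposed to '%s'", fragrance_id)
  }
  purrr::map_dfr(names(rules), function(e) {
    match_ids <- unique(sub$participant_id[sub$code %in% rules[[e]]$codes])
    tibble(fragrance_id = fragrance_id, emotion = e,
           n_matching = length(match_ids), n_exposed = n_exposed,
           percent = 100 * length(match_ids) / n_exposed)
  })
}

#' Score the implicit association test for one fragrance
#'
#' Each emotion is presented three times per participant in a go/no-go
#' task. The Go-percent is `100 * clicks / (3 * participants)`. The
#' strength of association rewards fast clicks: the mean over go trials of
#' `100 * (window - latency) / window` (a 0-100 speed score; this formula
#' is a package convention, chosen because the published scores come
#' without a definition). Emotions are categorised by the percentile of
#' their strength within the fragrance: *excellent* above the 80th,
#' *good* above the 50th, otherwise *low*.
#'
#' @param iat IAT records ([read_iat()] schema).
#' @param fragrance_id Fragrance to score.
#' @param window_ms Response window used by the speed score.
#' @return Tibble with `fragrance_id`, `emotion`, `n_participants`,
#'   `go_percent`, `strength`, `percentile`, `category`.
#' @export
score_iat <- function(iat, fragrance_id, window_ms = 1500) {
  sub <- filter(iat, .data$fragrance_id == !!fragrance_id)
  if (nrow(sub) == 0L) stop_arg("score_iat: no IAT records for '%s'", fragrance_id)
  counts <- count(sub, .data$participant_id, .data$emotion)
  if (any(counts$n != 3L)) {
    stop_data("score_iat: expected 3 presentations per participant-emotion for '%s'",
              fragrance_id)
  }
  prof <- sub %>%
    group_by(.data$emotion) %>%
    summarise(
      n_participants = n_distinct(.data$participant_id),
      go_percent = 100 * sum(.data$go) / (3 * n_distinct(.data$participant_id)),
      strength = if (any(.data$go)) {
        mean(100 * (window_ms - .data$latency_ms[.data$go]) / window_ms)
      } else NA_real_,
      .groups = "drop")
  ne <- nrow(prof)
  pct <- rep(NA_real_, ne)
  ok <- !is.na(prof$strength)
  if (sum(ok) > 1L) {
    pct[ok] <- 100 * (rank(prof$strength[ok], ties.method = "average") - 1) /
      (sum(ok) - 1)
  } else if (sum(ok) == 1L) {
    pct[ok] <- 0
  }
  prof$percentile <- pct
  prof$category <- ifelse(is.na(pct), "low",
                          ifelse(pct > 80, "excellent",
                                 ifelse(pct > 50, "good", "low")))
  prof$fragrance_id <- fragrance_id
  prof[, c("fragrance_id", "emotion", "n_participants", "go_percent",
           "strength", "percentile", "category")]
}

all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- cbind(v[i], all_permutations(v[-i]))
  do.call(rbind, out)
}

#' Spearman correlation with exact permutation p-value
#'
#' Spearman's rank correlation; for `n <= max_exact` observations the
#' two-sided p-value is computed exactly by enumerating all `n!`
#' permutations of one ranking (valid under ties), otherwise via the
#' t approximation.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param max_exact Largest `n` for which permutations are enumerated.
#' @return List with `rho`, `p`, `method`.
#' @export
spearman_test <- function(x, y, max_exact = 8L) {
  n <- length(x)
  if (n != length(y) || n < 3L) stop_arg("spearman_test: need equal length >= 3")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= max_exact) {
    perms <- all_permutations(seq_len(n))
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2),
         method = "t approximation")
  }
}

#' Concordance between biomarker and IAT emotional profiles
#'
#' Rank agreement between a fragrance's CART-based signature (percent of
#' participants matching each emotion's biomarker rule) and its implicit
#' association measures (Go-percent and strength of association), as
#' Spearman correlations with exact permutation p-values for small
#' emotion sets.
#'
#' @param signature Output of [fragrance_signature()].
#' @param iat_profile Output of [score_iat()] for the same fragrance.
#' @return Tibble with `fragrance_id`, `measure`, `n_emotions`, `rho`,
#'   `p`, `method`.
#' @export
concordance <- function(signature, iat_profile) {
  shared <- inner_join(signature, iat_profile,
                       by = c("fragrance_id", "emotion"))
  if (nrow(shared) < 3L) {
    stop_arg("concordance: need at least 3 shared emotions (got %d)", nrow(shared))
  }
  purrr::map_dfr(c("go_percent", "strength"), function(measure) {
    keep <- !is.na(shared[[measure]])
    res <- spearman_test(shared$percent[keep], shared[[measure]][keep])
    tibble(fragrance_id = shared$fragrance_id[1], measure = measure,
           n_emotions = sum(keep), rho = res$rho, p = res$p,
           method = res$method)
  })
}

#' Valuation groups and biomarker ratio analysis
#'
#' Ratings 1-2 form the *high*-valuation group, 3-4 *medium*, 5-6 *low*.
#' Per analyte the group mean S2/S1 ratios are summarised; a
#' Kruskal-Wallis test compares the three groups and pairwise Wilcoxon
#' rank-sum tests follow, with Benjamini-Hochberg adjustment across the
#' full analyte-by-comparison family.
#'
#' @param valuation Valuation tibble ([read_valuation()] schema).
#' @param ratios Ratio tibble ([compute_ratios()] output).
#' @return List: `summary` (group x analyte means), `kruskal` (per-analyte
#'   test), `pairwise` (per analyte and group pair, with `p_adj`), and
#'   `flags` for empty groups.
#' @export
valuation_analysis <- function(valuation, ratios) {
  joined <- inner_join(ratios, valuation,
                       by = c("participant_id", "fragrance_id")) %>%
    mutate(group = valuation_group(.data$valuation))
  flags <- character(0)
  present <- intersect(c("high", "medium", "low"), unique(joined$group))
  for (g in setdiff(c("high", "medium", "low"), present)) {
    flags <- c(flags, sprintf("valuation group '%s' empty: omitted", g))
  }
  long <- tidyr::pivot_longer(joined[, c("group", ANALYTES)],
                              cols = all_of(ANALYTES),
                              names_to = "analyte", values_to = "ratio")
  summary <- long %>%
    group_by(.data$group, .data$analyte) %>%
    summarise(n = n(), mean_ratio = mean(.data$ratio), .groups = "drop")
  if (length(present) < 2L) {
    return(list(summary = summary,
                kruskal = tibble(analyte = character(0)),
                pairwise = tibble(analyte = character(0)), flags = flags))
  }
  kw <- purrr::map_dfr(ANALYTES, function(a) {
    d <- filter(long, .data$analyte == a)
    kt <- kruskal.test(ratio ~ factor(group), data = d)
    tibble(analyte = a, statistic = unname(kt$statistic), p = kt$p.value)
  })
  pairs <- utils::combn(present, 2L, simplify = FALSE)
  pw <- purrr::map_dfr(ANALYTES, function(a) {
    purrr::map_dfr(pairs, function(pr) {
      d <- filter(long, .data$analyte == a, .data$group %in% pr)
      wt <- suppressWarnings(wilcox.test(ratio ~ factor(group), data = d))
      tibble(analyte = a, group1 = pr[1], group2 = pr[2], p = wt$p.value)
    })
  })
  pw$p_adj <- bh_adjust(pw$p)
  list(summary = summary, kruskal = kw, pairwise = pw, flags = flags)
}

#' @rdname valuation_analysis
#' @param rating Integer vector of 1-6 ratings.
#' @export
valuation_group <- function(rating) {
  if (any(!rating %in% 1:6)) stop_arg("valuation_group: ratings must be in 1..6")
  ifelse(rating <= 2L, "high", ifelse(rating <= 4L, "medium", "low"))
}

#' Per-stratum Spearman correlation matrices of biomarker values
#'
#' Within each timepoint-by-fragrance stratum, the 4 x 4 Spearman
#' correlation matrix of biomarker values across participants. Cells with
#' fewer than `min_pairs` paired observations are flagged missing.
#'
#' @param samples Long-format samples tibble.
#' @param min_pairs Minimum paired observations per cell.
#' @return Long tibble: `fragrance_id`, `timepoint`, `analyte_row`,
#'   `analyte_col`, `rho`, `n_pairs`.
#' @export
correlation_heatmap <- function(samples, min_pairs = 3L) {
  strata <- distinct(samples, .data$fragrance_id, .data$timepoint)
  purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    sub <- filter(samples, .data$fragrance_id == strata$fragrance_id[i],
                  .data$timepoint == strata$timepoint[i])
    wide <- tidyr::pivot_wider(
      sub[, c("participant_id", "analyte", "value")],
      names_from = "analyte", values_from = "value")
    for (a in setdiff(ANALYTES, names(wide))) wide[[a]] <- NA_real_
    m <- as.matrix(wide[, ANALYTES])
    out <- tidyr::expand_grid(analyte_row = ANALYTES, analyte_col = ANALYTES)
    out$rho <- NA_real_
    out$n_pairs <- 0L
    for (r in seq_len(nrow(out))) {
      xi <- m[, out$analyte_row[r]]; yi <- m[, out$analyte_col[r]]
      ok <- is.finite(xi) & is.finite(yi)
      out$n_pairs[r] <- sum(ok)
      if (sum(ok) >= min_pairs) {
        out$rho[r] <- cor(xi[ok], yi[ok], method = "spearman")
      }
    }
    out$fragrance_id <- strata$fragrance_id[i]
    out$timepoint <- strata$timepoint[i]
    out[, c("fragrance_id", "timepoint", "analyte_row", "analyte_col",
            "rho", "n_pairs")]
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: sorted ascending,
#' `q_i = min_{j >= i} (m * p_j / j)`, capped at 1, original order
#' restored.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_arg("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
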
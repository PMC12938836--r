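# Post/pre-stimulation ratios, log2 transforms and the three-state
# discretization into the 81-profile lattice.

#' Compute post/pre-stimulation biomarker ratios
#'
#' Expresses each exposure's post-stimulation panel relative to its own
#' baseline: `ratio = value(post) / value(S1)` per analyte, with the log2
#' transform alongside (symmetric treatment of up- and down-shifts).
#' Normalising to each exposure's baseline removes inter-individual level
#' variability and measurement-unit differences. Exposures lacking the S1
#' or the requested post panel are excluded and reported via the
#' `n_excluded` attribute and a message.
#'
#' @param samples Long-format samples tibble ([read_samples()]).
#' @param horizon `"S2/S1"` (default, +5 min) or `"S3/S1"` (+20 min).
#' @return Tibble with `participant_id`, `fragrance_id`, `horizon`, one
#'   ratio column per analyte (`saa`, `crt`, `dhea`, `oxt`) and log2
#'   columns (`log2_saa`, ...); attribute `n_excluded`.
#' @export
compute_ratios <- function(samples, horizon = c("S2/S1", "S3/S1")) {
  horizon <- match.arg(horizon)
  post_tp <- if (horizon == "S2/S1") "S2" else "S3"
  wide <- samples %>%
    select("participant_id", "fragrance_id", "timepoint", "analyte", "value") %>%
    filter(.data$timepoint %in% c("S1", post_tp)) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  if (!"S1" %in% names(wide)) wide$S1 <- NA_real_
  if (!post_tp %in% names(wide)) wide[[post_tp]] <- NA_real_
  bad_base <- wide$S1 <= 0 & !is.na(wide$S1)
  if (any(bad_base)) {
    r <- which(bad_base)[1]
    stop_data("compute_ratios: non-positive baseline for %s/%s (%s)",
              wide$participant_id[r], wide$fragrance_id[r], wide$analyte[r])
  }
  wide$ratio <- wide[[post_tp]] / wide$S1
  per_exposure <- wide %>%
    select("participant_id", "fragrance_id", "analyte", "ratio") %>%
    tidyr::pivot_wider(names_from = "analyte", values_from = "ratio")
  for (a in setdiff(ANALYTES, names(per_exposure))) per_exposure[[a]] <- NA_real_
  complete <- stats::complete.cases(per_exposure[, ANALYTES])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("compute_ratios: excluded %d exposure(s) lacking S1 or %s panels",
                    n_excluded, post_tp))
  }
  out <- per_exposure[complete, c("participant_id", "fragrance_id", ANALYTES)]
  out$horizon <- horizon
  for (a in ANALYTES) out[[paste0("log2_", a)]] <- log2(out[[a]])
  out <- out[, c("participant_id", "fragrance_id", "horizon", ANALYTES,
                 paste0("log2_", ANALYTES))]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Discretization thresholds
#'
#' The three-state band derives from the mean assay coefficient of
#' variation (~10%): ratios below `low` are *decreased*, ratios above
#' `high` are *increased*, and the closed interval `[low, high]` is
#' *stable* (so the boundary values 0.9 and 1.1 themselves count as
#' stable).
#'
#' @param low,high Ratio cut points, `0 < low < high`.
#' @return List of class `discretization_thresholds`.
#' @export
discretization_thresholds <- function(low = 0.9, high = 1.1) {
  if (!(low > 0 && low < high)) stop_arg("thresholds: need 0 < low < high")
  structure(list(low = low, high = high), class = "discretization_thresholds")
}

STATE_LEVELS <- c("decreased", "stable", "increased")

# states: character vector/matrix over STATE_LEVELS -> integer 0..2
state_to_int <- function(states) {
  match(states, STATE_LEVELS) - 1L
}

#' Encode and decode discrete biomarker profiles
#'
#' A discrete profile is the 4-tuple of per-analyte states in the fixed
#' order (sAA, cortisol, DHEA, oxytocin). `encode_profile()` maps it to its
#' base-3 code 0..80 (decreased = 0, stable = 1, increased = 2, sAA most
#' significant); `decode_profile()` is the inverse.
#'
#' @param states Character vector of length 4 over
#'   `c("decreased", "stable", "increased")`, in analyte order.
#' @param code Integer in 0..80.
#' @return `encode_profile()`: integer code; `decode_profile()`: named
#'   character vector of states.
#' @export
encode_profile <- function(states) {
  ints <- state_to_int(states)
  if (length(ints) != 4L || anyNA(ints)) {
    stop_arg("encode_profile: need 4 states over {decreased, stable, increased}")
  }
  as.integer(sum(ints * c(27L, 9L, 3L, 1L)))
}

#' @rdname encode_profile
#' @export
decode_profile <- function(code) {
  if (any(code < 0L | code > 80L)) stop_arg("decode_profile: code must be in 0..80")
  digits <- c(code %/% 27L, (code %/% 9L) %% 3L, (code %/% 3L) %% 3L, code %% 3L)
  setNames(STATE_LEVELS[digits + 1L], ANALYTES)
}

#' Discretize ratio profiles into biomarker states
#'
#' Maps every exposure's four ratios onto the three-state alphabet using
#' [discretization_thresholds()] and attaches the base-3 profile code
#' (0..80).
#'
#' @param ratios Output of [compute_ratios()].
#' @param thresholds A [discretization_thresholds()].
#' @return Tibble with `participant_id`, `fragrance_id`, `horizon`, one
#'   state column per analyte (`state_saa`, ...) and `code`.
#' @export
discretize_ratios <- function(ratios, thresholds = discretization_thresholds()) {
  st <- function(x) {
    ifelse(x < thresholds$low, "decreased",
           ifelse(x > thresholds$high, "increased", "stable"))
  }
  out <- ratios[, c("participant_id", "fragrance_id", "horizon")]
  m <- matrix(0L, nrow(ratios), 4)
  for (j in seq_along(ANALYTES)) {
    s <- st(ratios[[ANALYTES[j]]])
    out[[paste0("state_", ANALYTES[j])]] <- s
    m[, j] <- state_to_int(s)
  }
  out$code <- as.integer(m %*% c(27L, 9L, 3L, 1L))
  out
}

#' Enumerate the 81-profile lattice
#'
#' All 3^4 = 81 combinations of the four biomarker states, sorted by code.
#'
#' @return Tibble with `code` (0..80) and one state column per analyte.
#' @export
enumerate_profiles <- function() {
  codes <- 0:80
  states <- t(vapply(codes, decode_profile, character(4)))
  out <- tibble(code = codes)
  for (j in seq_along(ANALYTES)) {
    out[[paste0("state_", ANALYTES[j])]] <- unname(states[, j])
  }
  out
}
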
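# Domain constants and tidy-CSV I/O shared by every pipeline stage.

#' Biomarker panel analytes
#'
#' The four salivary analytes measured at every sampling point, in the fixed
#' order used throughout the package (discrete-profile encoding, clustering
#' space, CART split tie-breaking): salivary alpha-amylase (`saa`, an
#' activity in U/mL, sympathetic arousal), cortisol (`crt`, pg/mL, HPA-axis
#' output), dehydroepiandrosterone (`dhea`, pg/mL, resilience-linked adrenal
#' steroid) and oxytocin (`oxt`, pg/mL, social/affiliative neuropeptide).
#'
#' @format Character vector of length 4.
#' @export
ANALYTES <- c("saa", "crt", "dhea", "oxt")

#' @rdname ANALYTES
#' @format `ANALYTE_UNITS`: named character vector, the measurement unit per
#'   analyte.
#' @export
ANALYTE_UNITS <- c(saa = "U/mL", crt = "pg/mL", dhea = "pg/mL", oxt = "pg/mL")

#' Sampling timepoints
#'
#' Saliva is collected 5 minutes before olfactory stimulation (`S1`) and 5
#' and 20 minutes after it (`S2`, `S3`). `TIMEPOINT_OFFSET_MIN` gives the
#' offset of each sampling point relative to stimulation, in minutes.
#'
#' @format Character vector of length 3; named numeric vector of offsets.
#' @export
TIMEPOINTS <- c("S1", "S2", "S3")

#' @rdname TIMEPOINTS
#' @export
TIMEPOINT_OFFSET_MIN <- c(S1 = -5, S2 = 5, S3 = 20)

#' Emotion vocabulary
#'
#' The six emotions probed after every stimulation, plus the three additional
#' ones used in the pilot questionnaire. Self-reports use a 0-2 valence scale
#' (0 lowest, 2 highest).
#'
#' @format Character vectors.
#' @export
EMOTIONS_CORE <- c("confident", "sensual", "happy", "dynamised", "relaxed",
                   "comforted")

#' @rdname EMOTIONS_CORE
#' @export
EMOTIONS_EXTENDED <- c(EMOTIONS_CORE, "elegant", "addict", "unique")

#' Baseline biomarker distribution (pre-stimulation, morning)
#'
#' Observed pre-stimulation (S1) means with their standard errors from an
#' n = 30 morning cohort: sAA 176.1 +/- 6.5 U/mL, cortisol 2076.2 +/- 103.2
#' pg/mL, DHEA 427.2 +/- 30.0 pg/mL, oxytocin 171.1 +/- 17.6 pg/mL. The
#' generator treats the +/- values as SEMs and rescales them to
#' per-participant SDs (SEM * sqrt(30)).
#'
#' @format Named numeric vectors over [ANALYTES].
#' @export
BASELINE_MEAN <- c(saa = 176.1, crt = 2076.2, dhea = 427.2, oxt = 171.1)

#' @rdname BASELINE_MEAN
#' @export
BASELINE_SEM <- c(saa = 6.5, crt = 103.2, dhea = 30.0, oxt = 17.6)

#' @rdname BASELINE_MEAN
#' @export
BASELINE_N_PILOT <- 30

# ---- internal validators ----------------------------------------------------

stop_schema <- function(msg, ...) abort(sprintf(msg, ...), class = "salivemo_schema_error")
stop_data   <- function(msg, ...) abort(sprintf(msg, ...), class = "salivemo_data_error")
stop_arg    <- function(msg, ...) abort(sprintf(msg, ...), class = "salivemo_argument_error")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_schema("%s: missing column(s) %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Validate a long-format samples table
#'
#' Checks the invariants of a per-analyte sample table: known analytes and
#' timepoints, strictly positive finite measurements, units matching the
#' analyte, and uniqueness of (participant, fragrance, timepoint, analyte).
#'
#' @param samples Tibble with columns `participant_id`, `fragrance_id`,
#'   `timepoint`, `clock_time_min`, `analyte`, `value`, `unit`.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_samples <- function(samples) {
  check_columns(samples, c("participant_id", "fragrance_id", "timepoint",
                           "clock_time_min", "analyte", "value", "unit"),
                "samples")
  bad_tp <- which(!samples$timepoint %in% TIMEPOINTS)
  if (length(bad_tp) > 0L) {
    stop_schema("samples: unknown timepoint '%s' at row %d",
                samples$timepoint[bad_tp[1]], bad_tp[1])
  }
  bad_an <- which(!samples$analyte %in% ANALYTES)
  if (length(bad_an) > 0L) {
    stop_schema("samples: unknown analyte '%s' at row %d",
                samples$analyte[bad_an[1]], bad_an[1])
  }
  bad_val <- which(!is.finite(samples$value) | samples$value <= 0)
  if (length(bad_val) > 0L) {
    stop_schema("samples: non-positive or non-finite value at row %d (%s = %s)",
                bad_val[1], samples$analyte[bad_val[1]],
                format(samples$value[bad_val[1]]))
  }
  bad_unit <- which(samples$unit != ANALYTE_UNITS[samples$analyte])
  if (length(bad_unit) > 0L) {
    stop_schema("samples: unit '%s' does not match analyte '%s' at row %d",
                samples$unit[bad_unit[1]], samples$analyte[bad_unit[1]],
                bad_unit[1])
  }
  key <- paste(samples$participant_id, samples$fragrance_id,
               samples$timepoint, samples$analyte, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_schema("samples: duplicate (participant, fragrance, timepoint, analyte) key at row %d",
                dup[1])
  }
  samples
}

#' Read and write pipeline CSV tables
#'
#' Tidy long-format, UTF-8, comma-separated tables with a header row.
#' `read_samples()` validates every row against the panel invariants
#' (positive finite values, known analytes/timepoints, unique keys) and
#' preserves row order; writers emit a canonical column order so that a
#' write/read round trip is the identity.
#'
#' @param path File path.
#' @param samples,emotions,valuation,iat Tibbles in the respective schema.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @name saliva_io
NULL

#' @rdname saliva_io
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    fragrance_id = readr::col_character(),
    timepoint = readr::col_character(),
    clock_time_min = readr::col_double(),
    analyte = readr::col_character(),
    value = readr::col_character(),   # parsed below: strtod round-trips exactly
    unit = readr::col_character()
  ))
  df$value <- as.numeric(df$value)
  validate_samples(df)
}

#' @rdname saliva_io
#' @export
write_samples <- function(samples, path) {
  validate_samples(samples)
  readr::write_csv(samples[, c("participant_id", "fragrance_id", "timepoint",
                               "clock_time_min", "analyte", "value", "unit")],
                   path)
  invisible(path)
}

#' @rdname saliva_io
#' @export
read_emotions <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    fragrance_id = readr::col_character(),
    emotion = readr::col_character(),
    valence = readr::col_integer()
  ))
  bad <- which(!df$valence %in% 0:2)
  if (length(bad) > 0L) {
    stop_schema("emotions: valence outside 0-2 at row %d", bad[1])
  }
  df
}

#' @rdname saliva_io
#' @export
write_emotions <- function(emotions, path) {
  readr::write_csv(emotions[, c("participant_id", "fragrance_id", "emotion",
                                "valence")], path)
  invisible(path)
}

#' @rdname saliva_io
#' @export
read_valuation <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    fragrance_id = readr::col_character(),
    valuation = readr::col_integer()
  ))
  bad <- which(!df$valuation %in% 1:6)
  if (length(bad) > 0L) {
    stop_schema("valuation: rating outside 1-6 at row %d", bad[1])
  }
  df
}

#' @rdname saliva_io
#' @export
write_valuation <- function(valuation, path) {
  readr::write_csv(valuation[, c("participant_id", "fragrance_id", "valuation")],
                   path)
  invisible(path)
}

#' @rdname saliva_io
#' @export
read_iat <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    fragrance_id = readr::col_character(),
    emotion = readr::col_character(),
    presentation = readr::col_integer(),
    go = readr::col_logical(),
    latency_ms = readr::col_character()
  ))
  df$latency_ms <- as.numeric(df$latency_ms)
  bad <- which(!df$presentation %in% 1:3)
  if (length(bad) > 0L) stop_schema("iat: presentation outside 1-3 at row %d", bad[1])
  bad <- which(df$go & (!is.finite(df$latency_ms) | df$latency_ms <= 0))
  if (length(bad) > 0L) stop_schema("iat: go trial without positive latency at row %d", bad[1])
  df
}

#' @rdname saliva_io
#' @export
write_iat <- function(iat, path) {
  readr::write_csv(iat[, c("participant_id", "fragrance_id", "emotion",
                           "presentation", "go", "latency_ms")], path)
  invisible(path)
}

#' Summarise the sampling design
#'
#' Counts participants, fragrances, participant-fragrance combinations and
#' biomarker panels (one panel = one timepoint of one exposure) and checks
#' the complete-design arithmetic: with every exposure sampled at S1, S2 and
#' S3, `n_participants x n_fragrances = n_combinations` and
#' `n_combinations x 3 = n_panels`. Exposures missing a timepoint are
#' reported, never rejected: a 59-participant, 4-fragrance complete design
#' yields 236 combinations and 708 panels.
#'
#' @param samples Long-format samples tibble (see [read_samples()]).
#' @return A list of class `saliva_design` with counts, a logical
#'   `complete`, and a tibble `incomplete` of exposures lacking timepoints.
#' @export
validate_design <- function(samples) {
  panels <- distinct(samples, .data$participant_id, .data$fragrance_id,
                     .data$timepoint)
  combos <- distinct(panels, .data$participant_id, .data$fragrance_id)
  per_combo <- count(panels, .data$participant_id, .data$fragrance_id,
                     name = "n_timepoints")
  incomplete <- filter(per_combo, .data$n_timepoints < 3L)
  out <- list(
    n_participants = n_distinct(panels$participant_id),
    n_fragrances = n_distinct(panels$fragrance_id),
    n_combinations = nrow(combos),
    n_panels = nrow(panels),
    complete = nrow(incomplete) == 0L &&
      nrow(combos) == n_distinct(panels$participant_id) *
                      n_distinct(panels$fragrance_id) &&
      nrow(panels) == nrow(combos) * 3L,
    incomplete = incomplete
  )
  structure(out, class = "saliva_design")
}

#' @export
print.saliva_design <- function(x, ...) {
  cat(sprintf("Saliva sampling design: %d participants x %d fragrances\n",
              x$n_participants, x$n_fragrances))
  cat(sprintf("  %d participant-fragrance combinations, %d biomarker panels\n",
              x$n_combinations, x$n_panels))
  if (x$complete) {
    cat("  complete design (every exposure sampled at S1, S2, S3)\n")
  } else {
    cat(sprintf("  incomplete: %d exposure(s) missing timepoints\n",
                nrow(x$incomplete)))
  }
  invisible(x)
}
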
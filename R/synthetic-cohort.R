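# Synthetic cohort generator: emulates the study design (n participants x
# fragrances x S1/S2/S3), morning circadian drift, log-normal assay noise and
# latent emotion-linked phenotypes that shift post/pre biomarker ratios.

#' Default latent phenotype palette
#'
#' Four response phenotypes whose log2 ratio shifts and emotion-report
#' probabilities mirror the recurring cluster types seen across fragrances:
#' a *happy_relaxed* type (modest decreases of sAA, cortisol and DHEA with
#' moderately increased oxytocin; predominantly happy, moderately relaxed),
#' a *happy_dynamised* type (pronounced decreases of sAA, cortisol and DHEA
#' with near-stable oxytocin; happy and dynamised), a *comforted* type
#' (decreased/stable sAA, increased cortisol and oxytocin, stable DHEA) and
#' a *non_responder* type (no shift, little reported emotion). Each
#' phenotype also carries a valuation distribution on the 1-6 scale; types
#' with decreased sAA and increased oxytocin lean toward poor ratings (5-6),
#' emulating the observed association between those ratio shifts and low
#' hedonic valuation.
#'
#' @return A list of phenotype definitions; each has `label`, `weight`,
#'   `shift_mean` and `shift_sd` (named log2-ratio vectors over
#'   [ANALYTES]), `emissions` (per emotion, probabilities of valence 0/1/2)
#'   and `valuation_probs` (probabilities of ratings 1..6).
#' @export
default_phenotypes <- function() {
  emis <- function(p0, p1, p2) c(p0, p1, p2)
  list(
    list(
      label = "happy_relaxed", weight = 0.30,
      shift_mean = c(saa = -0.35, crt = -0.35, dhea = -0.35, oxt = 0.40),
      shift_sd = c(saa = 0.15, crt = 0.15, dhea = 0.15, oxt = 0.15),
      emissions = list(
        happy = emis(0.10, 0.30, 0.60), relaxed = emis(0.40, 0.40, 0.20),
        comforted = emis(0.50, 0.30, 0.20), confident = emis(0.70, 0.20, 0.10),
        sensual = emis(0.70, 0.20, 0.10), dynamised = emis(0.80, 0.15, 0.05)),
      valuation_probs = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.25)
    ),
    list(
      label = "happy_dynamised", weight = 0.25,
      shift_mean = c(saa = -0.80, crt = -0.80, dhea = -0.80, oxt = -0.05),
      shift_sd = c(saa = 0.15, crt = 0.15, dhea = 0.15, oxt = 0.15),
      emissions = list(
        happy = emis(0.15, 0.35, 0.50), relaxed = emis(0.60, 0.30, 0.10),
        comforted = emis(0.70, 0.20, 0.10), confident = emis(0.55, 0.30, 0.15),
        sensual = emis(0.70, 0.20, 0.10), dynamised = emis(0.15, 0.35, 0.50)),
      valuation_probs = c(0.20, 0.25, 0.20, 0.15, 0.10, 0.10)
    ),
    list(
      label = "comforted", weight = 0.20,
      shift_mean = c(saa = -0.20, crt = 0.40, dhea = 0.00, oxt = 0.40),
      shift_sd = c(saa = 0.15, crt = 0.15, dhea = 0.15, oxt = 0.15),
      emissions = list(
        happy = emis(0.35, 0.40, 0.25), relaxed = emis(0.40, 0.40, 0.20),
        comforted = emis(0.15, 0.35, 0.50), confident = emis(0.50, 0.35, 0.15),
        sensual = emis(0.60, 0.25, 0.15), dynamised = emis(0.75, 0.20, 0.05)),
      valuation_probs = c(0.30, 0.30, 0.20, 0.10, 0.05, 0.05)
    ),
    list(
      label = "non_responder", weight = 0.25,
      shift_mean = c(saa = 0, crt = 0, dhea = 0, oxt = 0),
      shift_sd = c(saa = 0.10, crt = 0.10, dhea = 0.10, oxt = 0.10),
      emissions = list(
        happy = emis(0.80, 0.15, 0.05), relaxed = emis(0.80, 0.15, 0.05),
        comforted = emis(0.85, 0.10, 0.05), confident = emis(0.85, 0.10, 0.05),
        sensual = emis(0.90, 0.07, 0.03), dynamised = emis(0.85, 0.10, 0.05)),
      valuation_probs = c(0.10, 0.20, 0.25, 0.25, 0.10, 0.10)
    )
  )
}

#' Generator configuration
#'
#' Assembles and validates the parameters of the synthetic cohort. Defaults
#' reproduce the main study conditions: 59 participants smelling four
#' fragrances (F2-F5) with saliva panels at S1/S2/S3, morning sessions,
#' baseline biomarker distributions from the observed pre-stimulation means
#' (the +/- values are treated as SEMs of an n = 30 cohort, so the
#' per-participant SD is SEM * sqrt(30)), ~10% multiplicative assay CV, and
#' a per-analyte circadian drift bounded at 6% per 30 minutes.
#'
#' @param n_participants Number of participants.
#' @param fragrances Character vector of fragrance identifiers.
#' @param baseline_mean,baseline_sem Named numeric vectors over [ANALYTES];
#'   SEMs are rescaled by `sqrt(baseline_n)` to per-participant SDs.
#' @param baseline_n Size of the cohort whose SEMs are quoted.
#' @param assay_cv Coefficient of variation of the multiplicative log-normal
#'   assay noise applied to every measurement.
#' @param circadian Named list per analyte with elements `rate` (fractional
#'   level change per 30 min, >= 0) and `pattern` (`"morning_decline"` or
#'   `"afternoon_rise"`); see [circadian_drift()].
#' @param drift_heterogeneity_sdlog sdlog of the mean-one log-normal factor
#'   that scales each session's circadian slope (inter-individual
#'   variability of the diurnal rhythm).
#' @param phenotypes Latent phenotype palette, see [default_phenotypes()];
#'   mixing weights must sum to 1.
#' @param s3_attenuation Multiplier applied to each exposure's log2 ratio
#'   shift at S3 relative to its S2 effect (the stimulus response has
#'   partially washed out 20 min after stimulation).
#' @param session_start_range Clock-time window (minutes since midnight) in
#'   which S1 collections start; default 09:00-11:30.
#' @param iat Go/no-go response model: go probabilities and log-normal
#'   latency parameters for felt vs unfelt emotions, and the response
#'   window (ms).
#' @param seed Master seed; every generator draw derives from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 59,
                             fragrances = c("F2", "F3", "F4", "F5"),
                             baseline_mean = BASELINE_MEAN,
                             baseline_sem = BASELINE_SEM,
                             baseline_n = BASELINE_N_PILOT,
                             assay_cv = 0.10,
                             circadian = list(
                               saa  = list(rate = 0.06, pattern = "afternoon_rise"),
                               crt  = list(rate = 0.06, pattern = "morning_decline"),
                               dhea = list(rate = 0.06, pattern = "morning_decline"),
                               oxt  = list(rate = 0.03, pattern = "morning_decline")),
                             drift_heterogeneity_sdlog = 0.15,
                             phenotypes = default_phenotypes(),
                             s3_attenuation = 0.5,
                             session_start_range = c(540, 690),
                             iat = list(go_felt = 0.85, go_unfelt = 0.20,
                                        latency_meanlog_felt = log(600),
                                        latency_meanlog_unfelt = log(950),
                                        latency_sdlog = 0.25,
                                        window_ms = 1500),
                             seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              fragrances = as.character(fragrances),
              baseline_mean = baseline_mean[ANALYTES],
              baseline_sem = baseline_sem[ANALYTES],
              baseline_n = baseline_n,
              assay_cv = assay_cv, circadian = circadian,
              drift_heterogeneity_sdlog = drift_heterogeneity_sdlog,
              phenotypes = phenotypes, s3_attenuation = s3_attenuation,
              session_start_range = session_start_range, iat = iat,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop_arg("config: n_participants must be >= 1")
  if (length(cfg$fragrances) < 1L) stop_arg("config: at least one fragrance required")
  if (any(!is.finite(cfg$baseline_mean)) || any(cfg$baseline_mean <= 0)) {
    stop_arg("config: baseline means must be positive")
  }
  if (any(cfg$baseline_sem < 0)) stop_arg("config: baseline SEMs must be >= 0")
  if (cfg$assay_cv < 0) stop_arg("config: assay_cv must be >= 0")
  for (a in ANALYTES) {
    cc <- cfg$circadian[[a]]
    if (is.null(cc) || cc$rate < 0) stop_arg("config: circadian rate for %s must be >= 0", a)
    if (!cc$pattern %in% c("morning_decline", "afternoon_rise")) {
      stop_arg("config: unknown circadian pattern '%s'", cc$pattern)
    }
  }
  if (cfg$drift_heterogeneity_sdlog < 0) stop_arg("config: drift heterogeneity sdlog must be >= 0")
  w <- vapply(cfg$phenotypes, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop_arg("config: phenotype weights must sum to 1 (got %g)", sum(w))
  if (cfg$s3_attenuation < 0) stop_arg("config: s3_attenuation must be >= 0")
  invisible(cfg)
}

# Relative circadian level of an analyte at clock time t (minutes since
# midnight), anchored at 1.0 at 09:00. Geometric (log-linear) segments keep
# the relative change of ANY interval <= rate per 30 min, not just intervals
# starting at 09:00.
circadian_level <- function(analyte, t, config) {
  cc <- config$circadian[[analyte]]
  anchor <- 540  # 09:00
  noon <- 720
  if (cc$pattern == "morning_decline") {
    (1 - cc$rate)^((t - anchor) / 30)
  } else {
    # flat through the morning, rising after midday
    ifelse(t <= noon, 1, (1 + cc$rate)^((t - noon) / 30))
  }
}

#' Deterministic circadian drift factor
#'
#' Multiplicative level change of an analyte between two clock times under
#' the configured diurnal model: cortisol, DHEA and (more modestly) oxytocin
#' decline geometrically from their 09:00 morning high, while sAA activity
#' is flat through the morning and rises after midday. The geometric
#' parameterisation guarantees `|factor - 1| <= rate` for any interval of at
#' most 30 minutes, matching the observed ~6% short-term variation bound.
#'
#' @param analyte One of [ANALYTES].
#' @param t0,t1 Clock times in minutes since midnight, `t0 <= t1`, same day.
#' @param config A [generator_config()].
#' @return Positive scalar factor `level(t1) / level(t0)`.
#' @export
circadian_drift <- function(analyte, t0, t1, config = generator_config()) {
  if (!analyte %in% ANALYTES) stop_arg("unknown analyte '%s'", analyte)
  if (any(t1 < t0)) stop_arg("circadian_drift: t1 must be >= t0")
  if (any(t0 < 0) || any(t1 > 1440)) stop_arg("circadian_drift: times must lie within one day")
  circadian_level(analyte, t1, config) / circadian_level(analyte, t0, config)
}

#' Simulate circadian trajectories
#'
#' Draws `n` per-session circadian drift factors for each analyte between
#' two clock times. Each session's slope is scaled by a mean-one log-normal
#' heterogeneity factor (`drift_heterogeneity_sdlog`), so individual
#' trajectories scatter around the deterministic curve while the population
#' mean drift stays at the configured rate.
#'
#' @param n Number of trajectories per analyte.
#' @param t0,t1 Clock times (minutes since midnight), default 09:00-09:30.
#' @param config A [generator_config()].
#' @param seed Seed; defaults to the config seed.
#' @return Tibble with columns `analyte`, `draw`, `factor`.
#' @export
simulate_circadian_trajectories <- function(n, t0 = 540, t1 = 570,
                                            config = generator_config(),
                                            seed = config$seed) {
  set.seed(seed)
  sdlog <- config$drift_heterogeneity_sdlog
  purrr::map_dfr(ANALYTES, function(a) {
    base <- circadian_drift(a, t0, t1, config)
    m <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    tibble(analyte = a, draw = seq_len(n), factor = exp(m * log(base)))
  })
}

# mean-one multiplicative log-normal noise with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

draw_categorical <- function(n, probs) {
  probs <- probs / sum(probs)
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Simulates the full study design for one cohort: every participant is
#' exposed to every fragrance (one morning session each); saliva panels are
#' drawn at S1 (session start), S2 (+10 min) and S3 (+25 min). Baselines
#' are log-normal per participant; circadian drift (with per-session slope
#' heterogeneity) acts between timepoints; each exposure draws one latent
#' phenotype whose log2 ratio shift is applied at S2 and, attenuated by
#' `s3_attenuation`, at S3; every measurement finally receives mean-one
#' log-normal assay noise with CV `assay_cv`. Emotion valences (0-2) and a
#' 1-6 valuation are emitted from the phenotype. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_cohort`: `samples` (long tibble in
#'   the [read_samples()] schema), `emotions`, `valuation`, and `latent`
#'   (the ground-truth phenotype per exposure, for recovery tests only).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  participants <- sprintf("P-%03d", seq_len(n))
  sd_part <- config$baseline_sem * sqrt(config$baseline_n)

  # participant-level baselines (log-normal with configured mean and SD)
  baselines <- sapply(ANALYTES, function(a) {
    m <- config$baseline_mean[[a]]; s <- sd_part[[a]]
    sdlog <- sqrt(log(1 + (s / m)^2))
    rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  })
  rownames(baselines) <- participants

  exposures <- tidyr::expand_grid(participant_id = participants,
                                  fragrance_id = config$fragrances)
  ne <- nrow(exposures)
  start <- round(runif(ne, config$session_start_range[1],
                       config$session_start_range[2]))
  pheno_idx <- draw_categorical(ne, vapply(config$phenotypes,
                                           function(p) p$weight, numeric(1)))
  drift_mult <- rlnorm(ne, meanlog = -config$drift_heterogeneity_sdlog^2 / 2,
                       sdlog = config$drift_heterogeneity_sdlog)

  offsets <- c(S1 = 0, S2 = 10, S3 = 25)  # minutes after S1 collection
  rows <- vector("list", ne)
  emo_rows <- vector("list", ne)
  val_rows <- vector("list", ne)
  emotions <- names(config$phenotypes[[1]]$emissions)

  for (i in seq_len(ne)) {
    pid <- exposures$participant_id[i]
    fid <- exposures$fragrance_id[i]
    ph <- config$phenotypes[[pheno_idx[i]]]
    shift <- rnorm(length(ANALYTES), ph$shift_mean[ANALYTES],
                   ph$shift_sd[ANALYTES])
    names(shift) <- ANALYTES
    tp_rows <- vector("list", 3)
    for (j in seq_along(TIMEPOINTS)) {
      tp <- TIMEPOINTS[j]
      tt <- start[i] + offsets[[tp]]
      level <- vapply(ANALYTES, function(a) {
        drift <- exp(drift_mult[i] *
                       log(circadian_drift(a, start[i], tt, config)))
        eff <- switch(tp, S1 = 0, S2 = shift[[a]],
                      S3 = config$s3_attenuation * shift[[a]])
        baselines[pid, a] * drift * 2^eff
      }, numeric(1))
      value <- level * rlnorm_cv(length(ANALYTES), config$assay_cv)
      tp_rows[[j]] <- tibble(
        participant_id = pid, fragrance_id = fid, timepoint = tp,
        clock_time_min = tt, analyte = ANALYTES, value = unname(value),
        unit = unname(ANALYTE_UNITS[ANALYTES]))
    }
    rows[[i]] <- bind_rows(tp_rows)
    valence <- vapply(emotions, function(e) {
      draw_categorical(1, ph$emissions[[e]]) - 1L
    }, integer(1))
    emo_rows[[i]] <- tibble(participant_id = pid, fragrance_id = fid,
                            emotion = emotions, valence = unname(valence))
    val_rows[[i]] <- tibble(participant_id = pid, fragrance_id = fid,
                            valuation = draw_categorical(1, ph$valuation_probs))
  }

  out <- list(
    samples = validate_samples(bind_rows(rows)),
    emotions = bind_rows(emo_rows),
    valuation = bind_rows(val_rows),
    latent = mutate(exposures,
                    phenotype = vapply(pheno_idx,
                                       function(k) config$phenotypes[[k]]$label,
                                       character(1)))
  )
  structure(out, class = "synthetic_cohort")
}

#' Generate implicit association test records
#'
#' Simulates the go/no-go IAT for every participant-fragrance exposure: each
#' emotion is presented three times; whether the exposure "feels" the
#' emotion is drawn from its latent phenotype's probability of a positive
#' valence, and felt emotions have a higher go probability and shorter
#' log-normal latencies than unfelt ones. Latencies at or beyond the
#' response window become no-go trials. Deterministic given the seed
#' (default: config seed + 1, the documented child-seed offset).
#'
#' @param latent Ground-truth assignment tibble from [generate_cohort()].
#' @param config A [generator_config()].
#' @param seed Seed for the IAT draws.
#' @return Tibble in the [read_iat()] schema (`latency_ms` is `NA` on no-go
#'   trials).
#' @export
generate_iat <- function(latent, config = generator_config(),
                         seed = config$seed + 1L) {
  set.seed(seed)
  pheno_by_label <- setNames(config$phenotypes,
                             vapply(config$phenotypes, function(p) p$label,
                                    character(1)))
  emotions <- names(config$phenotypes[[1]]$emissions)
  p_iat <- config$iat
  out <- vector("list", nrow(latent))
  for (i in seq_len(nrow(latent))) {
    ph <- pheno_by_label[[latent$phenotype[i]]]
    rows <- vector("list", length(emotions))
    for (k in seq_along(emotions)) {
      e <- emotions[k]
      p_felt <- sum(ph$emissions[[e]][2:3])
      felt <- runif(1) < p_felt
      go_p <- if (felt) p_iat$go_felt else p_iat$go_unfelt
      meanlog <- if (felt) p_iat$latency_meanlog_felt else p_iat$latency_meanlog_unfelt
      go <- runif(3) < go_p
      lat <- ifelse(go, rlnorm(3, meanlog, p_iat$latency_sdlog), NA_real_)
      too_slow <- !is.na(lat) & lat >= p_iat$window_ms
      go[too_slow] <- FALSE
      lat[too_slow] <- NA_real_
      rows[[k]] <- tibble(participant_id = latent$participant_id[i],
                          fragrance_id = latent$fragrance_id[i],
                          emotion = e, presentation = 1:3, go = go,
                          latency_ms = lat)
    }
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}
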
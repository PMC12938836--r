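# End-to-end orchestration: simulate/read -> ratios -> discretize ->
# cluster -> CART -> signatures -> IAT concordance -> valuation, with every
# stage table written to the output directory and a JSON run report.

#' Pipeline configuration
#'
#' Collects the knobs of a full run in one place. Exactly one of
#' `generator` (a [generator_config()], the cohort is simulated) or
#' `inputs` (named list of CSV paths: `samples`, `emotions`, optionally
#' `valuation` and `iat`) must be given. All stage thresholds live here:
#' the discretization band, the clustering controls, the CART controls,
#' the valence cut that counts an emotion as felt, and the IAT response
#' window.
#'
#' @param generator Optional [generator_config()].
#' @param inputs Optional named list of input CSV paths.
#' @param thresholds A [discretization_thresholds()].
#' @param clustering List: `k_range`, `min_size`, `max_depth`.
#' @param cart A [cart_control()].
#' @param valence_cut Minimum valence counting as "felt" (shared by
#'   cluster profiling and CART labels).
#' @param iat_window_ms IAT response window for the strength score.
#' @param out_dir Output directory for stage tables and the report.
#' @param seed Master seed; stage seeds derive from it by fixed offsets
#'   (generator: seed; IAT: seed + 1; k-means restarts: seed + 2).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, inputs = NULL,
                            thresholds = discretization_thresholds(),
                            clustering = list(k_range = 2:6, min_size = 5L,
                                              max_depth = 2L),
                            cart = cart_control(),
                            valence_cut = 1L,
                            iat_window_ms = 1500,
                            out_dir = "results/pipeline",
                            seed = 1L) {
  if (is.null(generator) == is.null(inputs)) {
    stop_arg("pipeline_config: exactly one of generator / inputs must be given")
  }
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, inputs = inputs,
                 thresholds = thresholds, clustering = clustering,
                 cart = cart, valence_cut = valence_cut,
                 iat_window_ms = iat_window_ms, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields; `generator`
#'   entries are passed to [generator_config()], `cart` to
#'   [cart_control()], `thresholds` to [discretization_thresholds()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$generator)) {
    gen_args <- raw$generator
    if (!is.null(gen_args$baseline_mean)) gen_args$baseline_mean <- unlist(gen_args$baseline_mean)
    if (!is.null(gen_args$baseline_sem)) gen_args$baseline_sem <- unlist(gen_args$baseline_sem)
    args$generator <- do.call(generator_config, gen_args)
  }
  if (!is.null(raw$inputs)) args$inputs <- raw$inputs
  if (!is.null(raw$thresholds)) args$thresholds <- do.call(discretization_thresholds, raw$thresholds)
  if (!is.null(raw$clustering)) args$clustering <- raw$clustering
  if (!is.null(raw$cart)) args$cart <- do.call(cart_control, raw$cart)
  for (f in c("valence_cut", "iat_window_ms", "out_dir", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- cohort (simulated or read), design
#' summary, S2/S1 and S3/S1 ratios, discretization, per-fragrance
#' recursive hk-means clustering with cluster emotion profiles, pooled
#' per-emotion CART with rule extraction and resubstitution metrics,
#' fragrance signatures, IAT scoring and concordance (when IAT records
#' exist), and valuation analysis -- writing each stage's table under
#' `config$out_dir` and returning (and writing) a machine-readable run
#' report. Idempotent given the seed and inputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report` (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_arg("run_pipeline: config must be a pipeline_config")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # ---- stage 1: data --------------------------------------------------------
  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator)
    iat <- generate_iat(cohort$latent, config$generator,
                        seed = config$seed + 1L)
    samples <- cohort$samples
    emotions <- cohort$emotions
    valuation <- cohort$valuation
    write_samples(samples, file.path(out, "samples.csv"))
    write_emotions(emotions, file.path(out, "emotions.csv"))
    write_valuation(valuation, file.path(out, "valuation.csv"))
    write_iat(iat, file.path(out, "iat.csv"))
    readr::write_csv(cohort$latent, file.path(out, "latent_assignments.csv"))
  } else {
    samples <- read_samples(config$inputs$samples)
    emotions <- read_emotions(config$inputs$emotions)
    valuation <- if (!is.null(config$inputs$valuation)) {
      read_valuation(config$inputs$valuation)
    }
    iat <- if (!is.null(config$inputs$iat)) read_iat(config$inputs$iat)
  }
  design <- validate_design(samples)

  # ---- stage 2: ratios and discretization ----------------------------------
  ratios_s2 <- compute_ratios(samples, "S2/S1")
  ratios_s3 <- compute_ratios(samples, "S3/S1")
  readr::write_csv(bind_rows(ratios_s2, ratios_s3), file.path(out, "ratios.csv"))
  profiles <- discretize_ratios(ratios_s2, config$thresholds)
  readr::write_csv(profiles, file.path(out, "profiles.csv"))

  # ---- stage 3: per-fragrance clustering -----------------------------------
  cl <- config$clustering
  cluster_rows <- list(); cluster_prof_rows <- list()
  for (f in sort(unique(ratios_s2$fragrance_id))) {
    sub <- filter(ratios_s2, .data$fragrance_id == f)
    if (nrow(sub) < 2L * cl$min_size) next
    rs <- recursive_subcluster(sub[, paste0("log2_", ANALYTES)],
                               min_size = cl$min_size,
                               max_depth = cl$max_depth,
                               k_range = cl$k_range)
    assignments <- tibble(participant_id = sub$participant_id,
                          fragrance_id = f,
                          cluster = paste0(f, rs$leaf))
    cluster_rows[[f]] <- assignments
    cluster_prof_rows[[f]] <- profile_clusters(assignments, emotions,
                                               config$valence_cut)
  }
  clusters <- bind_rows(cluster_rows)
  cluster_profiles <- bind_rows(cluster_prof_rows)
  readr::write_csv(clusters, file.path(out, "clusters.csv"))
  readr::write_csv(cluster_profiles, file.path(out, "cluster_profiles.csv"))

  # ---- stage 4: pooled per-emotion CART ------------------------------------
  tree_dir <- file.path(out, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  emotions_list <- sort(unique(emotions$emotion))
  trees <- list(); rules <- list(); metric_rows <- list(); rule_rows <- list()
  for (e in emotions_list) {
    lab <- emotion_labels(emotions, e, config$valence_cut)
    dat <- inner_join(profiles, lab, by = c("participant_id", "fragrance_id"))
    tree <- fit_cart(dat, dat$label, config$cart)
    trees[[e]] <- tree
    cart_to_json(tree, file.path(tree_dir, paste0(e, ".json")))
    rules[[e]] <- extract_rules(tree, e)
    m <- evaluate_cart(tree, dat, dat$label)
    metric_rows[[e]] <- tibble(emotion = e, tp = m$tp, fp = m$fp, tn = m$tn,
                               fn = m$fn, sensitivity = m$sensitivity,
                               specificity = m$specificity,
                               accuracy = m$accuracy)
    if (length(rules[[e]]$codes) > 0L) {
      rule_rows[[e]] <- tibble(emotion = e, code = rules[[e]]$codes)
    }
  }
  metrics <- bind_rows(metric_rows)
  readr::write_csv(metrics, file.path(out, "cart_metrics.csv"))
  readr::write_csv(bind_rows(rule_rows), file.path(out, "rules.csv"))

  # ---- stage 5: fragrance signatures and IAT concordance -------------------
  signatures <- purrr::map_dfr(sort(unique(profiles$fragrance_id)),
                               function(f) fragrance_signature(rules, profiles, f))
  readr::write_csv(signatures, file.path(out, "signatures.csv"))
  iat_profiles <- NULL; conc <- NULL
  if (!is.null(iat)) {
    iat_profiles <- purrr::map_dfr(sort(unique(iat$fragrance_id)),
                                   function(f) score_iat(iat, f, config$iat_window_ms))
    readr::write_csv(iat_profiles, file.path(out, "iat_profiles.csv"))
    conc <- purrr::map_dfr(
      intersect(unique(signatures$fragrance_id),
                unique(iat_profiles$fragrance_id)),
      function(f) concordance(filter(signatures, .data$fragrance_id == f),
                              filter(iat_profiles, .data$fragrance_id == f)))
    readr::write_csv(conc, file.path(out, "concordance.csv"))
  }

  # ---- stage 6: valuation ---------------------------------------------------
  valuation_result <- NULL
  if (!is.null(valuation)) {
    valuation_result <- valuation_analysis(valuation, ratios_s2)
    readr::write_csv(valuation_result$summary,
                     file.path(out, "valuation_summary.csv"))
    if (nrow(valuation_result$pairwise) > 0L) {
      readr::write_csv(valuation_result$pairwise,
                       file.path(out, "valuation_tests.csv"))
    }
  }

  report <- structure(list(
    design = unclass(design)[c("n_participants", "n_fragrances",
                               "n_combinations", "n_panels", "complete")],
    n_exposures_ratioed = nrow(ratios_s2),
    cluster_sizes = if (nrow(clusters) > 0L) {
      count(clusters, .data$cluster, name = "n")
    } else NULL,
    n_clusters = if (nrow(clusters) > 0L) n_distinct(clusters$cluster) else 0L,
    cart = metrics,
    signatures = signatures,
    concordance = conc,
    valuation = if (!is.null(valuation_result)) valuation_result$summary,
    seed = config$seed,
    version = as.character(utils::packageVersion("salivemo"))
  ), class = "run_report")
  jsonlite::write_json(
    lapply(report, function(x) if (is_tibble(x)) x else x),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(report)
}
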
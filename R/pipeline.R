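#' Full-run configuration
#'
#' Bundles every stage's parameters plus the analysis order:
#' `"vision_first"` enters vision-based similarity in the baseline model
#' and adds language-based similarity in the test model (image-task
#' style); `"language_first"` is the reverse (word-task style).
#'
#' @param generator a [generator_config()].
#' @param lists a [list_config()].
#' @param response a [response_model()].
#' @param n_participants simulated participants (default 40).
#' @param order `"vision_first"` or `"language_first"`.
#' @param output_dir directory for run artifacts.
#' @param master_seed integer; every stage seed is derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(generator = generator_config(), lists = list_config(),
                       response = response_model(), n_participants = 40L,
                       order = c("vision_first", "language_first"),
                       output_dir = tempfile("drmsim_run"), master_seed = 1L) {
  order <- match.arg(order)
  structure(list(generator = generator, lists = lists, response = response,
                 n_participants = as.integer(n_participants), order = order,
                 output_dir = output_dir, master_seed = as.integer(master_seed)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full generation-to-inference pipeline
#'
#' Executes, under seeds derived from `master_seed`: coupled-space
#' generation, catalog filtering, list building, dual-space similarity
#' annotation and cross-modal correlation, response simulation,
#' compliance filtering, baseline and test GLMM fits in the configured
#' order, hierarchical AIC comparison, odds ratios per predictor,
#' collinearity check, interaction test, and recognition descriptives.
#' All artifacts (vector tables, lists, trial table, results JSON, run
#' manifest) are written under `config$output_dir`; a run is fully
#' determined by its manifest.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return a `results_bundle` list: `paths` (artifact files),
#'   `correlation`, `baseline`, `test` (`glmm_fit`s), `comparison`,
#'   `effects` (per-predictor [odds_ratio_ci()]s), `collinearity`,
#'   `interaction`, `summary` (recognition descriptives), `excluded`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  log_ <- if (quiet) function(...) invisible() else stage_log
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- config$master_seed

  cfg_g <- config$generator
  cfg_g$seed <- derive_seed(ms, 1L)
  spaces <- generate_coupled_spaces(cfg_g)
  log_("generate", "%d items; vision d=%d, language d=%d, alpha=%.3f",
       cfg_g$n_items, cfg_g$d_vision, cfg_g$d_language, cfg_g$alpha)

  catalog <- filter_catalog(spaces$catalog, quiet = TRUE)
  log_("filter", "%d of %d catalog items retained",
       nrow(catalog), nrow(spaces$catalog))

  cfg_l <- config$lists
  cfg_l$seed <- derive_seed(ms, 2L)
  lists <- build_lists(spaces$vision, cfg_l)
  log_("lists", "%d lists x (%d studied, %d targets, %d+%d lures)",
       length(lists), cfg_l$n_studied, cfg_l$n_targets,
       cfg_l$n_lure_close, cfg_l$n_lure_far)

  sim_tab <- similarity_table(lists, spaces$vision, spaces$language)
  correlation <- cross_modal_correlation(sim_tab)
  log_("similarity", "%d lure rows; cross-modal rho = %.3f (p = %.2g)",
       nrow(sim_tab), correlation$rho, correlation$p_value)

  trials <- simulate_responses(sim_tab, lists, config$response,
                               config$n_participants,
                               seed = derive_seed(ms, 3L),
                               catalog = spaces$catalog)
  log_("simulate", "%d participants, %d rows (%d lure rows)",
       config$n_participants, nrow(trials), sum(lure_rows(trials)))

  filt <- compliance_filter(trials, quiet = TRUE)
  log_("compliance", "%d participant(s) excluded; %d rows analyzed",
       length(filt$excluded), nrow(filt$table))
  analyzed <- standardize(filt$table, c("sim_vision_z", "sim_language_z"))

  predictors <- c(vision = "sim_vision_z", language = "sim_language_z")
  first <- if (config$order == "vision_first") predictors[["vision"]]
           else predictors[["language"]]
  baseline <- fit_glmm(analyzed, glmm_spec(fixed_terms = first))
  test <- fit_glmm(analyzed, glmm_spec(fixed_terms = unname(predictors)))
  comparison <- compare_hierarchical(baseline, test)
  log_("glmm", "baseline AIC %.1f, test AIC %.1f, dAIC %.2f, w(test) %.3f",
       baseline$aic, test$aic, comparison$delta_aic,
       comparison$akaike_weights[["test"]])

  effects <- lapply(unname(predictors), function(p) {
    row <- test$terms[test$terms$term == p, ]
    odds_ratio_ci(row$b, row$z)
  })
  names(effects) <- names(predictors)

  collinearity <- vif(analyzed, unname(predictors))
  interaction <- test_interaction(analyzed, glmm_spec(fixed_terms = unname(predictors)))
  log_("interaction", "dAIC favouring interaction = %.2f",
       interaction$comparison$delta_aic)
  summary <- recognition_summary(filt$table)

  paths <- list(
    vision = file.path(config$output_dir, "vision.vec"),
    language = file.path(config$output_dir, "language.vec"),
    lists = file.path(config$output_dir, "lists.tsv"),
    similarity = file.path(config$output_dir, "similarity.tsv"),
    trials = file.path(config$output_dir, "trials.tsv"),
    results = file.path(config$output_dir, "results.json"),
    summary = file.path(config$output_dir, "summary.tsv"),
    manifest = file.path(config$output_dir, "manifest.json"))
  write_vec_table(spaces$vision, paths$vision)
  write_vec_table(spaces$language, paths$language)
  write_lists(lists, paths$lists)
  utils::write.table(sim_tab, paths$similarity, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_trials(trials, paths$trials)
  write_summary_table(summary, paths$summary)

  results <- list(
    correlation = correlation,
    baseline = fit_summary(baseline),
    test = fit_summary(test),
    comparison = comparison,
    effects = effects,
    vif = as.list(collinearity$vif),
    interaction = interaction$comparison,
    excluded_participants = filt$excluded)
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    package = "drmsim",
    version = as.character(utils::packageVersion("drmsim")),
    master_seed = ms,
    order = config$order,
    n_participants = config$n_participants,
    generator = unclass(config$generator),
    lists = unclass(config$lists),
    response = unclass(config$response),
    stage_seeds = list(generate = derive_seed(ms, 1L),
                       lists = derive_seed(ms, 2L),
                       simulate = derive_seed(ms, 3L)),
    checksum = bundle_checksum(sim_tab, trials))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(paths = paths, correlation = correlation, baseline = baseline,
                 test = test, comparison = comparison, effects = effects,
                 collinearity = collinearity, interaction = interaction,
                 summary = summary, excluded = filt$excluded,
                 manifest = manifest), class = "results_bundle")
}

# order-insensitive content digest of the run's random artifacts; digest is
# a plain numeric hash so the bundle stays text-only and dependency-free
bundle_checksum <- function(sim_tab, trials) {
  s <- paste(c(format(sim_tab$sim_vision, digits = 12),
               format(sim_tab$sim_language, digits = 12),
               trials$item_id, trials$response), collapse = "|")
  v <- utf8ToInt(s)
  # rolling modular hash, kept in double-safe range
  h <- 0
  m <- 4294967291
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 9973))) %% m
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the configuration recorded in a
#' manifest and verifies the regenerated artifacts against the recorded
#' content checksum, erroring on any mismatch (e.g. a tampered seed).
#'
#' @param manifest path to a `manifest.json` written by [run_pipeline()].
#' @param output_dir directory for the replayed artifacts (a fresh
#'   temporary directory by default).
#' @return the replayed `results_bundle`.
#' @export
replay <- function(manifest, output_dir = tempfile("drmsim_replay")) {
  if (!file.exists(manifest)) {
    stop_drm("drm_io_error", "manifest not found: %s", manifest)
  }
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (!identical(m$package, "drmsim") || is.null(m$master_seed)) {
    stop_drm("drm_input_error", "not a drmsim run manifest: %s", manifest)
  }
  if (!identical(m$version, as.character(utils::packageVersion("drmsim")))) {
    stop_drm("drm_input_error",
             "manifest written by drmsim %s; this is %s — refusing to replay",
             m$version, utils::packageVersion("drmsim"))
  }
  cfg <- run_config(
    generator = do.call(generator_config, m$generator[setdiff(names(m$generator), "seed")]),
    lists = do.call(list_config, m$lists[setdiff(names(m$lists), "seed")]),
    response = do.call(response_model, as.list(m$response)),
    n_participants = m$n_participants, order = m$order,
    output_dir = output_dir, master_seed = m$master_seed)
  bundle <- run_pipeline(cfg, quiet = TRUE)
  if (!identical(bundle$manifest$checksum, m$checksum)) {
    stop_drm("drm_input_error",
             "replay checksum mismatch (%s vs recorded %s): manifest does not describe these artifacts",
             bundle$manifest$checksum, m$checksum)
  }
  bundle
}
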
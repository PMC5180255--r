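#' Pipeline run configuration
#'
#' One seeded configuration object driving the whole analysis: stimulus
#' geometry, V1 filter bank, perceptron settings, simulated cohorts, and
#' curve-fit settings. Every random stage derives its own sub-seed from the
#' global `seed` and a fixed stage label (see the internal scheme in
#' `derive_seed()`), so stages are individually re-runnable.
#'
#' @param seed Global integer seed.
#' @param geometry A `stim_geometry`.
#' @param spec A `filterbank_spec`.
#' @param params A `v1_params`.
#' @param max_epochs Perceptron epoch budget.
#' @param n_rats,n_humans Cohort sizes for the simulated groups.
#' @param rat_protocol,human_protocol Protocols.
#' @param strategy Strategy used by the simulated cohorts.
#' @param baseline Logistic-model baseline constant.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       geometry = stim_geometry(),
                       spec = filterbank_spec(),
                       params = v1_params(),
                       max_epochs = 20,
                       n_rats = 3,
                       n_humans = 8,
                       rat_protocol = protocol_rat(),
                       human_protocol = protocol_human(),
                       strategy = strategy_linear_template(),
                       baseline = 0.55) {
  structure(list(seed = as.integer(seed), geometry = geometry, spec = spec,
                 params = params, max_epochs = max_epochs, n_rats = n_rats,
                 n_humans = n_humans, rat_protocol = rat_protocol,
                 human_protocol = human_protocol, strategy = strategy,
                 baseline = baseline),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every structural invariant of the configuration and returns all
#' violations with actionable messages (an empty character vector means the
#' configuration is valid).
#'
#' @param config A `run_config`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "run_config")) return("not a run_config object")
  g <- config$geometry
  if (g$central_arm_width >= g$total_width)
    add("geometry: central arm wider than the canvas")
  if (config$spec$filter_size > min(g$nrow, g$ncol))
    add("filter bank: filter larger than the rendered image")
  if (length(config$spec$orientations) < 2)
    add("filter bank: need at least 2 orientations")
  if (length(config$spec$spatial_frequencies) < 2)
    add("filter bank: need at least 2 spatial frequencies")
  if (config$max_epochs < 1) add("perceptron: max_epochs must be >= 1")
  if (config$n_rats < 1) add("cohorts: n_rats must be >= 1")
  if (config$n_humans < 1) add("cohorts: n_humans must be >= 1")
  hp <- config$human_protocol
  n_pairs <- 4
  if (hp$block_length %% n_pairs != 0)
    add("human protocol: block length not divisible by pair count")
  if (hp$per_pair_per_block * n_pairs != hp$block_length)
    add("human protocol: per-pair repeats x pairs != block length")
  if (2 * hp$left_targets_per_block != hp$block_length)
    add("human protocol: left-target count must be half the block")
  for (sp in c("human", "rat")) {
    d <- logistic_fit_defaults(sp)
    if (any(d$lower > d$upper))
      add(sprintf("fit defaults (%s): lower bound above upper bound", sp))
  }
  if (config$baseline <= 0 || config$baseline > 1)
    add("fit: baseline must be in (0, 1]")
  v
}

#' Run the full analysis pipeline
#'
#' Deterministically (per seed) produces: the stimulus manifest and the
#' pixel- and model-based distance matrices with their within/between class
#' summaries; perceptron training histories on raw pixels and V1 responses
#' for both tasks; simulated rat and human cohorts for both tasks; backward
#' learning curves and logistic/linear fits; per-pair performance and
#' staged transfer analysis; template-model predictions for the manipulated
#' pair set; and a machine-readable summary.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory; when given, CSV/JSON artifacts
#'   are written (each with the seed recorded in a sidecar).
#' @return A list with all computed objects and a `summary` list.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  violations <- validate_config(config)
  if (length(violations) > 0)
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  seed <- config$seed
  res <- list(config = config)

  # --- stimuli and dissimilarities -------------------------------------
  configs <- make_base_set()
  images <- lapply(configs, render_stimulus, geometry = config$geometry)
  pix_d <- matrix(0, 4, 4, dimnames = list(names(configs), names(configs)))
  for (i in 1:3) for (j in (i + 1):4)
    pix_d[i, j] <- pix_d[j, i] <- pixel_distance(images[[i]], images[[j]])
  vm <- v1_response_matrix(images, config$spec, config$params)
  res$pixel_distances <- pix_d
  res$model_distances <- vm$distances
  res$class_summary <- list(
    pixel_linear = class_distance_from_matrix(task_mapping("linear"), pix_d),
    pixel_nonlinear = class_distance_from_matrix(task_mapping("nonlinear"), pix_d),
    model_linear = class_distance_from_matrix(task_mapping("linear"), vm$distances),
    model_nonlinear = class_distance_from_matrix(task_mapping("nonlinear"), vm$distances)
  )

  # --- perceptron readout (reusing the V1 responses computed above) ----
  res$perceptron <- list()
  pix_feats <- t(vapply(images, function(im) as.vector(im$pixels * 1.0),
                        numeric(length(images[[1]]$pixels))))
  v1_feats <- t(vapply(vm$responses, function(r) r$values,
                       numeric(length(vm$responses[[1]]$values))))
  for (space in c("pixels", "v1")) {
    feats <- if (space == "pixels") pix_feats else v1_feats
    for (tk in c("linear", "nonlinear")) {
      labs <- vapply(configs, task_mapping(tk)$class_of, "")
      ds <- labeled_dataset(feats, labs, ids = names(configs))
      res$perceptron[[paste(space, tk, sep = "_")]] <-
        perceptron_train(ds, max_epochs = config$max_epochs)
    }
  }

  # --- simulated cohorts ------------------------------------------------
  res$cohorts <- list()
  for (tk in c("linear", "nonlinear")) {
    res$cohorts[[paste0("rat_", tk)]] <- simulate_cohort(
      config$n_rats, config$strategy, task_mapping(tk), config$rat_protocol,
      base_seed = derive_seed(seed, paste0("rat_", tk)))
    res$cohorts[[paste0("human_", tk)]] <- simulate_cohort(
      config$n_humans, strategy_oracle(lapse_rate = 0.15), task_mapping(tk),
      config$human_protocol,
      base_seed = derive_seed(seed, paste0("human_", tk)))
  }

  # --- backward curves and fits ----------------------------------------
  res$curves <- list(); fits_species <- c()
  linear_for <- character(0)
  for (nm in names(res$cohorts)) {
    sp <- if (startsWith(nm, "rat")) "rat" else "human"
    proto <- if (sp == "rat") config$rat_protocol else config$human_protocol
    reached <- vapply(res$cohorts[[nm]], function(l)
      attr(l, "criterion_reached"), TRUE)
    curve <- tryCatch(
      suppressWarnings(backward_curve(
        res$cohorts[[nm]], proto,
        align = if (any(reached)) "criterion" else "end")),
      error = function(e) NULL)
    if (!is.null(curve)) {
      res$curves[[nm]] <- curve
      fits_species[nm] <- sp
      if (!any(reached)) linear_for <- c(linear_for, nm)
    }
  }
  res$fit_report <- model_selection_report(res$curves, fits_species,
                                           baseline = config$baseline,
                                           linear_for = linear_for)

  # --- strategy analysis -------------------------------------------------
  mp <- build_manipulated_pairs(task_mapping("linear"))
  res$manipulated <- mp
  res$template_predictions <- lapply(
    c(full = "full", upper_field = "upper_field", lower_field = "lower_field"),
    function(kind) template_predictions(
      template_model(kind, config$geometry),
      mp$pairs[!mp$pairs$identical, , drop = FALSE], config$geometry,
      mode = "graded"))

  staged <- simulate_staged_subject(config$strategy,
                                    task_mapping("nonlinear"),
                                    config$rat_protocol,
                                    seed = derive_seed(seed, "staged"))
  res$transfer <- transfer_analysis(staged)
  res$per_pair <- per_pair_performance(
    do.call(rbind, res$cohorts$rat_nonlinear), last_sessions = 10)

  # --- summary -----------------------------------------------------------
  crit_frac <- function(nm) mean(vapply(res$cohorts[[nm]], function(l)
    attr(l, "criterion_reached"), TRUE))
  res$summary <- list(
    seed = seed,
    n_manipulated_positives = length(mp$positives),
    n_manipulated_negatives = length(mp$negatives),
    n_pairs_raw = mp$n_raw,
    n_pairs_removed = mp$n_removed,
    n_pairs_retained = mp$n_retained,
    class_summary = res$class_summary,
    perceptron_converged = lapply(res$perceptron, `[[`, "converged"),
    cohort_criterion_fraction = stats::setNames(
      lapply(names(res$cohorts), crit_frac), names(res$cohorts)),
    transfer_first_session = stats::setNames(
      as.list(res$transfer$first_session$accuracy),
      res$transfer$first_session$pair)
  )

  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# Write the pipeline artifacts (CSV/JSON) with a seed sidecar.
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stimulus_manifest(file.path(out_dir, "stimuli"),
                          res$config$geometry)
  utils::write.csv(res$pixel_distances,
                   file.path(out_dir, "pixel_distances.csv"))
  utils::write.csv(res$model_distances,
                   file.path(out_dir, "model_distances.csv"))
  hist <- do.call(rbind, lapply(names(res$perceptron), function(nm)
    data.frame(run = nm, epoch = seq_along(res$perceptron[[nm]]$epoch_history),
               accuracy = res$perceptron[[nm]]$epoch_history)))
  utils::write.csv(hist, file.path(out_dir, "perceptron_history.csv"),
                   row.names = FALSE)
  for (nm in names(res$curves)) {
    utils::write.csv(res$curves[[nm]],
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(res$fit_report, file.path(out_dir, "fit_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$per_pair, file.path(out_dir, "per_pair.csv"),
                   row.names = FALSE)
  for (nm in names(res$template_predictions))
    utils::write.csv(res$template_predictions[[nm]],
                     file.path(out_dir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("seed: %d", res$config$seed),
               sprintf("package: crosslearn %s",
                       as.character(utils::packageVersion("crosslearn")))),
             file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}
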
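#' Default pipeline configuration
#'
#' All stage parameters in one list: the synthetic-cohort settings, the
#' variable-selection threshold, the PCA variance target and k-range, the
#' transition day grid, the proteomics screen settings and the MCCV
#' configuration. Any element can be overridden; a YAML file with the same
#' structure can be passed to [run_pipeline()] instead.
#'
#' @param seed Master seed; every stochastic stage derives its own child
#'   seed from it (recorded in the manifest).
#' @param n_patients Cohort size for the simulate stage.
#' @param ... Overrides for individual elements.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1, n_patients = 384, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("simulate", "preprocess", "cluster", "trajectories",
               "proteomics", "classify"),
    simulate = list(n_patients = n_patients, days = c(1, 4, 7, 10),
                    n_proteins = 609, n_batches = 4, batch_effect_sd = 0.5,
                    missing_rate = 0.10),
    preprocess = list(threshold = 0.30),
    cluster = list(variance_target = 0.70, k_range = 2:8, n_restarts = 10,
                   use_focus = TRUE),
    proteomics = list(min_n = 5),
    classify = list(r_max = 0.7, n_outer = 25, n_inner = 25,
                    num_trees = 200, rebalance_factor = 0.6,
                    max_features = 10),
    inputs = list()
  )
  utils::modifyList(cfg, list(...))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(pipeline_config(), config)
}

#' Run the full phenotyping pipeline
#'
#' Executes, in order: cohort simulation (or loading of input files),
#' preprocessing (variable selection, daily aggregation, lookahead
#' imputation), phenotype derivation, trajectory and transition analysis,
#' the proteome differential-abundance screen, and the compact-feature
#' classifier. All intermediates are written as CSV/JSON into `out_dir`
#' together with a manifest (stage seeds, row counts, configuration) so any
#' single stage can be re-run bit-identically.
#'
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("septaphen")),
    seed = cfg$seed, stages = list(), config = cfg)
  res <- list()
  stage_on <- function(s) s %in% cfg$stages

  ## ---- simulate ----------------------------------------------------------
  if (stage_on("simulate")) {
    seed_sim <- child_seed(cfg$seed, "simulate")
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed_sim)))
    cohort <- generate_cohort(sc)
    proteome <- generate_proteome(cohort$truth, sc)
    write_csv17(cohort$observations, file.path(out_dir, "observations.csv"))
    write_csv17(cohort$truth$outcomes, file.path(out_dir, "outcomes.csv"))
    write_csv17(cohort$truth$states, file.path(out_dir, "true_states.csv"))
    write_csv17(cohort$focus, file.path(out_dir, "focus.csv"))
    manifest$stages$simulate <- list(seed = seed_sim,
                                     n_observations = nrow(cohort$observations),
                                     n_patients = sc$n_patients)
    res$cohort <- cohort
    res$proteome <- proteome
  } else {
    paths <- cfg$inputs
    for (p in c("observations", "outcomes", "focus")) {
      if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
        stop("pipeline input missing: ", p, " (",
             paths[[p]] %||% "unset", ")", call. = FALSE)
      }
    }
    obs <- utils::read.csv(paths$observations, stringsAsFactors = FALSE)
    outcomes <- utils::read.csv(paths$outcomes, stringsAsFactors = FALSE)
    focus <- utils::read.csv(paths$focus, stringsAsFactors = FALSE)
    res$cohort <- list(observations = obs,
                       truth = list(outcomes = outcomes, states = NULL),
                       focus = focus)
    if (stage_on("proteomics")) {
      if (is.null(paths$proteome) || !file.exists(paths$proteome)) {
        stop("pipeline input missing: proteome (",
             paths$proteome %||% "unset", ")", call. = FALSE)
      }
      res$proteome <- read_protein_matrix(paths$proteome)
    }
  }

  ## ---- preprocess --------------------------------------------------------
  if (stage_on("preprocess")) {
    obs <- res$cohort$observations
    specs <- select_variables(obs, day = 1,
                              threshold = cfg$preprocess$threshold)
    daily <- aggregate_daily(obs, specs)
    days <- as.numeric(names(daily))
    d1 <- impute_lookahead(daily[[1]],
                           if (length(daily) > 1) daily[[2]] else NULL,
                           if (length(daily) > 2) daily[[3]] else NULL)
    write_csv17(specs, file.path(out_dir, "variable_specs.csv"))
    write_csv17(data.frame(patient_id = rownames(d1), d1,
                           check.names = FALSE),
                file.path(out_dir, "day1_matrix.csv"))
    manifest$stages$preprocess <- list(
      n_retained = sum(specs$retained), n_patients_day1 = nrow(d1))
    res$specs <- specs
    res$daily <- daily
    res$day1 <- d1
  }

  ## ---- cluster -----------------------------------------------------------
  if (stage_on("cluster")) {
    seed_cl <- child_seed(cfg$seed, "cluster")
    focus <- if (isTRUE(cfg$cluster$use_focus)) res$cohort$focus else NULL
    model <- derive_phenotypes(res$day1,
                               variance_target = cfg$cluster$variance_target,
                               k_range = cfg$cluster$k_range,
                               seed = seed_cl, focus = focus,
                               n_restarts = cfg$cluster$n_restarts)
    write_phenotype_model(model, file.path(out_dir, "phenotype_model.json"))
    write_csv17(data.frame(patient_id = names(model$labels), day = 1,
                           phenotype = unname(model$labels)),
                file.path(out_dir, "labels_day1.csv"))
    manifest$stages$cluster <- list(seed = seed_cl, k = model$k,
                                    m = model$pca$m,
                                    sizes = as.integer(table(model$labels)))
    res$model <- model
  }

  ## ---- trajectories ------------------------------------------------------
  if (stage_on("trajectories")) {
    days <- as.numeric(names(res$daily))
    d1_medians <- apply(res$daily[[1]], 2, stats::median, na.rm = TRUE)
    focus_v <- stats::setNames(res$cohort$focus$focus,
                               res$cohort$focus$patient_id)
    assignments <- list()
    assignments[[as.character(days[1])]] <- res$model$labels
    for (i in seq_along(days)[-1]) {
      lookahead <- list(if (i + 1 <= length(days)) res$daily[[i + 1]] else NULL,
                        if (i + 2 <= length(days)) res$daily[[i + 2]] else NULL)
      di <- impute_lookahead(res$daily[[i]], lookahead[[1]], lookahead[[2]],
                             fallback = d1_medians)
      assignments[[as.character(days[i])]] <-
        predict(res$model, di, focus = focus_v)
    }
    traj <- build_trajectories(assignments, res$cohort$truth$outcomes, days)
    trans <- build_transitions(traj)
    summ <- transition_summary(trans, traj, res$cohort$truth$outcomes)
    write_csv17(traj, file.path(out_dir, "trajectories.csv"))
    trans_long <- do.call(rbind, lapply(trans, function(tt) {
      df <- as.data.frame(as.table(tt$counts), stringsAsFactors = FALSE)
      names(df) <- c("source_state", "target_state", "count")
      cbind(source_day = tt$source_day, target_day = tt$target_day, df)
    }))
    write_csv17(trans_long, file.path(out_dir, "transitions.csv"))
    manifest$stages$trajectories <- list(n_day_pairs = length(trans),
                                         n_states = nrow(traj))
    res$trajectories <- traj
    res$transitions <- trans
    res$transition_summary <- summ
  }

  ## ---- proteomics --------------------------------------------------------
  if (stage_on("proteomics")) {
    pm <- res$proteome
    norm <- normalize_batches(pm$intensity, pm$batch)
    labels <- if (!is.null(res$model)) {
      res$model$labels[rownames(norm)]
    } else {
      pm$phenotype[rownames(norm)]
    }
    da <- differential_abundance(norm, labels, min_n = cfg$proteomics$min_n)
    write_csv17(da, file.path(out_dir, "da_results.csv"))
    manifest$stages$proteomics <- list(
      n_tested = nrow(da), n_excluded = attr(da, "n_excluded"))
    res$da <- da
  }

  ## ---- classify ----------------------------------------------------------
  if (stage_on("classify")) {
    seed_ml <- child_seed(cfg$seed, "classify")
    labels <- res$model$labels
    xall <- res$day1[names(labels), , drop = FALSE]
    kept <- correlation_prune(xall, r_max = cfg$classify$r_max)
    cfg_ml <- mccv_config(n_outer = cfg$classify$n_outer,
                          n_inner = cfg$classify$n_inner,
                          num_trees = cfg$classify$num_trees,
                          rebalance_factor = cfg$classify$rebalance_factor,
                          seed = seed_ml)
    ranking <- shap_rank_features(xall[, kept, drop = FALSE], labels, cfg_ml)
    top <- utils::head(ranking$feature, cfg$classify$max_features)
    curve <- mccv_recall_curve(xall[, top, drop = FALSE], labels, top, cfg_ml)
    knee <- knee_select(curve)
    chosen <- top[seq_len(knee)]
    report <- evaluate_final(xall, labels, chosen, cfg_ml, knee_f = knee)
    write_csv17(as.data.frame(curve), file.path(out_dir, "recall_curve.csv"))
    writeLines(chosen, file.path(out_dir, "chosen_features.txt"))
    jsonlite::write_json(
      list(macro = report$macro, overfitting = report$overfitting,
           notes = report$notes),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$classify <- list(seed = seed_ml, n_pruned = length(kept),
                                     knee = knee, chosen = chosen,
                                     overfitting = report$overfitting)
    res$ranking <- ranking
    res$recall_curve <- curve
    res$knee <- knee
    res$report <- report
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Read a samples x proteins CSV into the proteome container
#'
#' Expected layout: first column sample id, a `batch` column, optionally a
#' `phenotype` column, remaining columns protein identifiers (log2
#' intensities, empty = missing).
#'
#' @param path CSV path.
#' @return List with `intensity`, `batch`, `phenotype`.
#' @export
read_protein_matrix <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- x[[1]]
  batch <- stats::setNames(x$batch, ids)
  phenotype <- if ("phenotype" %in% names(x))
    stats::setNames(x$phenotype, ids) else NULL
  drop <- c(names(x)[1], "batch", "phenotype")
  m <- as.matrix(x[, setdiff(names(x), drop), drop = FALSE])
  rownames(m) <- ids
  list(intensity = m, batch = batch, phenotype = phenotype)
}

#' Write the proteome container as a samples x proteins CSV
#'
#' @param pm List with `intensity`, `batch` and optionally `phenotype`.
#' @param path Output path.
#' @export
write_protein_matrix <- function(pm, path) {
  df <- data.frame(sample_id = rownames(pm$intensity),
                   batch = unname(pm$batch[rownames(pm$intensity)]),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(pm$phenotype)) {
    df$phenotype <- unname(pm$phenotype[rownames(pm$intensity)])
  }
  write_csv17(cbind(df, as.data.frame(pm$intensity, check.names = FALSE)),
              path)
}
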
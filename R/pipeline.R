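#' Build a run configuration
#'
#' A single configuration drives the whole protocol: data source, gene-tier
#' policy, feature selection, the model zoo, cross-validation scale,
#' consensus and applicability-domain settings, and the run seed. One global
#' seed fans out to per-stage seeds through stable hashing of stage labels,
#' so any stage reruns reproducibly on its own.
#'
#' @param endpoint endpoint name (`"ER"`, `"AR"`, `"TR"`).
#' @param cohort `NULL`, or a list of [synth_config()] arguments used to
#'   simulate the input cohort.
#' @param signature_paths named list (per cell line) of signature TSV paths,
#'   used when `cohort` is `NULL`.
#' @param activity_path activity-table TSV path, used when `cohort` is
#'   `NULL`.
#' @param tiers gene tiers kept for modelling (default `"landmark"`).
#' @param use_selector run MultiSURF feature selection (default `TRUE`).
#' @param models named list of [model_spec()] objects (default
#'   [default_model_zoo()]).
#' @param repeats,folds,inner_folds outer-CV repetitions/folds and inner
#'   grid-search folds (protocol scale: 10 / 5 / 5).
#' @param n_validation chemicals sampled into the shared validation set.
#' @param ad list with `k`, `Z` and `tiers` for the applicability domain
#'   (defaults: 3 nearest neighbours, `Z = 0.5`, landmark + best-inferred
#'   features).
#' @param seed global integer seed.
#' @param out_dir artifact directory.
#' @return A `run_config` list.
#' @export
run_config <- function(endpoint = "ER", cohort = NULL,
                       signature_paths = NULL, activity_path = NULL,
                       tiers = "landmark", use_selector = TRUE,
                       models = default_model_zoo(), repeats = 10L,
                       folds = 5L, inner_folds = 5L, n_validation = 0L,
                       ad = list(k = 3L, Z = 0.5,
                                 tiers = c("landmark", "best_inferred")),
                       seed = 1L, out_dir = tempfile("qgexar_run_")) {
  structure(list(endpoint = endpoint, cohort = cohort,
                 signature_paths = signature_paths,
                 activity_path = activity_path, tiers = tiers,
                 use_selector = isTRUE(use_selector), models = models,
                 repeats = as.integer(repeats), folds = as.integer(folds),
                 inner_folds = as.integer(inner_folds),
                 n_validation = as.integer(n_validation),
                 ad = modifyList(list(k = 3L, Z = 0.5,
                                      tiers = c("landmark", "best_inferred")),
                                 as.list(ad)),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `models` field
#' is a list of algorithm names (given default grids) or of
#' name-to-grid mappings.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$models)) {
    raw$models <- if (is.character(raw$models))
      setNames(lapply(raw$models, model_spec), raw$models)
    else
      setNames(lapply(names(raw$models), function(a)
        model_spec(a, grid = raw$models[[a]])), names(raw$models))
  }
  do.call(run_config, raw)
}

#' Validate a run configuration
#'
#' Collects every violation rather than failing on the first.
#'
#' @param config a `run_config`.
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  if (config$folds < 2L) v <- c(v, "folds must be at least 2")
  if (config$inner_folds < 2L) v <- c(v, "inner_folds must be at least 2")
  if (config$repeats < 1L) v <- c(v, "repeats must be at least 1")
  if (config$n_validation < 0L) v <- c(v, "n_validation must be >= 0")
  if (config$ad$k < 1L) v <- c(v, "ad k must be at least 1")
  if (!length(config$models)) v <- c(v, "at least one model is required")
  bad_tier <- setdiff(config$tiers, c("landmark", "best_inferred", "inferred"))
  if (length(bad_tier))
    v <- c(v, paste("unknown tier:", paste(bad_tier, collapse = ", ")))
  if (is.null(config$cohort)) {
    if (is.null(config$signature_paths) || is.null(config$activity_path))
      v <- c(v, "either a cohort spec or dataset paths are required")
    for (p in c(unlist(config$signature_paths), config$activity_path))
      if (!is.null(p) && !file.exists(p))
        v <- c(v, paste("missing dataset path:", p))
  }
  v
}

# Artifact writer: first line records the config hash, then a TSV.
write_artifact <- function(df, path, hash) {
  cat(sprintf("# config_hash: %s\n", hash), file = path)
  suppressWarnings(
    data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE))
  invisible(path)
}

#' Read a pipeline artifact TSV (skipping the config-hash header)
#'
#' @param path artifact path written by [run_all()].
#' @return data.frame.
#' @export
read_artifact <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", skip = 1L))
}

#' Run the full protocol
#'
#' Orchestrates the pipeline end to end: obtain (or simulate) per-cell-line
#' signature matrices and activity records; resolve label conflicts and
#' deduplicate profiles by TAS; restrict gene tiers; draw the shared
#' validation split; per cell line, run every model of the zoo through outer
#' repeated cross-validation (with MultiSURF selection inside each fold when
#' enabled), pick the best model by mean balanced accuracy, refit it on the
#' full training set and score the validation chemicals; combine the
#' cell-line probabilities into the consensus prediction; assess the
#' applicability domain; and report Kruskal-Wallis gene importance. All
#' tables are written as TSV under `config$out_dir`, each carrying the config
#' hash, together with a JSON run manifest.
#'
#' @param config a validated [run_config()].
#' @return (invisibly) a list with per-cell-line results (`cv_reports`,
#'   `best`, `final`, `validation_metrics`), `consensus`
#'   (table + metrics), `ad` (per cell line), `importance` (per cell line),
#'   `split`, `manifest`.
#' @export
run_all <- function(config) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))

  ## --- data ---------------------------------------------------------------
  if (!is.null(config$cohort)) {
    cfg <- do.call(synth_config, config$cohort)
    cohort <- generate_cohort(cfg)
    raw_sigs <- cohort$signatures
    raw_activity <- cohort$activity
    if (cfg$duplicate_profile_rate > 0 || cfg$conflict_label_rate > 0) {
      for (cl in names(raw_sigs)) {
        inj <- inject_duplicates(raw_sigs[[cl]], raw_activity, cfg)
        raw_sigs[[cl]] <- inj$matrix
        raw_activity <- inj$activity
      }
    }
  } else {
    raw_sigs <- lapply(config$signature_paths, read_signature_matrix)
    raw_activity <- read_activity_table(config$activity_path)
  }

  ## --- assembly -----------------------------------------------------------
  activity <- resolve_activity_conflicts(raw_activity)
  activity <- activity[activity$endpoint == config$endpoint, , drop = FALSE]
  sigs_full <- lapply(raw_sigs, dedupe_profiles_by_tas)
  sigs <- lapply(sigs_full, filter_gene_tier, keep = config$tiers)
  split <- make_split(sigs, activity, config$n_validation,
                      seed = stage_seed(config$seed, "split"))
  write_split(split, out("split.tsv"))
  datasets <- lapply(sigs, assemble_dataset, activity = activity,
                     split = split)

  selector <- if (config$use_selector) multisurf_selector() else NULL
  results <- list()
  valid_probs <- list()

  for (cl in names(datasets)) {
    ds <- datasets[[cl]]
    rownames(ds$x_valid) <- ds$chemical_valid
    reports <- lapply(config$models, function(spec)
      outer_repeated_cv(ds$x_train, ds$y_train, spec,
                        repeats = config$repeats, k = config$folds,
                        feature_selector = selector,
                        inner_k = config$inner_folds,
                        seed = stage_seed(config$seed, paste0("cv_", cl))))
    cv_rows <- do.call(rbind, lapply(reports, function(r)
      cbind(algorithm = r$label, r$folds)))
    write_artifact(cv_rows, out("cv_report_", cl, ".tsv"), hash)
    cv_agg <- do.call(rbind, lapply(reports, function(r)
      cbind(algorithm = r$label, r$aggregate)))
    write_artifact(cv_agg, out("cv_aggregate_", cl, ".tsv"), hash)

    best <- select_best_model(reports)
    final <- fit_final_and_predict(
      ds$x_train, ds$y_train, best, ds$x_valid,
      feature_selector = selector, inner_k = config$inner_folds,
      seed = stage_seed(config$seed, paste0("final_", cl)))
    if (config$use_selector) {
      w <- multisurf_weights(ds$x_train, ds$y_train)
      write_feature_weights(w, out("feature_weights_", cl, ".tsv"))
    }
    vm <- if (length(final$probabilities))
      metric_set(confusion(final$probabilities, ds$y_valid),
                 final$probabilities, ds$y_valid) else NULL
    if (length(final$probabilities))
      write_artifact(
        data.frame(chemical_id = ds$chemical_valid,
                   probability = unname(final$probabilities),
                   label = ds$y_valid),
        out("validation_predictions_", cl, ".tsv"), hash)
    results[[cl]] <- list(cv_reports = reports, best = best, final = final,
                          validation_metrics = vm)
    valid_probs[[cl]] <- final$probabilities
  }

  ## --- consensus ----------------------------------------------------------
  consensus <- NULL
  if (config$n_validation > 0 && length(valid_probs) >= 1L) {
    cons_tab <- consensus_probability(valid_probs)
    y_valid <- datasets[[1]]$y_valid
    names(y_valid) <- datasets[[1]]$chemical_valid
    cons_ms <- evaluate_consensus(cons_tab, y_valid)
    write_artifact(cons_tab, out("consensus.tsv"), hash)
    consensus <- list(table = cons_tab, metrics = cons_ms)
  }

  ## --- applicability domain ----------------------------------------------
  ad <- list()
  if (config$n_validation > 0) {
    for (cl in names(sigs_full)) {
      m <- filter_gene_tier(sigs_full[[cl]], keep = config$ad$tiers)
      tr_idx <- match(split$training[[cl]], m$chemical_id)
      va_idx <- match(split$validation, m$chemical_id)
      xt <- m$values[tr_idx, , drop = FALSE]
      rownames(xt) <- split$training[[cl]]
      xv <- m$values[va_idx, , drop = FALSE]
      rownames(xv) <- split$validation
      assess <- assess_domain(xv, xt, Z = config$ad$Z, k = config$ad$k)
      write_artifact(assess, out("ad_", cl, ".tsv"), hash)
      curve <- coverage_curve(assess$mean_top3_cosine,
                              valid_probs[[cl]][split$validation],
                              datasets[[cl]]$y_valid)
      write_artifact(curve, out("ad_curve_", cl, ".tsv"), hash)
      ad[[cl]] <- list(assessment = assess, curve = curve)
    }
  }

  ## --- gene importance ----------------------------------------------------
  importance <- list()
  for (cl in names(datasets)) {
    ds <- datasets[[cl]]
    imp <- kruskal_wallis_genes(ds$x_train, ds$y_train)
    write_artifact(imp, out("importance_", cl, ".tsv"), hash)
    importance[[cl]] <- imp
  }

  manifest <- list(
    config_hash = hash, endpoint = config$endpoint, seed = config$seed,
    tiers = config$tiers, use_selector = config$use_selector,
    models = names(config$models), repeats = config$repeats,
    folds = config$folds, n_validation = config$n_validation,
    best_algorithm = lapply(results, function(r) r$best$label),
    package_version = as.character(utils::packageVersion("qgexar")),
    artifacts = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(results = results, consensus = consensus, ad = ad,
                 importance = importance, split = split, manifest = manifest,
                 out_dir = config$out_dir))
}
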
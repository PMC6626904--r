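#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end run in one list. The cohort is
#' either simulated (`simulate` is a `simulation_config`) or read from disk
#' (`manifest` is a `cohort_manifest` whose records carry `source` paths).
#'
#' @param simulate a `simulation_config`, or `NULL` to read files.
#' @param manifest a `cohort_manifest` with `source` paths (ignored when
#'   simulating).
#' @param cofactor arcsinh cofactor.
#' @param k,n_meta,min_cluster_fraction,min_meta_fraction clustering
#'   parameters (study defaults 49 / 15 / 1e-5 / 0.005).
#' @param annotation_threshold `"midrange"` or `"median"`.
#' @param min_cells minimum events backing a feature cell.
#' @param models feature model variants to run.
#' @param n_lambda,lambda_min_ratio penalty grid shape.
#' @param seed master seed for cleanup initialization and the FPS start.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, manifest = NULL, cofactor = 5,
                            k = 49L, n_meta = 15L,
                            min_cluster_fraction = 1e-5,
                            min_meta_fraction = 0.005,
                            annotation_threshold = "midrange",
                            min_cells = 10L,
                            models = c("basal", "ratio", "combined"),
                            n_lambda = 50L, lambda_min_ratio = 1e-3,
                            seed = 1L) {
  if (is.null(simulate) && is.null(manifest))
    stop("either a simulation config or a manifest with sources is required")
  structure(list(simulate = simulate, manifest = manifest,
                 cofactor = cofactor, k = k, n_meta = n_meta,
                 min_cluster_fraction = min_cluster_fraction,
                 min_meta_fraction = min_meta_fraction,
                 annotation_threshold = annotation_threshold,
                 min_cells = min_cells, models = models,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `simulate` holds [simulation_config()] arguments (plus optional
#' `scenario: paper` and `effect_scale` to start from
#' [default_paper_scenario()]).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    if (identical(s$scenario, "paper")) {
      args <- s[setdiff(names(s), "scenario")]
      sim <- do.call(default_paper_scenario, args)
    } else {
      sim <- do.call(simulation_config, s)
    }
  }
  manifest <- NULL
  if (!is.null(y$manifest)) manifest <- cohort_manifest(
    as.data.frame(do.call(rbind, lapply(y$manifest, as.data.frame))))
  args <- y[setdiff(names(y), c("simulate", "manifest"))]
  do.call(pipeline_config, c(list(simulate = sim, manifest = manifest), args))
}

#' Run the full analysis pipeline
#'
#' Simulate-or-read, per-sample QC cleanup, arcsinh transform, pooled FPS
#' clustering with meta-clustering and annotation, feature extraction,
#' lasso classification under double leave-one-out cross-validation for
#' each requested model variant, final non-zero coefficients, PCA of the
#' selected combined-model features, group comparisons and abundances. All
#' exports are written under `out_dir`, together with a JSON log of every
#' threshold applied and per-stage event counts. Re-running with the same
#' configuration reproduces all numeric outputs exactly.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   all file exports.
#' @return list with all intermediate results (`manifest`, `cleanup`,
#'   `clustering`, `features`, `cv`, `final`, `pca`, `comparisons`,
#'   `abundance`), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    manifest <- sim$manifest
    tables <- sim$tables
    truth <- sim$truth
  } else {
    manifest <- config$manifest
    r <- manifest$records
    tables <- stage("read", lapply(seq_len(nrow(r)), function(i)
      read_events(r$source[i], default_panel(config$cofactor), r[i, ])))
  }
  if (any(config$models != "basal")) check_paired(manifest)

  cleaned <- stage("cleanup", clean_cohort(tables, seed = config$seed))
  transformed <- stage("transform", lapply(cleaned$tables, arcsinh_transform,
                                           cofactor = config$cofactor))
  clustering <- stage("cluster", cluster_cohort(
    transformed, k = config$k, n_meta = config$n_meta, seed = config$seed,
    min_cluster_fraction = config$min_cluster_fraction,
    min_meta_fraction = config$min_meta_fraction,
    threshold = config$annotation_threshold))

  features <- list(); cv <- list(); final <- list()
  for (m in config$models) {
    features[[m]] <- stage(paste0("features/", m), build_feature_table(
      transformed, clustering, model = m, min_cells = config$min_cells))
    cv[[m]] <- stage(paste0("classify/", m), double_loocv(
      features[[m]], n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio))
    final[[m]] <- stage(paste0("classify/", m), final_nonzero_coefficients(
      features[[m]], n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio))
  }
  pca <- NULL
  if ("combined" %in% config$models &&
      nrow(final[["combined"]]$nonzero) >= 2L)
    pca <- stage("pca", pca_selected(features[["combined"]],
                                     final[["combined"]]$nonzero$name))
  comparisons <- stage("compare", compare_groups(transformed, clustering))
  abundance <- stage("compare", abundance_table(transformed, clustering))

  result <- list(manifest = manifest, truth = truth,
                 cleanup = cleaned$report, clustering = clustering,
                 features = features, cv = cv, final = final, pca = pca,
                 comparisons = comparisons, abundance = abundance,
                 config = config)
  if (is.null(out_dir)) return(result)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) utils::write.table(
    df, file.path(out_dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(manifest$records, "manifest.tsv")
  jsonlite::write_json(cleaned$report, file.path(out_dir, "cleanup_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  mm <- clustering$meta_model
  w(data.frame(meta_id = rownames(mm$profiles),
               annotation = mm$annotations[rownames(mm$profiles)],
               abundance = mm$abundance[mm$kept_metas], mm$profiles,
               check.names = FALSE), "meta_profiles.tsv")
  for (m in names(features)) {
    write_feature_table(features[[m]],
                        file.path(out_dir, sprintf("features_%s.tsv", m)))
    jsonlite::write_json(list(
      model = m, cv_accuracy = cv[[m]]$cv_accuracy, auc = cv[[m]]$auc,
      confusion = as.data.frame(cv[[m]]$confusion),
      probabilities = data.frame(individual_id = cv[[m]]$individuals,
                                 truth = cv[[m]]$truth,
                                 probability_RA = cv[[m]]$probabilities,
                                 predicted = cv[[m]]$predicted),
      selected_lambda_per_fold = cv[[m]]$selected_lambda_per_fold),
      file.path(out_dir, sprintf("cv_%s.json", m)),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    w(final[[m]]$nonzero, sprintf("coefficients_%s.tsv", m))
  }
  if (!is.null(pca))
    w(data.frame(individual_id = rownames(pca$scores),
                 group = attr(pca$scores, "group"), unclass(pca$scores)),
      "pca_scores.tsv")
  w(comparisons, "comparisons.tsv")
  w(abundance, "abundance.tsv")
  log <- list(
    package_version = as.character(utils::packageVersion("cytofps")),
    r_version = R.version.string,
    seed = config$seed, cofactor = config$cofactor,
    k = config$k, n_meta = config$n_meta,
    min_cluster_fraction = config$min_cluster_fraction,
    min_meta_fraction = config$min_meta_fraction,
    annotation_threshold = config$annotation_threshold,
    min_cells = config$min_cells,
    n_lambda = config$n_lambda, lambda_min_ratio = config$lambda_min_ratio,
    events_in = sum(cleaned$report$n_total),
    events_kept = sum(cleaned$report$n_kept),
    n_clusters_kept = length(clustering$cluster_model$kept_clusters),
    n_metas_kept = length(mm$kept_metas))
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
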
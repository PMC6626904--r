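#' Summary statistic of a marker within a subset
#'
#' Median, or 90% quantile by linear interpolation between order statistics
#' (`h = (n-1) * 0.9`, the type-7 convention).
#'
#' @param values numeric vector (arcsinh scale).
#' @param statistic `"median"` or `"q90"`.
#' @return The summary value, or `NA` for empty input (handled downstream
#'   by imputation).
#' @export
subset_summary <- function(values, statistic = c("median", "q90")) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) return(NA_real_)
  switch(statistic,
         median = stats::median(values),
         q90 = unname(stats::quantile(values, 0.9, type = 7)))
}

#' Stimulation-vs-basal arcsinh ratio
#'
#' The stimulation-induced change of a marker on the arcsinh scale: the
#' difference of the stimulated and basal medians of already
#' arcsinh-transformed values (the phospho-cytometry "arcsinh ratio").
#'
#' @param stim_values,basal_values arcsinh-scale values from the stimulated
#'   and basal condition.
#' @return `median(stim) - median(basal)`, or `NA` if either side is empty.
#' @export
arcsinh_ratio <- function(stim_values, basal_values) {
  if (length(stim_values) == 0L || length(basal_values) == 0L)
    return(NA_real_)
  stats::median(stim_values) - stats::median(basal_values)
}

feature_descriptors <- function(meta, panel, model) {
  fun_ch <- panel_channels(panel, "functional")
  markers <- panel_markers(panel, "functional")
  stats_for <- switch(model,
                      basal = c("median_basal", "q90_basal"),
                      ratio = "arcsinh_ratio",
                      combined = c("median_basal", "q90_basal",
                                   "arcsinh_ratio"))
  # combined = basal columns then ratio columns
  stats_order <- c("median_basal", "q90_basal", "arcsinh_ratio")
  out <- list()
  for (st in stats_order[stats_order %in% stats_for]) {
    for (m in meta$kept_metas) {
      ann <- meta$annotations[[as.character(m)]]
      if (is.null(ann)) ann <- "unassigned"
      for (j in seq_along(fun_ch)) {
        out[[length(out) + 1L]] <- data.frame(
          meta_id = m, annotation = ann, channel = fun_ch[j],
          marker = markers[j],
          statistic = st, stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, out)
  d$name <- sprintf("meta%d_%s__%s__%s", d$meta_id,
                    gsub("[^A-Za-z0-9]+", ".", d$annotation), d$marker,
                    d$statistic)
  d
}

#' Build the per-individual feature table
#'
#' One row per individual; columns are (meta-cluster x functional marker x
#' statistic) in a deterministic order: basal medians, then basal 90%
#' quantiles, then arcsinh ratios, each block ordered by meta id then panel
#' marker order. Cells backed by fewer than `min_cells` events per
#' (individual, meta, condition) are treated as missing, imputed with the
#' cohort median of the column, and logged.
#'
#' @param tables list of transformed `event_table` (the cleaned cohort).
#' @param clustering result of [cluster_cohort()] on these tables.
#' @param model `"basal"`, `"ratio"` or `"combined"`.
#' @param min_cells minimum events backing a summary cell (default 10).
#' @return An object of class `feature_table` with `matrix` (imputed),
#'   `missing` (logical mask), `descriptors`, `labels`, `individuals`,
#'   `model`, `imputation_log`.
#' @export
build_feature_table <- function(tables, clustering,
                                model = c("combined", "basal", "ratio"),
                                min_cells = 10L) {
  model <- match.arg(model)
  panel <- tables[[1]]$panel
  fun_ch <- panel_channels(panel, "functional")
  meta <- clustering$meta_model
  origin <- clustering$origin
  ev_meta <- clustering$event_meta

  info <- data.frame(
    individual_id = vapply(tables, `[[`, "", "individual_id"),
    group = vapply(tables, `[[`, "", "group"),
    condition = vapply(tables, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  individuals <- unique(info$individual_id)
  labels <- info$group[match(individuals, info$individual_id)]
  for (id in individuals) {
    has <- info$condition[info$individual_id == id]
    if (!"basal" %in% has)
      stop("individual ", id, " has no basal sample")
    if (model != "basal" && !"stim" %in% has)
      stop("individual ", id, " has no stim sample (required for ",
           model, " model)")
  }

  # per (table, kept meta): median and q90 of each functional channel
  kept <- meta$kept_metas
  summaries <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    rows <- which(origin$table == i)
    em <- ev_meta[rows]
    tab_rows <- origin$row[rows]
    per_meta <- lapply(kept, function(m) {
      idx <- tab_rows[which(em == m)]
      v <- tables[[i]]$values[idx, fun_ch, drop = FALSE]
      list(n = length(idx),
           med = apply(v, 2L, function(x) subset_summary(x, "median")),
           q90 = apply(v, 2L, function(x) subset_summary(x, "q90")))
    })
    names(per_meta) <- as.character(kept)
    summaries[[i]] <- per_meta
  }

  desc <- feature_descriptors(meta, panel, model)
  n_ind <- length(individuals)
  mat <- matrix(NA_real_, n_ind, nrow(desc),
                dimnames = list(individuals, desc$name))
  for (r in seq_len(n_ind)) {
    id <- individuals[r]
    i_basal <- which(info$individual_id == id & info$condition == "basal")
    i_stim <- which(info$individual_id == id & info$condition == "stim")
    for (cidx in seq_len(nrow(desc))) {
      m <- as.character(desc$meta_id[cidx])
      ch <- desc$channel[cidx]
      st <- desc$statistic[cidx]
      if (st %in% c("median_basal", "q90_basal")) {
        s <- summaries[[i_basal]][[m]]
        if (s$n >= min_cells)
          mat[r, cidx] <- if (st == "median_basal") s$med[[ch]] else s$q90[[ch]]
      } else {
        sb <- summaries[[i_basal]][[m]]
        ss <- summaries[[i_stim]][[m]]
        if (sb$n >= min_cells && ss$n >= min_cells)
          mat[r, cidx] <- ss$med[[ch]] - sb$med[[ch]]
      }
    }
  }

  missing <- is.na(mat)
  log <- NULL
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)
    log <- data.frame(individual = individuals[idx[, 1L]],
                      feature = colnames(mat)[idx[, 2L]],
                      reason = sprintf("fewer than %d events", min_cells),
                      stringsAsFactors = FALSE)
    for (j in unique(idx[, 2L])) {
      med <- stats::median(mat[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      mat[missing[, j], j] <- med
    }
  }
  structure(list(matrix = mat, missing = missing, descriptors = desc,
                 labels = labels, individuals = individuals, model = model,
                 min_cells = min_cells,
                 imputation_log = log),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table (%s): %d individuals x %d features, %d imputed cells\n",
    x$model, nrow(x$matrix), ncol(x$matrix), sum(x$missing)))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' @param table a `feature_table`.
#' @param path output path; a JSON descriptor manifest is written next to
#'   it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(individual_id = table$individuals, group = table$labels,
                   table$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table$descriptors, paste0(path, ".json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
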
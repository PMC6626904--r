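#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The p-value is exact (full enumeration of
#' rank arrangements) when `n1 * n2 <= 400` and the data are tie-free;
#' otherwise the normal approximation with tie and continuity correction is
#' used.
#'
#' @param a,b numeric samples (each non-empty).
#' @return list with `U` (number of (a, b) pairs with a > b, ties counting
#'   half) and `p` (two-sided).
#' @export
mwu_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

# per (individual, condition, kept meta): median and 75th percentile of
# each functional channel
condition_summaries <- function(tables, clustering) {
  panel <- tables[[1]]$panel
  fun_ch <- panel_channels(panel, "functional")
  markers <- panel_markers(panel, "functional")
  meta <- clustering$meta_model
  origin <- clustering$origin
  ev_meta <- clustering$event_meta
  rows <- list()
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    sel <- which(origin$table == i)
    em <- ev_meta[sel]
    tab_rows <- origin$row[sel]
    for (m in meta$kept_metas) {
      idx <- tab_rows[which(em == m)]
      if (length(idx) == 0L) next
      v <- t$values[idx, fun_ch, drop = FALSE]
      ann <- meta$annotations[[as.character(m)]]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = t$individual_id, group = t$group,
        condition = t$condition, meta_id = m,
        annotation = if (is.null(ann)) "unassigned" else ann,
        marker = markers, n = length(idx),
        median = apply(v, 2L, stats::median),
        q75 = apply(v, 2L, function(x)
          unname(stats::quantile(x, 0.75, type = 7))),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Group comparisons of meta-cluster summaries
#'
#' For every (meta-cluster, functional marker, condition) the per-individual
#' median and 75th percentile are compared between groups by Mann-Whitney U
#' tests. Raw p-values are reported (sorted ascending); no multiplicity
#' adjustment is applied unless `adjust = TRUE` adds a Benjamini-Hochberg
#' column.
#'
#' @param tables list of transformed `event_table` (cleaned cohort).
#' @param clustering result of [cluster_cohort()].
#' @param adjust add a BH-adjusted column (off by default).
#' @return data.frame with one row per (meta, marker, condition,
#'   statistic): `U`, `p`, and `direction` (`"HD>RA"` or `"RA>HD"` from the
#'   group medians of the summary).
#' @export
compare_groups <- function(tables, clustering, adjust = FALSE) {
  s <- condition_summaries(tables, clustering)
  out <- list()
  for (stat in c("median", "q75")) {
    agg <- s[, c("individual_id", "group", "condition", "meta_id",
                 "annotation", "marker")]
    agg$value <- s[[stat]]
    keys <- unique(agg[, c("meta_id", "annotation", "marker", "condition")])
    for (r in seq_len(nrow(keys))) {
      sub <- agg[agg$meta_id == keys$meta_id[r] &
                   agg$marker == keys$marker[r] &
                   agg$condition == keys$condition[r], ]
      hd <- sub$value[sub$group == "HD"]
      ra <- sub$value[sub$group == "RA"]
      if (length(hd) < 3L || length(ra) < 3L) next
      tst <- mwu_test(hd, ra)
      out[[length(out) + 1L]] <- data.frame(
        meta_id = keys$meta_id[r], annotation = keys$annotation[r],
        marker = keys$marker[r], condition = keys$condition[r],
        statistic = stat, n_hd = length(hd), n_ra = length(ra),
        U = tst$U, p = tst$p,
        direction = if (stats::median(hd) >= stats::median(ra))
          "HD>RA" else "RA>HD",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  if (adjust) res$p_bh <- stats::p.adjust(res$p, method = "BH")
  attr(res, "multiplicity_adjusted") <- adjust
  res
}

#' Per-individual meta-cluster abundances
#'
#' Fractions of each individual's (kept-meta) events per meta-cluster and
#' condition; each row sums to 1. Pooled abundances over the whole cohort
#' are attached as an attribute.
#'
#' @param tables list of `event_table` the clustering was run on.
#' @param clustering result of [cluster_cohort()].
#' @return data.frame: `individual_id`, `group`, `condition`, then one
#'   fraction column per kept meta (named `meta<ID>_<annotation>`), with
#'   attribute `"pooled"` (named numeric vector).
#' @export
abundance_table <- function(tables, clustering) {
  meta <- clustering$meta_model
  origin <- clustering$origin
  ev_meta <- clustering$event_meta
  kept <- meta$kept_metas
  cols <- sprintf("meta%d_%s", kept,
                  gsub("[^A-Za-z0-9]+", ".",
                       vapply(as.character(kept), function(m) {
                         a <- meta$annotations[[m]]
                         if (is.null(a)) "unassigned" else a
                       }, "")))
  rows <- list()
  pooled <- rep(0, length(kept))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    em <- ev_meta[origin$table == i]
    counts <- vapply(kept, function(m) sum(em == m, na.rm = TRUE), 0)
    pooled <- pooled + counts
    frac <- counts / sum(counts)
    df <- data.frame(individual_id = t$individual_id, group = t$group,
                     condition = t$condition, stringsAsFactors = FALSE)
    df[cols] <- as.list(frac)
    rows[[length(rows) + 1L]] <- df
  }
  res <- do.call(rbind, rows)
  attr(res, "pooled") <- stats::setNames(pooled / sum(pooled), cols)
  res
}
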
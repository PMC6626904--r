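#' Farthest point sampling
#'
#' Greedy selection of `k` representative points: the first is chosen
#' uniformly at random under `seed`, and each subsequent point maximizes
#' the minimum Euclidean distance to those already chosen (ties to the
#' lowest index). Runs in O(nk) time with a single running min-distance
#' array, which is what makes it usable on pooled cytometry data where
#' k-means proper would be expensive.
#'
#' @param points numeric n x d matrix.
#' @param k number of representatives; must not exceed the number of
#'   distinct points.
#' @param seed integer seed for the initial pick.
#' @return Integer vector of `k` row indices, in selection order.
#' @export
farthest_point_sampling <- function(points, k, seed = 1L) {
  points <- as.matrix(points)
  set.seed(seed)
  start <- sample.int(nrow(points), 1L)
  fps_cpp(points, as.integer(k), start)
}

#' Nearest-representative event assignment
#'
#' Maps every event to its nearest representative (Euclidean), ties broken
#' toward the lowest representative index. This Voronoi induction is the
#' k-means-approximation reading of farthest point sampling: no Lloyd
#' refinement is applied.
#'
#' @param points n x d matrix of events.
#' @param representatives K x d matrix.
#' @return Integer vector of representative indices (1..K) per event.
#' @export
assign_events <- function(points, representatives) {
  assign_cpp(as.matrix(points), as.matrix(representatives))
}

#' Covering radius of a representative set
#'
#' @param points n x d matrix.
#' @param representatives K x d matrix.
#' @return Maximum over points of the distance to the nearest
#'   representative.
#' @export
covering_radius <- function(points, representatives) {
  max(nearest_dist_cpp(as.matrix(points), as.matrix(representatives)))
}

#' Pool arcsinh phenotyping data across samples
#'
#' @param tables list of transformed `event_table`.
#' @return list with `matrix` (pooled events x 12 phenotyping channels) and
#'   `origin` (data.frame `table`, `row` mapping pooled rows back).
#' @export
pool_phenotyping <- function(tables) {
  stopifnot(length(tables) > 0)
  if (!all(vapply(tables, `[[`, TRUE, "transformed")))
    stop("all tables must be arcsinh-transformed before clustering")
  pheno_ch <- panel_channels(tables[[1]]$panel, "phenotyping")
  mats <- lapply(tables, function(t) t$values[, pheno_ch, drop = FALSE])
  ns <- vapply(mats, nrow, 0L)
  origin <- data.frame(table = rep(seq_along(tables), ns),
                       row = unlist(lapply(ns, seq_len), use.names = FALSE))
  list(matrix = do.call(rbind, mats), origin = origin)
}

#' Cluster pooled events by farthest point sampling
#'
#' Selects `k` representatives by FPS on the pooled phenotyping matrix,
#' assigns every event to its nearest representative, and applies the
#' small-cluster filter.
#'
#' @param points pooled events x d phenotyping matrix (arcsinh scale).
#' @param k number of clusters (the study default is 49).
#' @param seed seed for the FPS start point.
#' @param min_cluster_fraction clusters holding strictly less than this
#'   fraction of all events are discarded (default 1e-5, i.e. 1/100,000).
#' @return An object of class `cluster_model` with `representatives`,
#'   `representative_source_indices`, `assignments`, `cluster_sizes`,
#'   `kept_clusters`, `min_cluster_fraction`, `n_total`.
#' @export
fps_cluster <- function(points, k = 49L, seed = 1L,
                        min_cluster_fraction = 1e-5) {
  points <- as.matrix(points)
  rep_idx <- farthest_point_sampling(points, k, seed = seed)
  reps <- points[rep_idx, , drop = FALSE]
  assignments <- assign_events(points, reps)
  sizes <- tabulate(assignments, nbins = k)
  model <- structure(list(representatives = reps,
                          representative_source_indices = rep_idx,
                          assignments = assignments,
                          cluster_sizes = sizes,
                          kept_clusters = seq_len(k),
                          min_cluster_fraction = min_cluster_fraction,
                          n_total = nrow(points)),
                     class = "cluster_model")
  filter_small_clusters(model, min_cluster_fraction)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "cluster_model: %d events, %d clusters (%d kept, filter %g)\n",
    x$n_total, length(x$cluster_sizes), length(x$kept_clusters),
    x$min_cluster_fraction))
  invisible(x)
}

#' Discard clusters below a size fraction
#'
#' A cluster is discarded, along with its events, when its size is
#' strictly less than `min_fraction` of the total event count; a cluster
#' exactly on the boundary is kept.
#'
#' @param model a `cluster_model`.
#' @param min_fraction size threshold as a fraction of all events.
#' @return The model with `kept_clusters` updated.
#' @export
filter_small_clusters <- function(model, min_fraction = 1e-5) {
  threshold <- min_fraction * model$n_total
  kept <- which(!(model$cluster_sizes < threshold))
  if (length(kept) == 0L)
    stop("all clusters fall below the size filter")
  model$kept_clusters <- kept
  model$min_cluster_fraction <- min_fraction
  model
}

#' Complete-linkage meta-clustering of representatives
#'
#' Agglomerates the kept representatives by complete linkage (Euclidean),
#' cuts the dendrogram at `n_meta` groups, accumulates event counts from
#' member clusters, and discards meta-clusters holding strictly less than
#' `min_meta_fraction` of the total data (the denominator is the original
#' pooled event count, before the small-cluster filter).
#'
#' @param model a `cluster_model`.
#' @param n_meta number of meta-clusters to cut (study default 15).
#' @param min_meta_fraction meta-cluster size filter (default 0.005).
#' @return An object of class `metacluster_model` with `linkage` (hclust),
#'   `meta_assignments` (kept cluster id -> meta id), `meta_sizes`,
#'   `kept_metas`, `abundance`, `annotations` (filled by
#'   [annotate_metaclusters()]).
#' @export
metacluster <- function(model, n_meta = 15L, min_meta_fraction = 0.005) {
  kept <- model$kept_clusters
  if (length(kept) < n_meta)
    stop("fewer kept clusters (", length(kept), ") than n_meta (", n_meta, ")")
  reps <- model$representatives[kept, , drop = FALSE]
  hc <- stats::hclust(stats::dist(reps, method = "euclidean"),
                      method = "complete")
  cut <- stats::cutree(hc, k = n_meta)
  meta_assignments <- stats::setNames(cut, as.character(kept))
  meta_sizes <- vapply(seq_len(n_meta), function(m)
    sum(model$cluster_sizes[kept[cut == m]]), 0)
  frac <- meta_sizes / model$n_total
  kept_metas <- which(!(frac < min_meta_fraction))
  structure(list(linkage = hc, n_meta = as.integer(n_meta),
                 meta_assignments = meta_assignments,
                 meta_sizes = meta_sizes, kept_metas = kept_metas,
                 min_meta_fraction = min_meta_fraction,
                 abundance = frac,
                 n_total = model$n_total,
                 annotations = NULL),
            class = "metacluster_model")
}

#' @export
print.metacluster_model <- function(x, ...) {
  cat(sprintf("metacluster_model: %d meta-clusters (%d kept, filter %g)\n",
              x$n_meta, length(x$kept_metas), x$min_meta_fraction))
  if (!is.null(x$annotations)) {
    ann <- x$annotations[as.character(x$kept_metas)]
    cat("  ", paste(sprintf("%s:%s (%.1f%%)", names(ann), ann,
                            100 * x$abundance[x$kept_metas]),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-event meta-cluster ids
#'
#' @param model a `cluster_model`.
#' @param meta a `metacluster_model` derived from it.
#' @return Integer vector per pooled event: the meta id, or `NA` for events
#'   in discarded clusters or discarded meta-clusters.
#' @export
event_meta_assignments <- function(model, meta) {
  k <- length(model$cluster_sizes)
  map <- rep(NA_integer_, k)
  map[as.integer(names(meta$meta_assignments))] <- meta$meta_assignments
  map[!is.na(map) & !(map %in% meta$kept_metas)] <- NA_integer_
  map[model$assignments]
}

#' Median phenotyping profile per meta-cluster
#'
#' @param model,meta cluster and meta-cluster models.
#' @param points the pooled phenotyping matrix the model was fit on.
#' @return kept-metas x markers matrix of per-meta marker medians.
#' @export
meta_profiles <- function(model, meta, points) {
  ev_meta <- event_meta_assignments(model, meta)
  pheno <- colnames(points)
  prof <- t(vapply(meta$kept_metas, function(m) {
    apply(points[which(ev_meta == m), , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(points))))
  rownames(prof) <- as.character(meta$kept_metas)
  colnames(prof) <- pheno
  prof
}

# rule table applied in fixed priority order; hi/lo is relative to a
# per-marker threshold across the kept meta profiles
annotate_profile <- function(profile, thr, marker_of) {
  hi <- function(m) profile[marker_of(m)] > thr[marker_of(m)]
  lo <- function(m) !hi(m)
  if (hi("CD20") && hi("HLA-DR")) return("Bc")
  if (hi("CD3") && hi("CD4"))
    return(if (hi("CD45RA")) "naive CD4 Tc" else "memory CD4 Tc")
  if (hi("CD3") && hi("CD8a")) return("CD8 Tc")
  if (hi("CD56") && lo("CD3")) return("NKc")
  if (hi("CD14") && hi("CD61")) return("cM")
  if (hi("CD11c") && hi("HLA-DR") && lo("CD14")) return("mDc")
  if (hi("CD123") && hi("HLA-DR") && lo("CD11c")) return("pDc")
  "unassigned"
}

#' Annotate meta-clusters as immune subsets
#'
#' Computes the median phenotyping profile of each kept meta-cluster and
#' applies a fixed-priority rule table (B cells, CD4 T naive/memory, CD8 T,
#' NK, classical monocytes, myeloid and plasmacytoid dendritic cells). A
#' marker counts as "hi" when the meta-profile value exceeds a per-marker
#' threshold across meta-profiles: the midrange (default) or the median of
#' the kept meta-profiles. Profiles matching no rule are `"unassigned"`.
#'
#' @param meta a `metacluster_model`.
#' @param model the `cluster_model` it was derived from.
#' @param points the pooled phenotyping matrix.
#' @param threshold `"midrange"` (default) or `"median"`.
#' @return The `metacluster_model` with `annotations` (named by meta id)
#'   and `profiles` filled in.
#' @export
annotate_metaclusters <- function(meta, model, points,
                                  threshold = c("midrange", "median")) {
  threshold <- match.arg(threshold)
  prof <- meta_profiles(model, meta, points)
  thr <- switch(threshold,
                midrange = (apply(prof, 2L, max) + apply(prof, 2L, min)) / 2,
                median = apply(prof, 2L, stats::median))
  panel <- default_panel()
  ch <- panel$channels[panel$channels$role == "phenotyping", ]
  marker_of <- function(m) ch$channel[match(m, ch$marker)]
  ann <- vapply(seq_len(nrow(prof)), function(i)
    annotate_profile(prof[i, ], thr, marker_of), "")
  meta$annotations <- stats::setNames(ann, rownames(prof))
  meta$profiles <- prof
  meta
}

#' End-to-end clustering of a cohort
#'
#' Pools arcsinh-transformed events over all samples and both conditions
#' (so every meta-cluster exists in both conditions), runs FPS clustering,
#' complete-linkage meta-clustering, both size filters, and subset
#' annotation.
#'
#' @param tables list of transformed `event_table` (all samples, both
#'   conditions).
#' @param k,n_meta,seed,min_cluster_fraction,min_meta_fraction see
#'   [fps_cluster()] and [metacluster()].
#' @param threshold annotation threshold rule, see
#'   [annotate_metaclusters()].
#' @return list with `cluster_model`, `meta_model`, `origin` (pooled-row
#'   provenance) and `event_meta` (per pooled event: kept meta id or `NA`).
#' @export
cluster_cohort <- function(tables, k = 49L, n_meta = 15L, seed = 1L,
                           min_cluster_fraction = 1e-5,
                           min_meta_fraction = 0.005,
                           threshold = "midrange") {
  pooled <- pool_phenotyping(tables)
  model <- fps_cluster(pooled$matrix, k = k, seed = seed,
                       min_cluster_fraction = min_cluster_fraction)
  meta <- metacluster(model, n_meta = n_meta,
                      min_meta_fraction = min_meta_fraction)
  meta <- annotate_metaclusters(meta, model, pooled$matrix,
                                threshold = threshold)
  list(cluster_model = model, meta_model = meta, origin = pooled$origin,
       event_meta = event_meta_assignments(model, meta))
}
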
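# Shared cohort fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small end-to-end cohort: simulate -> clean -> transform -> cluster.
# `effect_scale = 0` gives a null cohort.
build_small_cohort <- function(n_per_group = 6, events = 800, effect_scale = 1,
                               seed = 7, response_scale = 0.25 * effect_scale) {
  cfg <- default_paper_scenario(effect_scale = effect_scale,
                                response_scale = response_scale,
                                n_hd = n_per_group, n_ra = n_per_group,
                                events_per_sample = events, seed = seed)
  sim <- simulate_cohort(cfg)
  cl <- clean_cohort(sim$tables, seed = seed)
  tr <- lapply(cl$tables, arcsinh_transform)
  clustering <- cluster_cohort(tr, seed = seed)
  list(config = cfg, sim = sim, cleaned = cl, transformed = tr,
       clustering = clustering)
}

small_cohort <- function() {
  cached("small_signal", function() build_small_cohort())
}

small_null_cohort <- function() {
  cached("small_null", function() build_small_cohort(effect_scale = 0))
}

small_feature_table <- function(model = "combined") {
  cached(paste0("features_", model), function() {
    co <- small_cohort()
    build_feature_table(co$transformed, co$clustering, model = model)
  })
}

# Map cleaned, pooled clustering rows back to ground-truth labels.
pooled_truth <- function(co) {
  origin <- co$clustering$origin
  truth <- character(nrow(origin))
  debris <- logical(nrow(origin))
  for (i in unique(origin$table)) {
    sel <- origin$table == i
    orig_rows <- co$cleaned$kept_index[[i]][origin$row[sel]]
    truth[sel] <- co$sim$truth$labels[[i]]$subset[orig_rows]
    debris[sel] <- co$sim$truth$labels[[i]]$debris[orig_rows]
  }
  list(subset = truth, debris = debris)
}

# RA-minus-HD difference of per-individual basal medians (arcsinh scale)
# of one channel within one true subset, straight from simulation truth.
group_marker_diff <- function(sim, subset, channel) {
  vals <- vapply(seq_along(sim$tables), function(i) {
    t <- sim$tables[[i]]
    if (t$condition != "basal") return(NA_real_)
    l <- sim$truth$labels[[i]]
    sel <- !l$debris & l$subset == subset
    stats::median(asinh(t$values[sel, channel] / 5))
  }, 0)
  grp <- vapply(sim$tables, `[[`, "", "group")
  mean(vals[grp == "RA"], na.rm = TRUE) - mean(vals[grp == "HD"], na.rm = TRUE)
}

# A hand-built clustering over fabricated tables, with exactly n_meta metas.
fabricate_clustering <- function(n_meta = 12, n_ind = 3, per_table = 20 * 12) {
  p <- default_panel()
  ch <- panel_channels(p)
  tabs <- list()
  info <- expand.grid(ind = sprintf("HD%02d", 1:n_ind),
                      cond = c("basal", "stim"), stringsAsFactors = FALSE)
  set.seed(1)
  for (i in seq_len(nrow(info))) {
    m <- matrix(abs(rnorm(per_table * 28, 3)), per_table, 28,
                dimnames = list(NULL, ch))
    tabs[[i]] <- event_table(m, p, info$ind[i], "HD", info$cond[i],
                             transformed = TRUE)
  }
  origin <- data.frame(table = rep(seq_along(tabs), each = per_table),
                       row = rep(seq_len(per_table), length(tabs)))
  ev_meta <- rep(rep(seq_len(n_meta), length.out = per_table), length(tabs))
  meta <- list(kept_metas = seq_len(n_meta),
               annotations = stats::setNames(
                 rep("unassigned", n_meta), seq_len(n_meta)))
  list(tables = tabs,
       clustering = list(meta_model = meta, origin = origin,
                         event_meta = ev_meta))
}

# A feature_table wrapped around a plain numeric matrix (rownames =
# individual ids), for classifier tests that need full control of X.
wrap_feature_table <- function(X, labels) {
  desc <- data.frame(meta_id = seq_len(ncol(X)), annotation = "unassigned",
                     channel = "156Gd_p-p38", marker = "p-p38",
                     statistic = "median_basal",
                     name = colnames(X), stringsAsFactors = FALSE)
  structure(list(matrix = X, missing = matrix(FALSE, nrow(X), ncol(X)),
                 descriptors = desc, labels = labels,
                 individuals = rownames(X), model = "basal",
                 min_cells = 10L, imputation_log = NULL),
            class = "feature_table")
}

# Permute individual-level group labels on transformed tables (for null
# calibration experiments).
permute_groups <- function(tables, seed) {
  ids <- vapply(tables, `[[`, "", "individual_id")
  inds <- unique(ids)
  grp <- vapply(inds, function(id) tables[[match(id, ids)]]$group, "")
  set.seed(seed)
  newg <- stats::setNames(sample(grp), inds)
  lapply(tables, function(t) { t$group <- newg[[t$individual_id]]; t })
}
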
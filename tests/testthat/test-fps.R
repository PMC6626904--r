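test_that("fps matches the brute-force greedy oracle index-for-index", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    X <- matrix(rnorm(120 * 4), 120, 4)
    got <- farthest_point_sampling(X, 15, seed = seed)
    expect_identical(got, as.integer(oracle_fps(X, 15, fps_start(120, seed))))
  }
})

test_that("fps geometry on a line picks the extremes", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  # force start at index 1 by trying seeds until sample.int gives 1
  seed <- which(vapply(1:50, function(s) fps_start(3, s) == 1L, TRUE))[1]
  got <- farthest_point_sampling(X, 2, seed = seed)
  expect_identical(got, c(1L, 3L))
})

test_that("fps distance ties resolve to the lowest index", {
  # two points equidistant from the start
  X <- matrix(c(0, -1, 1), ncol = 1)
  seed <- which(vapply(1:50, function(s) fps_start(3, s) == 1L, TRUE))[1]
  got <- farthest_point_sampling(X, 2, seed = seed)
  expect_identical(got[2], 2L)
})

test_that("fps refuses k beyond the number of distinct points", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_error(farthest_point_sampling(X, 3, seed = 1), "distinct")
})

test_that("event assignment is nearest-representative, ties to lowest", {
  X <- matrix(c(0, 0.4, 1), ncol = 1)
  reps <- matrix(c(0, 1), ncol = 1)
  expect_identical(assign_events(X, reps), c(1L, 1L, 2L))
  mid <- matrix(0.5, ncol = 1)
  expect_identical(assign_events(mid, reps), 1L)
})

test_that("fps covering radius is within twice the k-center optimum", {
  for (seed in 1:4) {
    set.seed(200 + seed)
    X <- matrix(rnorm(10 * 2), 10, 2)
    r_fps <- covering_radius(X, X[farthest_point_sampling(X, 3, seed = seed),
                                  , drop = FALSE])
    expect_lte(r_fps, 2 * oracle_kcenter_opt(X, 3) + 1e-12)
  }
})

test_that("complete-linkage agrees with a naive agglomeration oracle", {
  for (seed in 1:5) {
    set.seed(300 + seed)
    n <- sample(5:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    hc <- stats::hclust(stats::dist(X), method = "complete")
    oracle <- oracle_complete_linkage(X)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    for (k in 2:(n - 1))
      expect_true(same_partition(stats::cutree(hc, k),
                                 oracle$partitions[[k]]))
  }
})

test_that("small-cluster filter discards strictly below 1/100000", {
  sizes <- c(9L, 10L, 11L, as.integer(1e6 - 30))
  model <- structure(list(representatives = matrix(rnorm(8), 4, 2),
                          cluster_sizes = sizes,
                          kept_clusters = 1:4,
                          assignments = integer(0),
                          n_total = 1e6),
                     class = "cluster_model")
  out <- filter_small_clusters(model, 1e-5)
  expect_identical(out$kept_clusters, 2:4)  # 9 out, 10 exactly on boundary in
})

test_that("meta-cluster filter discards strictly below 0.5%", {
  # 15 well-separated representatives: each becomes its own meta-cluster
  reps <- cbind(seq(0, 140, by = 10), 0)
  sizes <- rep((1e6 - 9000) / 13, 15)
  sizes[1] <- 4000  # 0.4% -> discarded
  sizes[2] <- 5000  # 0.5% -> exactly on boundary, kept
  model <- structure(list(representatives = reps,
                          cluster_sizes = sizes,
                          kept_clusters = 1:15,
                          assignments = integer(0),
                          n_total = 1e6),
                     class = "cluster_model")
  meta <- metacluster(model, n_meta = 15, min_meta_fraction = 0.005)
  m1 <- unname(meta$meta_assignments["1"])
  m2 <- unname(meta$meta_assignments["2"])
  expect_false(m1 %in% meta$kept_metas)
  expect_true(m2 %in% meta$kept_metas)
})

test_that("metacluster requires enough kept clusters", {
  model <- structure(list(representatives = matrix(rnorm(10), 5, 2),
                          cluster_sizes = rep(100L, 5),
                          kept_clusters = 1:5, assignments = integer(0),
                          n_total = 500),
                     class = "cluster_model")
  expect_error(metacluster(model, n_meta = 15), "fewer kept clusters")
})

test_that("annotation rules map canonical profiles to the study subsets", {
  panel <- default_panel()
  ch <- panel$channels[panel$channels$role == "phenotyping", ]
  marker_of <- function(m) ch$channel[match(m, ch$marker)]
  base <- stats::setNames(rep(0.5, nrow(ch)), ch$channel)
  thr <- stats::setNames(rep(2, nrow(ch)), ch$channel)
  mk <- function(...) {
    p <- base
    p[vapply(c(...), marker_of, "")] <- 4
    p
  }
  ann <- function(p) cytofps:::annotate_profile(p, thr, marker_of)
  expect_equal(ann(mk("CD20", "HLA-DR")), "Bc")
  expect_equal(ann(mk("CD3", "CD4", "CD45RA")), "naive CD4 Tc")
  expect_equal(ann(mk("CD3", "CD4")), "memory CD4 Tc")
  expect_equal(ann(mk("CD3", "CD8a")), "CD8 Tc")
  expect_equal(ann(mk("CD56")), "NKc")
  expect_equal(ann(mk("CD14", "CD61")), "cM")
  expect_equal(ann(mk("CD11c", "HLA-DR")), "mDc")
  expect_equal(ann(mk("CD123", "HLA-DR")), "pDc")
  expect_equal(ann(base), "unassigned")
  # priority: B-cell rule fires before the dendritic rules
  expect_equal(ann(mk("CD20", "HLA-DR", "CD11c")), "Bc")
})

test_that("event meta ids are NA for events of discarded clusters", {
  set.seed(31)
  X <- rbind(matrix(rnorm(300 * 2, 0), ncol = 2),
             matrix(rnorm(300 * 2, 8), ncol = 2),
             matrix(rnorm(2 * 2, 20), ncol = 2))  # 2-event outlier cluster
  model <- fps_cluster(X, k = 3, seed = 1, min_cluster_fraction = 0.01)
  expect_lt(length(model$kept_clusters), 3)
  meta <- metacluster(model, n_meta = 2, min_meta_fraction = 0)
  ev <- event_meta_assignments(model, meta)
  expect_equal(length(ev), nrow(X))
  discarded <- setdiff(1:3, model$kept_clusters)
  expect_true(all(is.na(ev[model$assignments %in% discarded])))
  expect_true(all(!is.na(ev[model$assignments %in% model$kept_clusters])))
})

test_that("cohort clustering recovers the planted subsets (ARI)", {
  co <- small_cohort()
  tru <- pooled_truth(co)
  ev <- co$clustering$event_meta
  ann <- co$clustering$meta_model$annotations
  keep <- !is.na(ev) & !tru$debris
  called <- unname(ann[as.character(ev[keep])])
  expect_gt(adjusted_rand_index(tru$subset[keep], called), 0.8)
  # and the mclust reference implementation agrees with our ARI helper
  expect_equal(adjusted_rand_index(tru$subset[keep], called),
               mclust::adjustedRandIndex(tru$subset[keep], called),
               tolerance = 1e-12)
})
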
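test_that("summary statistics follow the type-7 quantile convention", {
  expect_equal(subset_summary(1:10, "q90"), 9.1)
  expect_equal(subset_summary(c(3, 1, 2), "median"), 2)
  expect_equal(subset_summary(1:10, "q90"),
               unname(stats::quantile(1:10, 0.9, type = 7)))
  expect_true(is.na(subset_summary(numeric(0), "median")))
  expect_true(is.na(subset_summary(numeric(0), "q90")))
})

test_that("arcsinh ratio is the difference of medians and antisymmetric", {
  a <- c(1, 2, 3); b <- c(0.5, 1.5, 4)
  expect_equal(arcsinh_ratio(a, b), median(a) - median(b))
  expect_equal(arcsinh_ratio(a, b), -arcsinh_ratio(b, a))
  expect_true(is.na(arcsinh_ratio(numeric(0), b)))
  expect_true(is.na(arcsinh_ratio(a, numeric(0))))
})

test_that("12 kept metas give 216/108/324 feature columns in fixed order", {
  fx <- fabricate_clustering()
  fb <- build_feature_table(fx$tables, fx$clustering, model = "basal")
  fr <- build_feature_table(fx$tables, fx$clustering, model = "ratio")
  fc <- build_feature_table(fx$tables, fx$clustering, model = "combined")
  expect_equal(ncol(fb$matrix), 216L)
  expect_equal(ncol(fr$matrix), 108L)
  expect_equal(ncol(fc$matrix), 324L)

  d <- fc$descriptors
  # statistic blocks in order, each meta-major then panel marker order
  expect_equal(unique(d$statistic),
               c("median_basal", "q90_basal", "arcsinh_ratio"))
  first_block <- d[d$statistic == "median_basal", ]
  expect_equal(first_block$meta_id, rep(1:12, each = 9))
  expect_equal(first_block$marker[1:9],
               panel_markers(default_panel(), "functional"))
  # combined = basal columns then ratio columns
  expect_identical(colnames(fc$matrix),
                   c(colnames(fb$matrix), colnames(fr$matrix)))
})

test_that("basal feature values equal direct summaries of the events", {
  fx <- fabricate_clustering()
  ft <- build_feature_table(fx$tables, fx$clustering, model = "combined")
  t1 <- fx$tables[[1]]  # HD01 basal
  idx <- fx$clustering$origin$row[
    fx$clustering$origin$table == 1 &
      fx$clustering$event_meta == 1]
  v <- t1$values[idx, "156Gd_p-p38"]
  expect_equal(unname(ft$matrix["HD01", "meta1_unassigned__p-p38__median_basal"]),
               median(v))
  expect_equal(unname(ft$matrix["HD01", "meta1_unassigned__p-p38__q90_basal"]),
               unname(quantile(v, 0.9, type = 7)))
})

test_that("sparse cells are masked, imputed with cohort medians and logged", {
  fx <- fabricate_clustering()
  # knock meta 1 out of HD01's basal table: reassign its events to meta 2
  em <- fx$clustering$event_meta
  sel <- fx$clustering$origin$table == 1 & em == 1
  em[sel] <- 2L
  fx$clustering$event_meta <- em
  ft <- build_feature_table(fx$tables, fx$clustering, model = "combined",
                            min_cells = 10)
  miss_cols <- grepl("^meta1_", colnames(ft$matrix)) &
    grepl("basal$", colnames(ft$matrix))
  expect_true(all(ft$missing["HD01", miss_cols]))
  expect_true(all(!ft$missing["HD02", miss_cols]))
  # imputed with the median over the other individuals
  j <- which(miss_cols)[1]
  others <- setdiff(rownames(ft$matrix), "HD01")
  expect_equal(unname(ft$matrix["HD01", j]),
               median(ft$matrix[others, j]))
  expect_true(any(ft$imputation_log$individual == "HD01"))
  # ratio features of meta 1 for HD01 are missing too (basal side empty)
  ratio_cols <- grepl("^meta1_", colnames(ft$matrix)) &
    grepl("arcsinh_ratio$", colnames(ft$matrix))
  expect_true(all(ft$missing["HD01", ratio_cols]))
})

test_that("missing conditions are rejected per model contract", {
  fx <- fabricate_clustering()
  basal_only <- which(vapply(fx$tables, `[[`, "", "condition") == "basal")
  tabs <- fx$tables[basal_only]
  cl <- fx$clustering
  keep <- cl$origin$table %in% basal_only
  cl$origin <- data.frame(table = match(cl$origin$table[keep], basal_only),
                          row = cl$origin$row[keep])
  cl$event_meta <- cl$event_meta[keep]
  expect_error(build_feature_table(tabs, cl, model = "combined"), "stim")
  expect_silent({ft <- build_feature_table(tabs, cl, model = "basal")})
  expect_equal(ncol(ft$matrix), 216L)
})

test_that("a planted basal shift appears in the features at its size", {
  co <- small_cohort()  # effect scale 1
  ft <- small_feature_table("combined")
  ann <- co$clustering$meta_model$annotations
  mem <- names(ann)[ann == "memory CD4 Tc"]
  cols <- paste0("meta", mem, "_memory.CD4.Tc__p-p38__median_basal")
  cols <- cols[cols %in% colnames(ft$matrix)]
  expect_gt(length(cols), 0)
  ra <- ft$labels == "RA"
  diffs <- vapply(cols, function(cn)
    mean(ft$matrix[ra, cn]) - mean(ft$matrix[!ra, cn]), 0)
  expect_equal(unname(mean(diffs)), 1, tolerance = 0.35)
})
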
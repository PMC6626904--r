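test_that("default panel has the 28 study channels with their roles", {
  p <- default_panel()
  expect_s3_class(p, "panel_definition")
  expect_equal(nrow(p$channels), 28L)
  expect_equal(sum(p$channels$role == "qc"), 7L)
  expect_equal(sum(p$channels$role == "phenotyping"), 12L)
  expect_equal(sum(p$channels$role == "functional"), 9L)
  expect_equal(p$cofactor, 5)
  expect_true("156Gd_p-p38" %in% p$channels$channel)
  expect_false(any(grepl("CD45$", p$channels$channel)))  # CD45 excluded
})

test_that("event tables align columns by name and reject missing channels", {
  p <- default_panel()
  ch <- panel_channels(p)
  m <- matrix(abs(rnorm(5 * 28)), 5, 28, dimnames = list(NULL, rev(ch)))
  t <- event_table(m, p, "HD01", "HD", "basal")
  expect_equal(colnames(t$values), ch)
  expect_equal(t$values[, "156Gd_p-p38"], m[, "156Gd_p-p38"])

  m2 <- m[, -1, drop = FALSE]
  expect_error(event_table(m2, p, "HD01", "HD", "basal"), "MissingChannel")
  m3 <- m; m3[1, 1] <- -1
  expect_error(event_table(m3, p, "HD01", "HD", "basal"), "non-negative")
})

test_that("arcsinh transform hits markers only, inverts, and cannot stack", {
  p <- default_panel()
  ch <- panel_channels(p)
  set.seed(1)
  m <- matrix(abs(rnorm(50 * 28, 10, 3)), 50, 28, dimnames = list(NULL, ch))
  t <- event_table(m, p, "HD01", "HD", "basal")
  tt <- arcsinh_transform(t)

  # value 5 with cofactor 5 -> asinh(1)
  m2 <- m; m2[, "156Gd_p-p38"] <- 5
  t2 <- arcsinh_transform(event_table(m2, p, "HD01", "HD", "basal"))
  expect_equal(unname(t2$values[1, "156Gd_p-p38"]), asinh(1))
  expect_equal(asinh(1), 0.8813736, tolerance = 1e-7)

  # qc channels untouched
  qc <- panel_channels(p, "qc")
  expect_identical(tt$values[, qc], t$values[, qc])

  expect_error(arcsinh_transform(tt), "already")
  back <- arcsinh_invert(tt)
  expect_equal(back$values, t$values, tolerance = 1e-9)
  expect_error(arcsinh_invert(t), "not transformed")
})

test_that("FCS 3.1 files round-trip values and channel names", {
  set.seed(2)
  vals <- matrix(abs(rnorm(200 * 28, 100, 40)), 200, 28,
                 dimnames = list(NULL, panel_channels(default_panel())))
  f <- tempfile(fileext = ".fcs")
  write_fcs(vals, f)
  got <- read_fcs(f)
  expect_equal(colnames(got$values), colnames(vals))
  # float32 storage: relative error bounded by single precision
  expect_equal(got$values, vals, tolerance = 1e-4)
  expect_true(looks_like_fcs(f))
  unlink(f)
})

test_that("read_events resolves FCS and TSV with aliases and validation", {
  p <- default_panel()
  ch <- panel_channels(p)
  set.seed(3)
  vals <- matrix(abs(rnorm(60 * 28, 50, 10)), 60, 28,
                 dimnames = list(NULL, ch))
  meta <- list(individual_id = "RA03", group = "RA", condition = "stim")

  f1 <- tempfile(fileext = ".fcs")
  t0 <- event_table(vals, p, meta$individual_id, meta$group, meta$condition)
  write_events(t0, f1)
  t1 <- read_events(f1, p, meta)
  expect_equal(t1$values, t0$values, tolerance = 1e-4)
  expect_equal(t1$individual_id, "RA03")

  f2 <- tempfile(fileext = ".tsv")
  write_events(t0, f2)
  t2 <- read_events(f2, p, meta)
  expect_equal(t2$values, t0$values, tolerance = 1e-6)

  # alias mapping: rename one channel in the file, map it back
  vals3 <- vals
  colnames(vals3)[colnames(vals3) == "156Gd_p-p38"] <- "p-p38"
  f3 <- tempfile(fileext = ".tsv")
  utils::write.table(vals3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  t3 <- read_events(f3, p, meta, aliases = c("p-p38" = "156Gd_p-p38"))
  expect_equal(t3$values[, "156Gd_p-p38"], unname(vals[, "156Gd_p-p38"]),
               tolerance = 1e-6)

  expect_error(read_events(tempfile(), p, meta), "no such file")
  unlink(c(f1, f2, f3))
})

test_that("transformed tables are refused by write_events", {
  p <- default_panel()
  vals <- matrix(abs(rnorm(10 * 28)), 10, 28,
                 dimnames = list(NULL, panel_channels(p)))
  t <- arcsinh_transform(event_table(vals, p, "HD01", "HD", "basal"))
  expect_error(write_events(t, tempfile(fileext = ".fcs")), "raw")
})

test_that("cohort manifests validate groups, conditions and pairing", {
  rec <- expand.grid(individual_id = c("HD01", "RA01"),
                     condition = c("basal", "stim"),
                     stringsAsFactors = FALSE)
  rec$group <- ifelse(grepl("HD", rec$individual_id), "HD", "RA")
  rec$path <- paste0(rec$individual_id, "_", rec$condition, ".fcs")
  man <- cohort_manifest(rec)
  expect_s3_class(man, "cohort_manifest")
  expect_silent(check_paired(man))

  bad <- rec; bad$group[1] <- "XX"
  expect_error(cohort_manifest(bad))
  unpaired <- rec[-1, ]
  expect_error(check_paired(cohort_manifest(unpaired)),
               "missing a condition")
})
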
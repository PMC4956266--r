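test_that("tables round-trip through TSV at full precision", {
  tab <- tiny_table()
  md <- tiny_metadata()
  dir <- withr::local_tempdir()
  write_metabolite_table(tab, file.path(dir, "t.tsv"),
                         annotations_path = file.path(dir, "f.tsv"),
                         metadata = md, metadata_path = file.path(dir, "m.tsv"))
  back <- read_metabolite_table(file.path(dir, "t.tsv"), file.path(dir, "m.tsv"),
                                annotations_path = file.path(dir, "f.tsv"))
  expect_identical(back$table$values, tab$values)
  expect_identical(back$table$sample_ids, tab$sample_ids)
  expect_identical(back$table$features$name, tab$features$name)
  expect_identical(back$table$features$identified, tab$features$identified)
  expect_identical(back$metadata$group, md$group)

  # irrational values survive the round trip too
  tab2 <- metabolite_table(matrix(c(pi, exp(1), sqrt(2), 1/3), 2, 2),
                           c("A", "B"), tab$features[1:2, ])
  write_metabolite_table(tab2, file.path(dir, "t2.tsv"))
  back2 <- read_metabolite_table(file.path(dir, "t2.tsv"), file.path(dir, "m2.tsv")) |>
    tryCatch(error = function(e) NULL)
  expect_null(back2)  # metadata file absent -> error
  write.table(data.frame(sample_id = c("A", "B"), group = "HV"),
              file.path(dir, "m2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back2 <- read_metabolite_table(file.path(dir, "t2.tsv"), file.path(dir, "m2.tsv"))
  expect_identical(back2$table$values, tab2$values)
})

test_that("readers reject orphans, non-numeric cells and bad labels by name", {
  tab <- tiny_table()
  dir <- withr::local_tempdir()
  write_metabolite_table(tab, file.path(dir, "t.tsv"))
  write.table(data.frame(sample_id = c("S1", "S2"), group = c("SLE_G1", "HV")),
              file.path(dir, "m.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metabolite_table(file.path(dir, "t.tsv"), file.path(dir, "m.tsv")),
               "S3")

  lines <- readLines(file.path(dir, "t.tsv"))
  lines[2] <- sub("\t1.0\t", "\tNA\t", lines[2], fixed = TRUE)
  writeLines(lines, file.path(dir, "bad.tsv"))
  write.table(tiny_metadata(), file.path(dir, "m3.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_metabolite_table(file.path(dir, "bad.tsv"),
                                     file.path(dir, "m3.tsv")),
               "non-numeric cell 'NA'")

  md_bad <- tiny_metadata(); md_bad$group[1] <- "lupus"
  write.table(md_bad, file.path(dir, "m4.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_metabolite_table(file.path(dir, "t.tsv"),
                                     file.path(dir, "m4.tsv")),
               "unknown group label")
})

test_that("constructor enforces the table invariants", {
  tab <- tiny_table()
  expect_error(metabolite_table(tab$values, c("S1", "S1", "S3"), tab$features),
               "duplicate sample id")
  f2 <- tab$features; f2$name[2] <- "tryptophan"
  expect_error(metabolite_table(tab$values, tab$sample_ids, f2),
               "duplicate feature name")
  v2 <- tab$values; v2[1, 1] <- -1
  expect_error(metabolite_table(v2, tab$sample_ids, tab$features), "negative")
  v2[1, 1] <- NA
  expect_error(metabolite_table(v2, tab$sample_ids, tab$features), "missing")
  f3 <- tab$features; f3$identified[4] <- TRUE  # IS flagged identified
  expect_error(metabolite_table(tab$values, tab$sample_ids, f3),
               "internal standards")
})

test_that("subgroup pooling maps the seven labels, preserves counts, idempotent", {
  md <- data.frame(
    sample_id = sprintf("S%02d", 1:87),
    group = rep(c("SLE_G1", "SLE_G2", "SLE_G3", "pSS", "SSc_lc", "SSc_dc", "HV"),
                c(10, 10, 10, 20, 9, 10, 18)),
    stringsAsFactors = FALSE)
  pooled <- pool_sle_subgroups(md)
  expect_equal(nrow(pooled), 87)
  expect_equal(sum(pooled$pooled_group == "SLE"), 30)
  expect_equal(sum(pooled$pooled_group == "SSc"), 19)
  expect_equal(sum(pooled$pooled_group == "pSS"), 20)
  expect_equal(sum(pooled$pooled_group == "HV"), 18)
  expect_identical(pooled$group, md$group)  # original labels preserved
  expect_identical(pool_sle_subgroups(pooled), pooled)  # idempotent
  empty <- md[0, ]
  expect_equal(nrow(pool_sle_subgroups(empty)), 0)
})

test_that("feature filtering keeps the identified analyte set", {
  coh <- generate_cohort(generator_config(seed = 7))
  expect_equal(dim(coh$table), c(87L, 254L))
  kept <- filter_features(coh$table, TRUE, TRUE)
  expect_equal(ncol(kept$values), 73)
  expect_true(all(kept$features$identified))
  # filtering is a positional subset
  expect_identical(kept$values,
                   coh$table$values[, coh$table$features$identified])
  none <- filter_features(coh$table, FALSE, FALSE)
  expect_identical(none$values, coh$table$values)
  only_is <- metabolite_table(
    coh$table$values[, coh$table$features$is_internal_standard],
    coh$table$sample_ids,
    coh$table$features[coh$table$features$is_internal_standard, ])
  expect_error(filter_features(only_is, TRUE, FALSE), "removed all features")
})

test_that("analysis config validates and loads from YAML and JSON", {
  cfg <- analysis_config()
  expect_s3_class(cfg, "analysis_config")
  expect_equal(cfg$cv_folds, 7L)
  expect_equal(cfg$ri_window, 10)
  expect_error(analysis_config(alpha = 1.2), "alpha")
  dir <- withr::local_tempdir()
  writeLines(c("alpha: 0.01", "cv_folds: 5", "feature_set: all"),
             file.path(dir, "cfg.yaml"))
  cfg2 <- read_analysis_config(file.path(dir, "cfg.yaml"))
  expect_equal(cfg2$alpha, 0.01)
  expect_equal(cfg2$cv_folds, 5L)
  expect_equal(cfg2$feature_set, "all")
  jsonlite::write_json(list(alpha = 0.1), file.path(dir, "cfg.json"),
                       auto_unbox = TRUE)
  expect_equal(read_analysis_config(file.path(dir, "cfg.json"))$alpha, 0.1)
})
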
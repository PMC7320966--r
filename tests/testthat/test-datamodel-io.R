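test_that("feature tables carry and validate a missingness mask", {
  v <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  ft <- feature_table(v)
  expect_equal(sum(ft$missing_mask), 1L)
  expect_true(ft$missing_mask["c", "f1"])
  expect_identical(subject_ids(ft), c("a", "b", "c"))
  expect_identical(feature_ids(ft), c("f1", "f2"))

  dup <- v
  rownames(dup) <- c("a", "a", "c")
  expect_error(feature_table(dup), "duplicate subject id.*a")
  expect_error(feature_table(unname(v)), "row names")
})

test_that("feature-table files round-trip values and mask losslessly", {
  set.seed(41)
  v <- matrix(rnorm(60) * exp(rnorm(60, 0, 3)), nrow = 10,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("f%d", 1:6)))
  v[sample(60, 7)] <- NA
  ft <- feature_table(v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(back$values, ft$values)
  expect_identical(back$missing_mask, ft$missing_mask)
})

test_that("malformed feature-table files are rejected with named cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,f1,f2", "s1,1,2", "s2,3,oops"), path)
  expect_error(read_feature_table(path), "oops.*s2.*f2")

  writeLines(c("subject_id,f1,f1", "s1,1,2"), path)
  expect_error(read_feature_table(path), "duplicate feature id.*f1")

  writeLines(c("subject_id,f1,f2", "s1,1,2", "s2,3"), path)
  expect_error(read_feature_table(path), "ragged")

  writeLines(c("subject_id,f1,f2", "s1,1,", "s2,3,4"), path)
  ft <- read_feature_table(path)
  expect_true(ft$missing_mask["s1", "f2"])
})

test_that("category maps enforce the single assigned diagnosis and coverage", {
  fc <- feature_categories(
    c("CAPS", "PCL", "BDI", "BAI", "CGI", "vol1", "cog1"),
    c("assigned_diagnosis", rep("clinical", 4), "biomarker", "biomarker"),
    c(NA, NA, NA, NA, NA, "structural", "cognitive"))
  expect_s3_class(fc, "feature_categories")
  expect_identical(sum(fc$category == "assigned_diagnosis"), 1L)

  expect_error(
    feature_categories(c("a", "b"), c("assigned_diagnosis", "assigned_diagnosis")),
    "exactly one")
  expect_error(feature_categories("a", "clinical"), "exactly one")
  expect_error(feature_categories(c("a", "b"), c("assigned_diagnosis", "biomarker")),
               "domain")

  v <- matrix(1:6, 2, dimnames = list(c("s1", "s2"), c("CAPS", "PCL", "extra")))
  fc2 <- feature_categories(c("CAPS", "PCL"),
                            c("assigned_diagnosis", "clinical"))
  expect_error(align_categories(fc2, feature_table(v)), "extra")
})

test_that("category maps round-trip through YAML", {
  fc <- feature_categories(
    c("CAPS", "PCL", "vol1"),
    c("assigned_diagnosis", "clinical", "biomarker"),
    c(NA, NA, "structural"))
  path <- withr::local_tempfile(fileext = ".yml")
  write_category_map(fc, path)
  back <- read_category_map(path)
  expect_identical(as.data.frame(back), as.data.frame(fc))
})

test_that("diagnosis labels must be binary and aligned", {
  expect_error(diagnosis_labels(c(a = 1, b = 2)), "binary")
  lab <- diagnosis_labels(c(a = 1, b = 0))
  expect_identical(unclass(lab), c(a = 1L, b = 0L))
})

test_that("run reports serialize numeric fields losslessly", {
  stab <- data.frame(fraction = seq(0.2, 0.9, 0.1),
                     mean_pct = c(83, 86, 86, 88, 89, 90, 90, 95) + pi * 1e-7,
                     sd_pct = c(10, 7, 10, 9, 7, 7, 6, 7))
  rep1 <- run_report(seed = 5, config = list(q_screen = 0.2),
                     stability = stab,
                     association = list(two_proportion = list(z = 4.5728915113)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.json")
  write_report(rep1, path)
  expect_true(file.exists(paste0(path, ".txt")))
  back <- read_report(path)
  expect_identical(back$provenance$seed, rep1$provenance$seed)
  expect_identical(back$provenance$config_hash, rep1$provenance$config_hash)
  expect_equal(as.data.frame(back$stability), stab)
  expect_identical(back$association$two_proportion$z,
                   rep1$association$two_proportion$z)
  expect_length(back$stability$mean_pct, 8L)
})
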
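test_that("cohort CSV round-trips exactly", {
  co <- make_toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(length(readLines(path)), nrow(co) + 1L)

  back <- read_cohort(path, label = "toy")
  expect_equal(as.data.frame(back), as.data.frame(co))

  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty cohort -> header-only file
  empty <- as_cohort(as.data.frame(co)[0, ])
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, path3)
  expect_equal(length(readLines(path3)), 1L)
})

test_that("validation rejects bad records with row-level messages", {
  df <- as.data.frame(make_toy_cohort())

  bad <- df; bad$silva[2] <- "D"
  expect_error(as_cohort(bad), "row 2.*P2.*silva")

  bad <- df; bad$patient_id[3] <- "P1"
  expect_error(as_cohort(bad), "duplicate patient_id")

  bad <- df; bad$dsi_fraction[1] <- 1.4
  expect_error(as_cohort(bad), "dsi_fraction")

  bad <- df; bad$os_months[4] <- 5  # rfs 10 > os 5
  expect_error(as_cohort(bad), "rfs_months")

  bad <- df; bad$lvsi[1] <- "mild"  # silva A with LVSI
  expect_error(as_cohort(bad), "pattern A")

  bad <- df; bad$rfs_months[5] <- 0
  expect_error(as_cohort(bad), "positive")

  # missing modeled field is rejected, not imputed
  bad <- df; bad$tumor_size_cm[2] <- NA
  expect_error(as_cohort(bad), "row 2.*tumor_size_cm")
})

test_that("read_cohort reports schema and cell errors", {
  co <- make_toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)

  # missing column named in the error
  lines <- readLines(path)
  crippled <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("\\btumor_size_cm\\b", "ts", lines), crippled)
  expect_error(read_cohort(crippled), "tumor_size_cm")
  # ... but resolvable through a schema map
  remapped <- read_cohort(crippled, schema = c(tumor_size_cm = "ts"))
  expect_equal(remapped$tumor_size_cm, co$tumor_size_cm)

  # unparseable cell names patient and field
  broken <- withr::local_tempfile(fileext = ".csv")
  lines2 <- readLines(path)
  lines2[3] <- sub("2.5", "two-ish", lines2[3], fixed = TRUE)
  writeLines(lines2, broken)
  expect_error(read_cohort(broken), "P2.*two-ish")

  # categorical decoding is case-insensitive
  lower <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], sub(",A,", ",a,", lines[2], fixed = TRUE)), lower)
  one <- read_cohort(lower)
  expect_equal(one$silva, "A")
})

test_that("dsi_third partitions [0,1] with left-open right-closed thirds", {
  expect_equal(as.character(dsi_third(c(0, 1 / 3, 0.5, 2 / 3, 0.8, 1))),
               c("none", "superficial", "middle", "middle", "deep", "deep"))
  # every fraction maps to exactly one category, non-decreasing
  grid <- seq(0, 1, by = 0.01)
  cats <- dsi_third(grid)
  expect_false(anyNA(cats))
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("default candidate set has 16 variables and the six retained ones", {
  vars <- make_cutoff_variables()
  expect_equal(nrow(vars), 16L)
  expect_equal(as.vector(table(vars$factor)[c("age", "silva", "size", "dsi",
                                              "lvsi")]),
               c(3L, 2L, 7L, 2L, 2L))

  six <- make_cutoff_variables(cutoff_config(
    age = numeric(0), silva = c("BC", "C"), size = c(3, 3.5),
    dsi = "2/3", lvsi = "gt_mild"))
  expect_setequal(six$name, c("silva_BC", "silva_C", "size_ge_3",
                              "size_ge_3.5", "dsi_gt_2_3", "lvsi_gt_mild"))

  none <- make_cutoff_variables(cutoff_config(
    age = numeric(0), silva = character(0), size = numeric(0),
    dsi = character(0), lvsi = character(0)))
  expect_equal(nrow(none), 0L)
})

test_that("factor_value implements the documented threshold conventions", {
  co <- make_toy_cohort()
  # P3: silva C, size 3.0, dsi 0.8, substantial LVSI
  expect_true(factor_value(co, "silva_C")[3])
  expect_false(factor_value(co, "silva_C")[2])
  expect_true(factor_value(co, "silva_BC")[2])
  expect_true(factor_value(co, "size_ge_3")[3])    # inclusive at 3.0
  expect_false(factor_value(co, "size_ge_3.5")[3])
  expect_false(factor_value(co, "dsi_gt_2_3")[5])  # exactly 2/3 is negative
  expect_true(factor_value(co, "dsi_gt_2_3")[3])
  expect_true(factor_value(co, "lvsi_gt_mild")[3])
  expect_false(factor_value(co, "lvsi_gt_mild")[2])  # mild is not > mild
  expect_true(factor_value(co, "lvsi_ge_mild")[2])
  expect_error(factor_value(co, "nonexistent"), "unknown cutoff variable")
})

test_that("raising severity never flips a factor from true to false", {
  co <- as.data.frame(make_toy_cohort())
  worse <- co
  worse$tumor_size_cm <- worse$tumor_size_cm + 1
  worse$dsi_fraction <- pmin(worse$dsi_fraction + 0.2, 1)
  worse$lvsi <- c(none = "mild", mild = "substantial",
                  substantial = "substantial")[worse$lvsi]
  vars <- make_cutoff_variables()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, , drop = FALSE]
    if (v$factor %in% c("size", "dsi", "lvsi")) {
      expect_true(all(factor_value(co, v) <= factor_value(worse, v)),
                  info = v$name)
    }
  }
})

test_that("high-risk exclusion partitions the cohort and is idempotent", {
  co <- make_toy_cohort()
  hr <- is_high_risk(co)
  expect_equal(hr, c(FALSE, FALSE, TRUE, TRUE, FALSE))  # pelvic LN; margin
  inter <- filter_intermediate(co)
  expect_equal(nrow(inter), 3L)
  expect_equal(nrow(inter) + sum(hr), nrow(co))
  expect_false(any(is_high_risk(inter)))
  refiltered <- filter_intermediate(inter)
  attr(refiltered, "label") <- attr(inter, "label")
  expect_equal(as.data.frame(refiltered), as.data.frame(inter))

  # all high-risk -> empty cohort
  allhr <- as.data.frame(co)
  allhr$margin_positive <- TRUE
  expect_equal(nrow(filter_intermediate(as_cohort(allhr))), 0L)

  # substantial LVSI alone is not high risk
  one <- as.data.frame(co)[4, ]
  one$margin_positive <- FALSE
  expect_false(is_high_risk(as_cohort(one)))
})
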
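test_that("load_cohort round-trips a conforming file and preserves row order", {
  sch <- toy_schema()
  schema_path <- tempfile(fileext = ".yaml")
  write_schema(sch, schema_path)
  d <- toy_responses(sch, coffee = c(3, 7), alcohol = c(1, 9),
                     noodle = c(2, 5), grill = c(4, 1),
                     id = c("first", "second"))
  csv <- tempfile(fileext = ".csv")
  write.csv(d, csv, row.names = FALSE)
  co <- load_cohort(csv, schema_path)
  expect_s3_class(co, "dc_cohort")
  expect_equal(n_participants(co), 2)
  expect_equal(co$data$id, c("first", "second"))
  expect_equal(co$data$coffee, d$coffee)
})

test_that("schema and response validation errors name the offending pieces", {
  sch <- toy_schema()
  schema_path <- tempfile(fileext = ".yaml")
  write_schema(sch, schema_path)
  d <- toy_responses(sch, 3, 1, 2, 4)
  csv <- tempfile(fileext = ".csv")
  write.csv(d[, setdiff(names(d), "coffee")], csv, row.names = FALSE)
  expect_error(load_cohort(csv, schema_path), "coffee")
  d2 <- d
  d2$coffee <- "ten times/day"
  write.csv(d2, csv, row.names = FALSE)
  expect_error(load_cohort(csv, schema_path), "T001.*coffee|coffee.*T001")
})

test_that("covariate derivation follows the clinical thresholds exactly", {
  d <- data.frame(id = "x", weight = 70, height = 1.75,
                  sbp = 142, dbp = 80, fbg = 126, ldl = 139, hdl = 41,
                  triglycerides = 149, sds = 39, sleep_hours = 7)
  out <- derive_covariates(d)
  expect_equal(out$bmi, 70 / 1.75^2, tolerance = 1e-12)  # 22.857
  expect_true(out$baseline_hypertension)   # SBP >= 140 alone suffices
  expect_false(out$diabetes)               # FBG rule is strict >126
  expect_false(out$dyslipidemia)           # all three lipid rules just miss
  expect_false(out$depressive)
  expect_true(out$typical_sleep)

  d$fbg <- 126.5; d$ldl <- 140
  out2 <- derive_covariates(d)
  expect_true(out2$diabetes)
  expect_true(out2$dyslipidemia)           # LDL >= 140

  # a missing measurement yields a flagged-missing NA, never a silent FALSE
  d3 <- data.frame(id = "y", sbp = 120, dbp = NA)
  expect_true(is.na(derive_covariates(d3)$baseline_hypertension))
  d4 <- data.frame(id = "z", sbp = 150, dbp = NA)
  expect_true(derive_covariates(d4)$baseline_hypertension)

  # idempotence
  once <- derive_covariates(d)
  expect_identical(derive_covariates(once), once)
})

test_that("exclusion cascade reproduces the printed selection arithmetic", {
  roster <- fig1_roster()
  expect_equal(nrow(roster), 1253)
  res <- apply_exclusion_cascade(roster, paper_exclusion_steps())
  expect_equal(res$cascade$n_out, 447)
  expect_equal(res$cascade$n_in, 1253)
  expect_equal(res$cascade$steps$n_removed,
               c(99, 295, 16, 52, 9, 188, 39, 44, 64))
  consent_pct <- 100 * (1253 - res$cascade$steps$n_removed[1]) / 1253
  expect_equal(round(consent_pct, 1), 92.1)
  # conservation
  expect_equal(res$cascade$n_in,
               res$cascade$n_out + sum(res$cascade$steps$n_removed))
  # JSON export carries the same arithmetic
  j <- jsonlite::fromJSON(cascade_to_json(res$cascade))
  expect_equal(j$n_out, 447)
})

test_that("cascade edge cases: empty step list and remove-all first step", {
  roster <- fig1_roster()
  res0 <- apply_exclusion_cascade(roster, list())
  expect_equal(res0$cascade$n_out, nrow(roster))
  expect_equal(nrow(res0$cohort), nrow(roster))

  steps <- c(list(everyone = function(d) rep(TRUE, nrow(d))),
             paper_exclusion_steps())
  res1 <- apply_exclusion_cascade(roster, steps)
  expect_equal(res1$cascade$n_out, 0)
  expect_equal(res1$cascade$steps$n_removed[1], nrow(roster))
  expect_true(all(res1$cascade$steps$n_removed[-1] == 0))
})

test_that("permuting cascade steps changes attribution but never the retained set", {
  roster <- fig1_roster()
  steps <- paper_exclusion_steps()
  base <- apply_exclusion_cascade(roster, steps)
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(steps)
    res <- apply_exclusion_cascade(roster, perm)
    expect_equal(res$cascade$n_out, base$cascade$n_out)
    expect_setequal(res$cohort$id, base$cohort$id)
    expect_equal(res$cascade$n_in,
                 res$cascade$n_out + sum(res$cascade$steps$n_removed))
  }
})
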
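test_that("untidy parser enforces the 4-column contract", {
  lines <- c("Patient Name (MRN)\tCollection Date\tCollection Time\tLab Results",
             "MRN1\t5/1/2020\t08:00\tSodium 140 mmol/L",
             "MRN2\t5/2/2020\t\tPotassium 4.0 mmol/L; Sodium 138 mmol/L")
  rows <- parse_ehr_export(lines, delim = "\t")
  expect_equal(nrow(rows), 2)
  expect_equal(rows$source_row, 1:2)
  expect_true(is.na(rows$collection_time[2]))

  three_col <- c("a\tb\tc", "MRN1\t5/1/2020\tSodium 140")
  expect_error(parse_ehr_export(three_col, delim = "\t", header = FALSE),
               regexp = "line 1", class = "labharbor_format_error")
  expect_equal(nrow(parse_ehr_export(character(), delim = "\t")), 0)
})

test_that("panel cells explode into observations with conservation", {
  rows <- tibble::tibble(
    patient_key = "MRN1", collection_date = as.Date("2020-05-01"),
    collection_time = "08:00",
    panel_text = "Sodium 140 mmol/L; Potassium, whole-bld 4.0 mmol/L; ???; K refused",
    source_row = 1L)
  ex <- explode_panels(rows)
  expect_equal(nrow(ex$observations), 3)  # refused is a value token
  expect_equal(nrow(ex$rejects), 1)
  expect_equal(ex$rejects$token, "???")
  # conservation: tokens = observations + rejects
  expect_equal(nrow(ex$observations) + nrow(ex$rejects), 4)
  got <- ex$observations
  expect_equal(got$source_test_name,
               c("Sodium", "Potassium, whole-bld", "K"))
  expect_equal(got$raw_value, c("140", "4.0", "refused"))
  expect_equal(got$raw_unit, c("mmol/L", "mmol/L", ""))

  empty <- rows
  empty$panel_text <- ""
  ex2 <- explode_panels(empty)
  expect_equal(nrow(ex2$observations), 0)
  expect_equal(nrow(ex2$rejects), 0)
})

test_that("EDW parser maps columns and rejects empty test names", {
  tab <- tibble::tibble(
    MRN = c("MRN1", "MRN1", "MRN2", "MRN2", "MRN3"),
    Collection_Date = c("5/1/2020", "5/1/2020", "2020-05-02", "5/3/2020", "5/4/2020"),
    Collection_Time = c("08:00", "08:00", "9:15", "", "10:00"),
    Test_Name = c("Sodium", "Potassium", "Creatinine", "", "Glucose"),
    Result = c("140", "4.0", "1.1", "5", "95"),
    Units = c("mmol/L", "mmol/L", "mg/dL", "", "mg/dL"))
  out <- parse_edw_export(tab)
  expect_equal(nrow(out$observations), 4)
  expect_equal(out$rejects$reason, "empty_test_name")
  expect_equal(out$observations$collection_date[3], as.Date("2020-05-02"))
  expect_equal(out$observations$collection_time[3], "09:15")
  # missing mapped column is a config error
  expect_error(parse_edw_export(tab, default_edw_colmap(test = "LAB_NM")),
               class = "labharbor_config_error")
})

test_that("EDW rendering and re-parsing round-trips observations", {
  truth <- simulate_cohort(sim_config(n_subjects = 8, seed = 5))
  edw <- render_edw(truth)
  out <- parse_edw_export(edw)
  expect_equal(nrow(out$observations), nrow(truth$observations))
  expect_equal(out$observations$raw_value,
               labharbor:::format_value(truth$observations$value))
  expect_equal(out$observations$collection_date,
               truth$observations$collection_date)
})

test_that("two-digit years and ambiguous dates are rejected at parse time", {
  d <- labharbor:::parse_flex_date(c("5/1/2020", "2020-05-01", "5/1/20",
                                     "01-02-2020", "garbage"))
  expect_equal(is.na(d), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(d[1], d[2])
})

test_that("parsing is order-independent beyond preserving input order", {
  truth <- simulate_cohort(sim_config(n_subjects = 6, seed = 9))
  r <- render_untidy(truth)
  rows <- parse_ehr_export(r$lines, delim = "\t")
  perm <- sample(nrow(rows))
  shuffled <- rows[perm, ]
  a <- explode_panels(rows)$observations
  b <- explode_panels(shuffled)$observations
  b <- b[order(b$source_row, match(b$source_test_name, a$source_test_name)), ]
  a <- a[order(a$source_row, match(a$source_test_name, a$source_test_name)), ]
  expect_setequal(paste(a$source_row, a$source_test_name, a$raw_value),
                  paste(b$source_row, b$source_test_name, b$raw_value))
})
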
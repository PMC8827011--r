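test_that("packaged dictionary defines the labs instrument correctly", {
  dd <- fixture_dd
  labs <- dd_lab_fields(dd)
  expect_length(labs, 35)
  expect_false(anyDuplicated(dd$fields$variable_name) > 0)
  expect_true("labs" %in% dd$repeating_forms)
  k <- dd$fields[dd$fields$variable_name == "k", ]
  expect_equal(k$validation, "number")
  expect_equal(k$form_name, "labs")
  # shared per-instance collection date and time fields
  expect_equal(dd$fields$validation[dd$fields$variable_name == "lab_date"],
               "date_mdy")
  expect_equal(dd$fields$validation[dd$fields$variable_name == "lab_time"],
               "time_hm")
  # survival instruments present and non-repeating
  expect_true(all(c("subject_status", "patient_characteristics") %in%
                    dd$fields$form_name))
  expect_false(any(c("subject_status", "patient_characteristics") %in%
                     dd$repeating_forms))
})

test_that("dictionary CSV round-trips and second write is byte-identical", {
  dd <- fixture_dd
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dd_csv(dd, p1)
  dd2 <- read_dd_csv(p1)
  expect_identical(dd2, dd)
  write_dd_csv(dd2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # row count = fields + header
  expect_length(readLines(p1), nrow(dd$fields) + 1)
})

test_that("malformed dictionary CSVs fail loudly", {
  dd <- fixture_dd
  p <- withr::local_tempfile(fileext = ".csv")
  write_dd_csv(dd, p)
  lines <- readLines(p)
  # drop the Form Name header
  no_form <- sub("Form Name", "Not Form", lines[1], fixed = TRUE)
  writeLines(c(no_form, lines[-1]), p)
  expect_error(read_dd_csv(p), class = "labharbor_schema_error")
  # duplicate variable name
  write_dd_csv(dd, p)
  lines <- readLines(p)
  krow <- grep("^k,", lines, value = TRUE)[1]
  writeLines(c(lines, krow), p)
  expect_error(read_dd_csv(p), class = "labharbor_integrity_error")
})

test_that("number validation accepts exactly the decimal-numeral grammar", {
  k <- fixture_dd$fields[fixture_dd$fields$variable_name == "k", ]
  # generator: build known numerals from parts, known non-numerals by
  # construction; validate_value must match the labels exactly
  set.seed(11)
  for (i in 1:200) {
    sign <- sample(c("", "+", "-"), 1)
    intpart <- paste(sample(0:9, sample(1:4, 1), replace = TRUE), collapse = "")
    frac <- sample(c("", paste0(".", paste(sample(0:9, sample(1:3, 1),
                                                  replace = TRUE),
                                           collapse = ""))), 1)
    numeral <- paste0(sign, intpart, frac)
    expect_true(validate_value(k, numeral)$ok, info = numeral)
    expect_true(validate_value(k, paste0("  ", numeral, " "))$ok,
                info = "whitespace stripped before validation")
  }
  non_numerals <- c("refused", "canceled", "REFUSED", "Canceled", "<0.01",
                    ">5", "1e5", "Inf", "NaN", "NA", "four", "4.0.1",
                    "5,0", "--4", "4-", "0x10", "", " ", "4 0", "refused 4")
  for (v in non_numerals) {
    res <- validate_value(k, v)
    expect_false(res$ok, info = v)
    expect_true(nzchar(res$message))
  }
})

test_that("date and time validation require real M/D/Y dates and HH:MM", {
  ld <- fixture_dd$fields[fixture_dd$fields$variable_name == "lab_date", ]
  expect_true(validate_value(ld, "5/1/2020")$ok)
  expect_true(validate_value(ld, "12/31/2020")$ok)
  expect_false(validate_value(ld, "13/45/2020")$ok)
  expect_false(validate_value(ld, "2/30/2020")$ok)
  expect_false(validate_value(ld, "2020-05-01")$ok)  # ISO is not M/D/Y
  expect_false(validate_value(ld, "5/1/20")$ok)      # two-digit year
  lt <- fixture_dd$fields[fixture_dd$fields$variable_name == "lab_time", ]
  expect_true(validate_value(lt, "08:30")$ok)
  expect_true(validate_value(lt, "23:59")$ok)
  expect_false(validate_value(lt, "24:00")$ok)
  expect_false(validate_value(lt, "8:61")$ok)
})

test_that("dictionary invariants are enforced at construction", {
  f <- fixture_dd$fields
  f2 <- rbind(f, f[f$variable_name == "k", ])
  expect_error(lab_dictionary(f2, "labs"), class = "labharbor_integrity_error")
  f3 <- f
  f3$field_type[f3$variable_name == "k"] <- "notes"  # number on non-text
  expect_error(lab_dictionary(f3, "labs"), class = "labharbor_schema_error")
})
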
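test_that("the seven potassium subtype spellings all remap to field k", {
  variants <- c("Potassium", "Potassium-External", "Potassium(POC)",
                "Potassium, whole-bld", "Potassium-Level-External",
                "Potassium, venous", "Potassium-whole-bld/plasma")
  obs <- tibble::tibble(
    patient_key = "MRN1", collection_date = as.Date("2020-05-01"),
    collection_time = "08:00", source_test_name = variants,
    raw_value = "4.0", raw_unit = "mmol/L",
    source_row = seq_along(variants))
  rm <- remap_tests(obs, fixture_lut)
  expect_equal(nrow(rm$mapped), 7)
  expect_true(all(rm$mapped$field_code == "k"))
  # case-insensitive after whitespace normalization, no fuzzy matching
  obs$source_test_name <- c("POTASSIUM", "potassium-external",
                            "  Potassium(POC) ", "Potassium,   whole-bld",
                            "Zinc-RBC", "Potasium", "K+")
  rm2 <- remap_tests(obs, fixture_lut)
  expect_equal(sum(rm2$mapped$field_code == "k"), 4)
  expect_equal(nrow(rm2$report), 3)
  expect_true(all(rm2$report$reason == "unmapped_test"))
})

test_that("value cleaning itemizes nonimportable tokens and unit mismatches", {
  obs <- tibble::tibble(
    patient_key = "MRN1", collection_date = as.Date(c("2020-05-01",
      "2020-05-01", "2020-05-01", "2020-05-01", NA)),
    collection_time = "08:00",
    source_test_name = "Potassium",
    raw_value = c("refused", "Canceled", "4.0", "4.0", "4.1"),
    raw_unit = c("mmol/L", "", "mg/dL", "mmol/L", "mmol/L"),
    source_row = 1:5)
  rm <- remap_tests(obs, fixture_lut)
  nv <- normalize_values(rm$mapped, dd = fixture_dd)
  expect_equal(nrow(nv$clean), 1)
  expect_equal(nv$clean$value, 4.0)
  counts <- exclusion_counts(nv$report)
  expect_equal(counts[["nonimportable_value"]], 2)
  expect_equal(counts[["unit_mismatch"]], 1)
  expect_equal(counts[["invalid_date"]], 1)
  expect_equal(sum(counts), nrow(nv$report))
})

test_that("scale factors apply audited unit conversions", {
  lut <- lab_lookup(tibble::tibble(
    source_name = "Potassium mEq", field_code = "k",
    allowed_units = "mEq/L", scale_factor = 1), dd = fixture_dd)
  obs <- tibble::tibble(
    patient_key = "M", collection_date = as.Date("2020-05-01"),
    collection_time = NA_character_, source_test_name = "Potassium mEq",
    raw_value = "4.0", raw_unit = "mEq/L", source_row = 1L)
  nv <- normalize_values(remap_tests(obs, lut)$mapped, dd = fixture_dd)
  expect_equal(nv$clean$value, 4.0)
  lut2 <- lab_lookup(tibble::tibble(
    source_name = "Hemoglobin g/L", field_code = "hgb",
    allowed_units = "g/L", scale_factor = 0.1), dd = fixture_dd)
  obs2 <- obs
  obs2$source_test_name <- "Hemoglobin g/L"
  obs2$raw_value <- "140"
  obs2$raw_unit <- "g/L"
  nv2 <- normalize_values(remap_tests(obs2, lut2)$mapped, dd = fixture_dd)
  expect_equal(nv2$clean$value, 14)
})

test_that("de-identification substitutes record ids and is strict by default", {
  obs <- normalize_values(remap_tests(tiny_raw_obs(), fixture_lut)$mapped,
                          dd = fixture_dd)$clean
  de <- deidentify(obs, tiny_crosswalk())
  expect_equal(nrow(de$obs), 4)
  expect_equal(sort(unique(de$obs$record_id)), c("A-0001", "A-0002"))
  expect_false("patient_key" %in% names(de$obs))
  # same patient key always maps to the same record id
  expect_equal(de$obs$record_id[1], de$obs$record_id[2])
  # unknown key: strict errors without naming the MRN; lax itemizes
  half <- lab_crosswalk(tibble::tibble(patient_key = "MRN12345",
                                       record_id = "A-0001"))
  err <- tryCatch(deidentify(obs, half), error = identity)
  expect_s3_class(err, "labharbor_deidentify_error")
  expect_false(grepl("MRN67890", conditionMessage(err)))
  lax <- deidentify(obs, half, strict = FALSE)
  expect_equal(nrow(lax$obs), 2)
  expect_equal(exclusion_counts(lax$report)[["unknown_patient"]], 2)
})

test_that("instances number collection events chronologically per record", {
  obs <- tibble::tibble(
    record_id = "A-0001", field_code = c("k", "na", "k", "k"),
    value = c(4, 140, 4.2, 4.4), unit = "mmol/L",
    collection_date = as.Date(c("2020-05-01", "2020-05-01", "2020-05-01",
                                "2020-04-30")),
    collection_time = c("08:00", "08:00", "14:00", NA),
    source_row = 1:4)
  out <- assign_instances(obs)
  expect_equal(out$instance, c(2, 2, 3, 1))
  # same-day repeat draws get distinct instances; same-event labs share one
  expect_equal(out$instance[1], out$instance[2])
  # permuting input order leaves assignments unchanged
  perm <- c(3, 1, 4, 2)
  out2 <- assign_instances(obs[perm, ])
  expect_equal(out2$instance, out$instance[perm])
  # untimed draw sorts before any timed draw on the same date
  obs$collection_date <- as.Date("2020-05-01")
  expect_equal(assign_instances(obs)$instance, c(2, 2, 3, 1))
})

test_that("the import table has the registry header and event rows", {
  obs <- tibble::tibble(
    record_id = "A-0001", field_code = c("k", "na"),
    value = c(4, 140), unit = "mmol/L",
    collection_date = as.Date("2020-05-01"),
    collection_time = "08:00", source_row = 1:2)
  tbl <- to_redcap_long(obs, dd = fixture_dd)
  expect_equal(names(tbl),
               c("record_id", "redcap_repeat_instrument",
                 "redcap_repeat_instance", "lab_date", "lab_time",
                 dd_lab_fields(fixture_dd)))
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$k, "4")
  expect_equal(tbl$na, "140")
  expect_equal(tbl$lab_date, "5/1/2020")
  expect_equal(tbl$redcap_repeat_instrument, "labs")
  # empty input: header-only table
  expect_equal(nrow(to_redcap_long(obs[0, ], dd = fixture_dd)), 0)
})

test_that("duplicate same-field same-event results open a new instance", {
  obs <- tibble::tibble(
    record_id = "A-0001", field_code = c("k", "na", "k"),
    value = c(4.0, 140, 4.4), unit = "mmol/L",
    collection_date = as.Date("2020-05-01"),
    collection_time = "08:00", source_row = 1:3)
  tbl <- to_redcap_long(obs, dd = fixture_dd)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$redcap_repeat_instance, 1:2)
  expect_equal(tbl$k, c("4", "4.4"))       # later source order opens instance 2
  expect_equal(tbl$na, c("140", ""))
  # truly identical key with conflicting values cannot be represented
  obs$source_row <- c(1, 2, 1)
  obs$field_code <- c("k", "k", "k")
  obs$value <- c(4.0, 4.2, 4.4)
  obs$source_row <- c(1, 1, 1)
  expect_error(to_redcap_long(obs, dd = fixture_dd),
               class = "labharbor_integrity_error")
})

test_that("import validation flags exactly the nonconforming cells", {
  obs <- tibble::tibble(
    record_id = "A-0001", field_code = "k", value = 4,
    unit = "mmol/L", collection_date = as.Date("2020-05-01"),
    collection_time = "08:00", source_row = 1L)
  tbl <- to_redcap_long(obs, dd = fixture_dd)
  expect_equal(nrow(validate_import(tbl, fixture_dd)), 0)
  bad <- tbl
  bad$lab_date <- "2020-14-01"
  rep <- validate_import(bad, fixture_dd)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$column, "lab_date")
  expect_equal(rep$row, 1L)
  # a nonempty report blocks export unless forced
  p <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_import_csv(bad, p, dd = fixture_dd),
               class = "labharbor_validation_error")
  expect_false(file.exists(p))
  write_import_csv(bad, p, dd = fixture_dd, force = TRUE)
  expect_true(file.exists(p))
})

test_that("site aggregation conserves rows and demands disjoint ids", {
  truth_a <- simulate_cohort(sim_config(n_subjects = 4, seed = 1,
                                        site_prefix = "A"))
  truth_b <- simulate_cohort(sim_config(n_subjects = 6, seed = 2,
                                        site_prefix = "B"))
  ta <- truth_import_table(truth_a)
  tb <- truth_import_table(truth_b)
  agg <- aggregate_sites(list(ta, tb))
  expect_equal(nrow(agg), nrow(ta) + nrow(tb))
  expect_identical(aggregate_sites(list(ta)), ta)
  expect_error(aggregate_sites(list(ta, ta)),
               class = "labharbor_integrity_error")
  tb2 <- tb
  names(tb2)[names(tb2) == "k"] <- "potassium"
  expect_error(aggregate_sites(list(ta, tb2)),
               class = "labharbor_schema_error")
})

test_that("LOINC annotation emits one code per covered field", {
  ann <- annotate_loinc(fixture_dd)
  expect_equal(nrow(ann), 35)
  expect_false(anyDuplicated(ann$field_code) > 0)
  expect_false(anyDuplicated(ann$loinc_code) > 0)
  expect_equal(nrow(annotate_loinc(fixture_dd, c())), 0)
  dup <- c(k = "2823-3", k = "6298-4")
  expect_error(annotate_loinc(fixture_dd, dup),
               class = "labharbor_integrity_error")
  expect_error(annotate_loinc(fixture_dd, c(zzz = "1-1")),
               class = "labharbor_schema_error")
})

test_that("harmonization is idempotent on already-clean output", {
  truth <- simulate_cohort(sim_config(n_subjects = 10, seed = 21))
  tbl <- truth_import_table(truth)
  obs <- import_to_obs(tbl, dd = fixture_dd)
  obs$unit <- NA_character_
  tbl2 <- to_redcap_long(obs, dd = fixture_dd)
  expect_equal(as.data.frame(tbl2), as.data.frame(tbl))
})
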
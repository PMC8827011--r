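# Shared small fixtures, built in code.

fixture_dd <- default_mcc_dictionary()
fixture_lut <- default_lookup(fixture_dd)

# A tiny hand-written observation set for harmonize-stage tests.
tiny_raw_obs <- function() {
  tibble::tibble(
    patient_key = c("MRN12345", "MRN12345", "MRN67890", "MRN67890"),
    collection_date = as.Date(c("2020-05-01", "2020-05-01",
                                "2020-05-01", "2020-06-02")),
    collection_time = c("08:00", "08:00", NA, "14:30"),
    source_test_name = c("Sodium", "Potassium, whole-bld",
                         "POTASSIUM", "Creatinine-External"),
    raw_value = c("140", "4.0", "3.8", "1.12"),
    raw_unit = c("mmol/L", "mmol/L", "mmol/L", "mg/dL"),
    source_row = 1:4
  )
}

tiny_crosswalk <- function() {
  lab_crosswalk(tibble::tibble(patient_key = c("MRN12345", "MRN67890"),
                               record_id = c("A-0001", "A-0002")),
                site_prefix = "A")
}

# Run the full ingest+harmonize pipeline on a rendered untidy export.
run_pipeline_on <- function(truth, lut = fixture_lut, dd = fixture_dd) {
  r <- render_untidy(truth, lut = lut)
  rows <- parse_ehr_export(r$lines, delim = "\t")
  ex <- explode_panels(rows)
  res <- harmonize_labs(ex$observations, lut = lut, dd = dd,
                        xwalk = truth$crosswalk)
  res$manifest <- r$manifest
  res$rejects <- ex$rejects
  res
}
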
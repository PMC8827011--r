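#' Exclusion reports
#'
#' Every raw observation the pipeline cannot import is itemized, never
#' silently dropped: record conservation (`|raw| = |imported| +
#' |excluded|`) is an invariant checked on every run. Reasons:
#' `unmapped_test`, `nonimportable_value`, `unit_mismatch`,
#' `invalid_date`, `unknown_patient`. Exclusion rows intentionally carry
#' the source row number but not the patient key, so the report itself
#' is shareable.
#'
#' @param rows Tibble of exclusions.
#' @return A tibble of class `exclusion_report` with columns
#'   `source_row`, `source_test_name`, `field_code`, `raw_value`,
#'   `raw_unit`, `reason`.
#' @export
exclusion_report <- function(rows = NULL) {
  empty <- tibble(source_row = integer(), source_test_name = character(),
                  field_code = character(), raw_value = character(),
                  raw_unit = character(), reason = character())
  out <- if (is.null(rows) || !nrow(rows)) empty else {
    bind_rows(empty, as_tibble(rows))[names(empty)]
  }
  class(out) <- c("exclusion_report", class(tibble()))
  out
}

#' @rdname exclusion_report
#' @param report An `exclusion_report`.
#' @return `exclusion_counts()` returns a named integer vector of counts
#'   per reason; the counts always sum to the number of exclusions.
#' @export
exclusion_counts <- function(report) {
  reasons <- c("unmapped_test", "nonimportable_value", "unit_mismatch",
               "invalid_date", "unknown_patient")
  out <- table(factor(report$reason, levels = reasons))
  stats::setNames(as.integer(out), reasons)
}

#' Remap source test names to registry field codes
#'
#' Tags each raw observation with the registry field code its normalized
#' source name maps to. Matching is exact after trimming, internal
#' whitespace collapse and case folding — deliberately no fuzzy
#' matching, which is unsafe for clinical data; unmapped names surface
#' in the exclusion report instead.
#'
#' @param obs Raw observations (from [explode_panels()] or
#'   [parse_edw_export()]).
#' @param lut A [lab_lookup()].
#' @return List with `mapped` (observations plus `field_code`,
#'   `allowed_units`, `scale_factor`) and `report` (an
#'   [exclusion_report()] of `unmapped_test` rows).
#' @examples
#' lut <- default_lookup()
#' obs <- tibble::tibble(patient_key = "M1", collection_date = as.Date("2020-05-01"),
#'   collection_time = NA_character_, source_test_name = "Potassium, whole-bld",
#'   raw_value = "4.0", raw_unit = "mmol/L", source_row = 1L)
#' remap_tests(obs, lut)$mapped$field_code  # "k"
#' @export
remap_tests <- function(obs, lut) {
  idx <- match(normalize_test_name(obs$source_test_name), lut$norm_name)
  hit <- !is.na(idx)
  mapped <- obs[hit, ]
  mapped$field_code <- lut$field_code[idx[hit]]
  mapped$allowed_units <- lut$allowed_units[idx[hit]]
  mapped$scale_factor <- lut$scale_factor[idx[hit]]
  miss <- obs[!hit, ]
  report <- exclusion_report(if (nrow(miss)) tibble(
    source_row = miss$source_row, source_test_name = miss$source_test_name,
    field_code = NA_character_, raw_value = miss$raw_value,
    raw_unit = miss$raw_unit, reason = "unmapped_test"))
  list(mapped = mapped, report = report)
}

#' Clean values and enforce dictionary units
#'
#' The cleaning stage the registry depends on: a value must validate as
#' a decimal numeral under the dictionary's number rule — tokens such as
#' "refused" or "canceled" (any case), comparator strings like "<0.01",
#' and free text all become `nonimportable_value` exclusions. The unit
#' must be one the lookup table allows for that field
#' (`unit_mismatch` otherwise; there is no implicit conversion — an
#' audited `scale_factor` in the lookup is the only multiplier applied).
#' Observations whose collection date failed to parse are excluded as
#' `invalid_date`.
#'
#' @param mapped Output `$mapped` of [remap_tests()].
#' @param dd The active dictionary.
#' @return List with `clean` (lab observations: `patient_key`,
#'   `field_code`, `value`, `unit`, `collection_date`,
#'   `collection_time`, `source_row`) and `report` (exclusions).
#' @export
normalize_values <- function(mapped, dd = default_mcc_dictionary()) {
  n <- nrow(mapped)
  if (!n) {
    return(list(clean = empty_lab_obs(), report = exclusion_report()))
  }
  ok_num <- check_valid("number", mapped$raw_value)$ok
  allowed <- lookup_units(mapped)
  unit <- trimws(mapped$raw_unit)
  ok_unit <- mapply(function(u, al) u %in% al, unit, allowed, USE.NAMES = FALSE)
  ok_date <- !is.na(mapped$collection_date)
  reason <- rep(NA_character_, n)
  reason[!ok_unit] <- "unit_mismatch"
  reason[!ok_num] <- "nonimportable_value"   # value problems trump unit
  reason[!ok_date] <- "invalid_date"
  keep <- is.na(reason)
  cl <- mapped[keep, ]
  clean <- tibble(
    patient_key = cl$patient_key,
    field_code = cl$field_code,
    value = as.numeric(cl$raw_value) * cl$scale_factor,
    unit = trimws(cl$raw_unit),
    collection_date = cl$collection_date,
    collection_time = cl$collection_time,
    source_row = cl$source_row
  )
  ex <- mapped[!keep, ]
  report <- exclusion_report(if (nrow(ex)) tibble(
    source_row = ex$source_row, source_test_name = ex$source_test_name,
    field_code = ex$field_code, raw_value = ex$raw_value,
    raw_unit = ex$raw_unit, reason = reason[!keep]))
  list(clean = clean, report = report)
}

empty_lab_obs <- function() {
  tibble(patient_key = character(), field_code = character(),
         value = numeric(), unit = character(),
         collection_date = as.Date(character()),
         collection_time = character(), source_row = integer())
}

#' Substitute record ids for patient identifiers
#'
#' Replaces the patient key (name/MRN) with the registry-assigned
#' `record_id` from the crosswalk. After this stage no patient key from
#' the crosswalk domain appears anywhere in the payload. In strict mode
#' an unknown patient key is an error naming only the source row (never
#' the key itself); with `strict = FALSE` unknown patients are routed to
#' the exclusion report as `unknown_patient`.
#'
#' @param obs Clean observations from [normalize_values()].
#' @param xwalk A [lab_crosswalk()].
#' @param strict Fail on unknown patient keys?
#' @return List with `obs` (observations keyed by `record_id`) and
#'   `report`.
#' @export
deidentify <- function(obs, xwalk, strict = TRUE) {
  idx <- match(obs$patient_key, xwalk$patient_key)
  unknown <- is.na(idx)
  if (any(unknown) && strict) {
    stop_labharbor(sprintf(
      "crosswalk does not cover the patient on source row(s) %s",
      paste(head(obs$source_row[unknown], 5), collapse = ", ")),
      "labharbor_deidentify_error")
  }
  out <- obs[!unknown, ]
  out$record_id <- xwalk$record_id[idx[!unknown]]
  out$patient_key <- NULL
  out <- out[c("record_id", setdiff(names(out), "record_id"))]
  ex <- obs[unknown, ]
  report <- exclusion_report(if (nrow(ex)) tibble(
    source_row = ex$source_row, source_test_name = NA_character_,
    field_code = ex$field_code, raw_value = format_value(ex$value),
    raw_unit = ex$unit, reason = "unknown_patient"))
  list(obs = out, report = report)
}

#' Assign repeating-instrument instances
#'
#' One labs-form instance corresponds to one collection event: all labs
#' sharing a `(record_id, date, time)` share one instance, and instances
#' are numbered 1..k per record in chronological order. An absent
#' collection time sorts before any timed draw on the same date. The
#' assignment depends only on the set of events, not on input row order.
#'
#' @param obs De-identified observations.
#' @return The observations with an `instance` column.
#' @export
assign_instances <- function(obs) {
  if (!nrow(obs)) {
    obs$instance <- integer()
    return(obs)
  }
  key <- paste(obs$collection_date, time_sort_key(obs$collection_time),
               sep = "\r")
  obs$instance <- NA_integer_
  for (rid in unique(obs$record_id)) {
    sel <- obs$record_id == rid
    k <- key[sel]
    lev <- sort(unique(k))
    obs$instance[sel] <- match(k, lev)
  }
  obs
}

#' Run the full harmonization pipeline
#'
#' Remap, clean, de-identify, assign instances and pivot to the
#' REDCap-importable table, returning the table together with the
#' combined exclusion report and conservation counts
#' (`n_raw = n_imported + n_excluded` always holds).
#'
#' @param raw Raw observations (from [explode_panels()] or
#'   [parse_edw_export()]).
#' @param lut A [lab_lookup()].
#' @param dd The dictionary.
#' @param xwalk A [lab_crosswalk()].
#' @param strict Passed to [deidentify()].
#' @return List with `table` (the import table), `exclusions` (an
#'   [exclusion_report()]) and `counts` (named list: `n_raw`,
#'   `n_imported`, `n_excluded`).
#' @export
harmonize_labs <- function(raw, lut = default_lookup(),
                           dd = default_mcc_dictionary(), xwalk,
                           strict = TRUE) {
  n_raw <- nrow(raw)
  rm <- remap_tests(raw, lut)
  nv <- normalize_values(rm$mapped, dd = dd)
  de <- deidentify(nv$clean, xwalk, strict = strict)
  obs <- assign_instances(de$obs)
  tbl <- to_redcap_long(obs, dd = dd)
  exclusions <- exclusion_report(bind_rows(rm$report, nv$report, de$report))
  n_imported <- nrow(obs)
  list(table = tbl, exclusions = exclusions,
       counts = list(n_raw = n_raw, n_imported = n_imported,
                     n_excluded = nrow(exclusions)))
}
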
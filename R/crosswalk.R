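#' De-identification crosswalks
#'
#' The crosswalk is the only place patient identifiers (names/MRNs) meet
#' registry record ids. It lives on the PHI side of the pipeline: it is
#' read, used to substitute `record_id` for the patient key, and never
#' co-located with shareable outputs. Record ids are zero-padded integers
#' with an optional site prefix (e.g. `"A-0001"`), which also guarantees
#' disjoint id sets when sites are aggregated.
#'
#' @param entries Data frame with columns `patient_key`, `record_id`.
#' @param site_prefix Site prefix recorded with the table.
#' @return A tibble of class `lab_crosswalk`.
#' @export
lab_crosswalk <- function(entries, site_prefix = "") {
  entries <- as_tibble(entries)[c("patient_key", "record_id")]
  entries$patient_key <- as.character(entries$patient_key)
  entries$record_id <- as.character(entries$record_id)
  if (anyDuplicated(entries$patient_key)) {
    stop_labharbor("crosswalk maps one patient key twice",
                   "labharbor_integrity_error")
  }
  if (anyDuplicated(entries$record_id)) {
    stop_labharbor("crosswalk assigns one record_id to two patients",
                   "labharbor_integrity_error")
  }
  structure(entries, site_prefix = site_prefix,
            class = c("lab_crosswalk", class(entries)))
}

#' Build a crosswalk for a set of patient keys
#'
#' @param patient_keys Character vector of patient names/MRNs.
#' @param site_prefix Site prefix for the generated record ids.
#' @param width Zero-padding width.
#' @return A [lab_crosswalk()].
#' @examples
#' make_crosswalk(c("MRN12345", "MRN67890"), site_prefix = "A")
#' @export
make_crosswalk <- function(patient_keys, site_prefix = "A", width = 4) {
  patient_keys <- unique(as.character(patient_keys))
  ids <- sprintf(paste0("%s-%0", width, "d"),
                 site_prefix, seq_along(patient_keys))
  if (!nzchar(site_prefix)) {
    ids <- sprintf(paste0("%0", width, "d"), seq_along(patient_keys))
  }
  lab_crosswalk(tibble(patient_key = patient_keys, record_id = ids),
                site_prefix = site_prefix)
}

#' Read / write a crosswalk CSV (PHI side)
#'
#' @param path File path; keep it outside any shareable output
#'   directory.
#' @param xwalk A [lab_crosswalk()].
#' @param site_prefix Site prefix to attach on read.
#' @export
read_crosswalk_csv <- function(path, site_prefix = "") {
  tab <- readr::read_csv(path, col_types = readr::cols(
    patient_key = readr::col_character(),
    record_id = readr::col_character()), progress = FALSE)
  lab_crosswalk(tab, site_prefix = site_prefix)
}

#' @rdname read_crosswalk_csv
#' @export
write_crosswalk_csv <- function(xwalk, path) {
  readr::write_csv(as_tibble(xwalk[c("patient_key", "record_id")]), path,
                   progress = FALSE)
  invisible(path)
}
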
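#' Lookup tables: source lab subtypes to registry field codes
#'
#' Bulk EHR pulls report many spellings ("subtypes") of the same test —
#' potassium alone arrives as "Potassium", "Potassium-External",
#' "Potassium(POC)", "Potassium, whole-bld", "Potassium-Level-External",
#' "Potassium, venous", "Potassium-whole-bld/plasma". The lookup table is
#' the key-value map from a normalized source test name to the registry
#' field code, the set of units the data dictionary accepts for it, and
#' an explicit scale factor (default 1 — no unit conversion unless a site
#' audits one in).
#'
#' @param entries A data frame with columns `source_name`, `field_code`,
#'   `allowed_units` (units separated by `|`) and optionally
#'   `scale_factor`.
#' @param dd Dictionary the table must be valid against: every
#'   `field_code` must be a lab field.
#' @return A tibble of class `lab_lookup` keyed by normalized source
#'   name.
#' @export
lab_lookup <- function(entries, dd = default_mcc_dictionary()) {
  entries <- as_tibble(entries)
  needed <- c("source_name", "field_code", "allowed_units")
  missing <- setdiff(needed, names(entries))
  if (length(missing)) {
    stop_labharbor(paste0("lookup table missing column(s): ",
                          paste(missing, collapse = ", ")),
                   "labharbor_schema_error")
  }
  if (!"scale_factor" %in% names(entries)) entries$scale_factor <- 1
  entries$scale_factor <- as.numeric(entries$scale_factor)
  if (any(!is.finite(entries$scale_factor) | entries$scale_factor <= 0)) {
    stop_labharbor("scale_factor must be a positive number",
                   "labharbor_schema_error")
  }
  entries$norm_name <- normalize_test_name(entries$source_name)
  if (anyDuplicated(entries$norm_name)) {
    dup <- entries$source_name[duplicated(entries$norm_name)][1]
    stop_labharbor(paste0("duplicate source name in lookup table: ", dup),
                   "labharbor_integrity_error")
  }
  unknown <- setdiff(unique(entries$field_code), dd_lab_fields(dd))
  if (length(unknown)) {
    stop_labharbor(paste0("lookup field code(s) not in dictionary: ",
                          paste(unknown, collapse = ", ")),
                   "labharbor_schema_error")
  }
  if (any(!nzchar(entries$allowed_units))) {
    stop_labharbor("allowed_units must be nonempty for every entry",
                   "labharbor_schema_error")
  }
  structure(entries[c("source_name", "norm_name", "field_code",
                      "allowed_units", "scale_factor")],
            class = c("lab_lookup", class(entries)))
}

#' Packaged demo lookup table
#'
#' Roughly 280 source-name variants mapping onto the 35 registry fields:
#' the seven potassium subtype spellings seen in real Epic/Clarity pulls,
#' plus generated suffix variants (External, point-of-care, outside
#' hospital, ...) for every field. This is an editable demo fixture — a
#' registry deploys its own curated table — but it exercises the same
#' remapping mechanics at the same scale.
#'
#' @param dd Dictionary to validate against.
#' @return A [lab_lookup()].
#' @export
default_lookup <- function(dd = default_mcc_dictionary()) {
  labs <- lab_field_table()
  suffixes <- c("", "-External", "(POC)", "-Level-External", ", serum",
                ", plasma", "-OSH", " (Manual)")
  base <- tidyr::crossing(labs[c("field_code", "label", "unit")],
                          suffix = suffixes)
  base$source_name <- paste0(base$label, base$suffix)
  k_unit <- labs$unit[labs$field_code == "k"]
  k_extra <- tibble(
    field_code = "k",
    source_name = c("Potassium, whole-bld", "Potassium, venous",
                    "Potassium-whole-bld/plasma"),
    unit = k_unit
  )
  entries <- bind_rows(base[c("source_name", "field_code", "unit")],
                       k_extra[c("source_name", "field_code", "unit")])
  entries <- tibble(source_name = entries$source_name,
                    field_code = entries$field_code,
                    allowed_units = entries$unit,
                    scale_factor = 1)
  lab_lookup(entries, dd = dd)
}

lookup_units <- function(lut) {
  strsplit(lut$allowed_units, "|", fixed = TRUE)
}

#' Read / write a lookup table CSV
#'
#' Columns `source_name`, `field_code`, `allowed_units` (pipe-separated),
#' `scale_factor`.
#'
#' @param path File path.
#' @param lut A [lab_lookup()].
#' @param dd Dictionary to validate against on read.
#' @return `read_lookup_csv()` returns a [lab_lookup()].
#' @export
read_lookup_csv <- function(path, dd = default_mcc_dictionary()) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    source_name = readr::col_character(), field_code = readr::col_character(),
    allowed_units = readr::col_character(), scale_factor = readr::col_double()),
    progress = FALSE)
  lab_lookup(tab, dd = dd)
}

#' @rdname read_lookup_csv
#' @export
write_lookup_csv <- function(lut, path) {
  readr::write_csv(lut[c("source_name", "field_code", "allowed_units",
                         "scale_factor")], path, progress = FALSE)
  invisible(path)
}
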
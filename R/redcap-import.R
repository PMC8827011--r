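#' Pivot observations into the REDCap-importable table
#'
#' Produces one output row per collection event — `(record_id,
#' redcap_repeat_instance)` — with the literal REDCap repeating-import
#' columns, the event's shared date (M/D/Y) and time fields, and one
#' column per dictionary lab field (blank when not measured at that
#' event). If the same field was measured twice at one event (same
#' record, date and time), the later result (by source order) opens a
#' new instance rather than overwriting; two results for the same field
#' at the same event *and* the same source position cannot be
#' represented and raise an integrity error.
#'
#' @param obs De-identified observations (see [deidentify()]); instance
#'   numbering is (re)computed here so duplicate-field events split
#'   deterministically.
#' @param dd The dictionary defining the lab field columns.
#' @return A tibble whose header is `record_id`,
#'   `redcap_repeat_instrument`, `redcap_repeat_instance`, `lab_date`,
#'   `lab_time`, then the lab fields in dictionary order. All payload
#'   cells are text, as in a REDCap import CSV.
#' @export
to_redcap_long <- function(obs, dd = default_mcc_dictionary()) {
  lab_fields <- dd_lab_fields(dd)
  header <- c("record_id", "redcap_repeat_instrument",
              "redcap_repeat_instance", "lab_date", "lab_time", lab_fields)
  if (!nrow(obs)) {
    out <- as_tibble(stats::setNames(
      replicate(length(header), character(), simplify = FALSE), header))
    out$redcap_repeat_instance <- integer()
    return(out)
  }
  unknown <- setdiff(unique(obs$field_code), lab_fields)
  if (length(unknown)) {
    stop_labharbor(paste0("field code(s) not in dictionary: ",
                          paste(unknown, collapse = ", ")),
                   "labharbor_schema_error")
  }
  obs <- obs[order(obs$record_id, obs$collection_date,
                   time_sort_key(obs$collection_time), obs$source_row), ]
  ev <- paste(obs$record_id, obs$collection_date,
              time_sort_key(obs$collection_time), sep = "\r")
  dupkey <- paste(ev, obs$field_code, obs$source_row, sep = "\r")
  if (anyDuplicated(dupkey)) {
    d <- dupkey[duplicated(dupkey)][1]
    vals <- unique(obs$value[dupkey == d])
    if (length(vals) > 1) {
      stop_labharbor(
        "two different values for one field at the same record, date, time and source position",
        "labharbor_integrity_error")
    }
    obs <- obs[!duplicated(dupkey), ]
    ev <- paste(obs$record_id, obs$collection_date,
                time_sort_key(obs$collection_time), sep = "\r")
  }
  # occurrence index: k-th repeat of a field within one event -> k-th sub-event
  occ <- stats::ave(seq_len(nrow(obs)), paste(ev, obs$field_code, sep = "\r"),
                    FUN = seq_along)
  subev <- paste(ev, occ, sep = "\r")
  long <- tibble(
    record_id = obs$record_id,
    subev = subev,
    sortkey = paste(obs$collection_date,
                    time_sort_key(obs$collection_time),
                    sprintf("%06d", occ), sep = "\r"),
    lab_date = format_mdy(obs$collection_date),
    lab_time = ifelse(is.na(obs$collection_time), "", obs$collection_time),
    field_code = obs$field_code,
    cell = format_value(obs$value)
  )
  wide <- tidyr::pivot_wider(long, id_cols = c("record_id", "subev", "sortkey",
                                               "lab_date", "lab_time"),
                             names_from = "field_code", values_from = "cell",
                             values_fill = "")
  wide <- wide[order(wide$record_id, wide$sortkey), ]
  inst <- stats::ave(seq_len(nrow(wide)), wide$record_id, FUN = seq_along)
  wide$redcap_repeat_instance <- as.integer(inst)
  wide$redcap_repeat_instrument <- "labs"
  for (f in setdiff(lab_fields, names(wide))) wide[[f]] <- ""
  wide[header]
}

#' Validate an import table against the dictionary
#'
#' The same field-by-field check REDCap applies at import: every
#' non-blank cell must conform to its field's validation rule (numbers
#' must be decimal numerals, dates real M/D/Y calendar dates, times
#' HH:MM), `record_id` must be nonempty, and the repeat columns must be
#' well formed. Returns the error report — an empty report means the
#' table would import cleanly; [write_import_csv()] refuses to write a
#' file whose report is nonempty unless forced.
#'
#' @param tbl An import table ([to_redcap_long()] output or a table read
#'   back with [read_import_csv()]).
#' @param dd The dictionary.
#' @return A tibble with one row per failing cell: `row`, `column`,
#'   `value`, `message`.
#' @export
validate_import <- function(tbl, dd = default_mcc_dictionary()) {
  errors <- list()
  add <- function(rows, column, values, message) {
    if (length(rows)) {
      errors[[length(errors) + 1]] <<- tibble(
        row = as.integer(rows), column = column,
        value = as.character(values), message = message)
    }
  }
  n <- nrow(tbl)
  if (!n) {
    return(tibble(row = integer(), column = character(),
                  value = character(), message = character()))
  }
  rid <- as.character(tbl$record_id)
  add(which(!nzchar(trimws(rid))), "record_id", rid[!nzchar(trimws(rid))],
      "record_id must be nonempty")
  if ("redcap_repeat_instance" %in% names(tbl)) {
    inst <- as.character(tbl$redcap_repeat_instance)
    bad <- !grepl("^[1-9]\\d*$", trimws(inst))
    add(which(bad), "redcap_repeat_instance", inst[bad],
        "repeat instance must be a positive integer")
  }
  payload <- setdiff(names(tbl), c("record_id", "redcap_repeat_instrument",
                                   "redcap_repeat_instance"))
  for (col in payload) {
    fdef <- dd_field(dd, col)
    if (is.null(fdef)) {
      add(seq_len(n), col, as.character(tbl[[col]]),
          "column is not a dictionary field")
      next
    }
    vals <- as.character(tbl[[col]])
    filled <- nzchar(trimws(vals))
    if (!any(filled)) next
    chk <- check_valid(fdef$validation, vals[filled])
    bad <- which(filled)[!chk$ok]
    add(bad, col, vals[bad], chk$message[!chk$ok][seq_along(bad)])
  }
  out <- bind_rows(errors)
  if (!nrow(out)) {
    out <- tibble(row = integer(), column = character(),
                  value = character(), message = character())
  }
  out[order(out$row, out$column), ]
}

#' Write / read a REDCap import CSV
#'
#' `write_import_csv()` validates first and refuses to emit a file with
#' a nonempty error report unless `force = TRUE` — mirroring how REDCap
#' itself fails an import that contains nonconforming data.
#'
#' @param tbl Import table.
#' @param path File path.
#' @param dd Dictionary used for validation.
#' @param force Write even when validation fails.
#' @return `write_import_csv()` invisibly returns the error report;
#'   `read_import_csv()` returns the table with all payload columns as
#'   text.
#' @export
write_import_csv <- function(tbl, path, dd = default_mcc_dictionary(),
                             force = FALSE) {
  report <- validate_import(tbl, dd = dd)
  if (nrow(report) && !force) {
    stop_labharbor(sprintf(
      "refusing to write import file: %d validation error(s); use force to override",
      nrow(report)), "labharbor_validation_error")
  }
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(report)
}

#' @rdname write_import_csv
#' @export
read_import_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  tbl[is.na(tbl)] <- ""
  if ("redcap_repeat_instance" %in% names(tbl)) {
    tbl$redcap_repeat_instance <- as.integer(tbl$redcap_repeat_instance)
  }
  tbl
}

#' Unpivot an import table back to long observations
#'
#' The inverse of [to_redcap_long()] up to the information an import
#' table carries (units are implied by the dictionary labels and not
#' restated per cell).
#'
#' @param tbl Import table.
#' @param dd Dictionary.
#' @return A tibble: `record_id`, `field_code`, `value`,
#'   `collection_date`, `collection_time`, `instance`, `source_row`.
#' @export
import_to_obs <- function(tbl, dd = default_mcc_dictionary()) {
  lab_fields <- intersect(dd_lab_fields(dd), names(tbl))
  if (!nrow(tbl)) {
    return(tibble(record_id = character(), field_code = character(),
                  value = numeric(), collection_date = as.Date(character()),
                  collection_time = character(), instance = integer(),
                  source_row = integer()))
  }
  long <- tidyr::pivot_longer(
    mutate(tbl, .row = seq_len(nrow(tbl)),
           across(all_of(lab_fields), as.character)),
    cols = all_of(lab_fields),
    names_to = "field_code", values_to = "cell")
  long <- long[nzchar(trimws(long$cell %|NA|% "")), ]
  tibble(
    record_id = as.character(long$record_id),
    field_code = long$field_code,
    value = suppressWarnings(as.numeric(long$cell)),
    collection_date = parse_flex_date(long$lab_date),
    collection_time = parse_flex_time(long$lab_time),
    instance = as.integer(long$redcap_repeat_instance),
    source_row = long$.row
  )
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Aggregate per-site import tables
#'
#' Because every site shares one dictionary, multisite aggregation is
#' row-wise concatenation of the per-site CSVs. Headers must be
#' identical and record_id sets disjoint across sites (the site prefix
#' guarantees this); row count is conserved.
#'
#' @param tables List of import tables sharing one header.
#' @return The concatenated table.
#' @export
aggregate_sites <- function(tables) {
  stopifnot(length(tables) >= 1)
  hdr <- names(tables[[1]])
  for (i in seq_along(tables)[-1]) {
    diff <- c(setdiff(hdr, names(tables[[i]])), setdiff(names(tables[[i]]), hdr))
    if (length(diff)) {
      stop_labharbor(paste0("site ", i, " header diverges on column(s): ",
                            paste(diff, collapse = ", ")),
                     "labharbor_schema_error")
    }
  }
  ids <- lapply(tables, function(t) unique(as.character(t$record_id)))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      clash <- intersect(ids[[i]], ids[[j]])
      if (length(clash)) {
        stop_labharbor(paste0("record_id present at two sites: ", clash[1]),
                       "labharbor_integrity_error")
      }
    }
  }
  bind_rows(tables)
}

#' Default LOINC annotation map
#'
#' One LOINC code per registry lab field, used only after data has been
#' cleaned, remapped and imported. These are widely used codes for the
#' common serum/blood forms of each analyte, shipped as editable
#' configuration — a registry substitutes its own curated mapping.
#'
#' @return A named character vector, field code to LOINC code.
#' @export
default_loinc_map <- function() {
  c(na = "2951-2", k = "2823-3", cl = "2075-0", co2 = "2028-9",
    bun = "3094-0", cre = "2160-0", gfr = "33914-3", glu = "2345-7",
    anion = "33037-3", alb = "1751-7", tbili = "1975-2", ca = "17861-6",
    tp = "2885-2", sgpt = "1742-6", sgot = "1920-8", alkp = "6768-6",
    glob = "10834-0", wbc = "6690-2", rbc = "789-8", hgb = "718-7",
    hct = "4544-3", mcv = "787-2", mch = "785-6", mchc = "786-4",
    plt = "777-3", mpv = "32623-1", rdw = "788-0", neut = "770-8",
    anc = "751-8", lymp = "736-9", alc = "731-0", mon = "5905-5",
    amc = "742-7", eosp = "713-8", ldh = "2532-0")
}

#' Annotate dictionary lab fields with LOINC codes
#'
#' Emits exactly one LOINC code per covered lab field for
#' interoperability with other registries. Assigning two codes to one
#' field is an integrity error; a code aimed at a field the dictionary
#' does not define is a schema error.
#'
#' @param dd The dictionary.
#' @param loinc_map Named character vector (field code to LOINC code),
#'   default [default_loinc_map()].
#' @return A tibble: `field_code`, `loinc_code`, `label` — one row per
#'   mapped field, in dictionary order.
#' @export
annotate_loinc <- function(dd = default_mcc_dictionary(),
                           loinc_map = default_loinc_map()) {
  fields <- names(loinc_map)
  if (is.null(fields) && length(loinc_map)) {
    stop_labharbor("loinc_map must be named by field code",
                   "labharbor_schema_error")
  }
  if (anyDuplicated(fields)) {
    stop_labharbor(paste0("field assigned two LOINC codes: ",
                          fields[duplicated(fields)][1]),
                   "labharbor_integrity_error")
  }
  lab_fields <- dd_lab_fields(dd)
  unknown <- setdiff(fields, lab_fields)
  if (length(unknown)) {
    stop_labharbor(paste0("LOINC code assigned to unknown field: ",
                          unknown[1]), "labharbor_schema_error")
  }
  keep <- intersect(lab_fields, fields)
  f <- dd$fields
  tibble(field_code = keep,
         loinc_code = unname(loinc_map[keep]),
         label = f$label[match(keep, f$variable_name)])
}
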
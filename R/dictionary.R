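#' REDCap data dictionaries
#'
#' A `lab_dictionary` models a REDCap project schema: an ordered set of
#' field definitions (name, form, type, validation rule, label, choices,
#' required flag) plus the set of repeating forms. The dictionary is the
#' contract every participating site shares: it fixes the field codes,
#' the units implied by their labels, and the validation REDCap applies
#' at import time, so that per-site CSVs can be aggregated by simple
#' concatenation.
#'
#' @param fields A data frame with columns `variable_name`, `form_name`,
#'   `field_type` (one of text, notes, dropdown, radio, yesno, calc),
#'   `validation` (one of none, number, date_mdy, time_hm), `label`,
#'   `choices` (character, `"code, Label | code, Label"` syntax, empty
#'   unless dropdown/radio) and `required` (logical).
#' @param repeating_forms Character vector of form names that repeat.
#' @return A `lab_dictionary` object.
#' @export
lab_dictionary <- function(fields, repeating_forms = character()) {
  fields <- as_tibble(fields)
  needed <- c("variable_name", "form_name", "field_type", "validation",
              "label", "choices", "required")
  missing <- setdiff(needed, names(fields))
  if (length(missing)) {
    stop_labharbor(paste0("dictionary fields missing column(s): ",
                          paste(missing, collapse = ", ")),
                   "labharbor_schema_error")
  }
  fields <- fields[needed]
  dd <- structure(list(fields = fields,
                       repeating_forms = unique(as.character(repeating_forms))),
                  class = "lab_dictionary")
  validate_dictionary(dd)
  dd
}

validate_dictionary <- function(dd) {
  f <- dd$fields
  if (anyDuplicated(f$variable_name)) {
    dup <- f$variable_name[duplicated(f$variable_name)][1]
    stop_labharbor(paste0("duplicate variable name: ", dup),
                   "labharbor_integrity_error")
  }
  bad_type <- setdiff(unique(f$field_type),
                      c("text", "notes", "dropdown", "radio", "yesno", "calc"))
  if (length(bad_type)) {
    stop_labharbor(paste0("unknown field type: ", bad_type[1]),
                   "labharbor_schema_error")
  }
  bad_val <- setdiff(unique(f$validation),
                     c("none", "number", "date_mdy", "time_hm"))
  if (length(bad_val)) {
    stop_labharbor(paste0("unknown validation rule: ", bad_val[1]),
                   "labharbor_schema_error")
  }
  if (any(f$validation == "number" & f$field_type != "text")) {
    stop_labharbor("number validation requires a text field",
                   "labharbor_schema_error")
  }
  needs_choices <- f$field_type %in% c("dropdown", "radio")
  if (any(needs_choices & !nzchar(f$choices))) {
    stop_labharbor("dropdown/radio fields need choices",
                   "labharbor_schema_error")
  }
  if (any(!needs_choices & nzchar(f$choices))) {
    stop_labharbor("choices only allowed on dropdown/radio fields",
                   "labharbor_schema_error")
  }
  invisible(dd)
}

#' @export
print.lab_dictionary <- function(x, ...) {
  cat("<lab_dictionary> ", nrow(x$fields), " fields on ",
      length(unique(x$fields$form_name)), " form(s); repeating: ",
      paste(x$repeating_forms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.lab_dictionary <- function(x, ...) {
  paste0("<lab_dictionary: ", nrow(x$fields), " fields>")
}

# The 35 registry lab analytes: code, human label, canonical unit and the
# Table-1-style panel each belongs to. This is the packaged default schema
# (a demo fixture a registry would replace with its own DD), not a clinical
# reference.
lab_field_table <- function() {
  tribble(
    ~field_code, ~label, ~unit, ~panel,
    "na",    "Sodium",                                  "mmol/L", "electrolytes_renal_glucose",
    "k",     "Potassium",                               "mmol/L", "electrolytes_renal_glucose",
    "cl",    "Chloride",                                "mmol/L", "electrolytes_renal_glucose",
    "co2",   "Carbon dioxide",                          "mmol/L", "electrolytes_renal_glucose",
    "bun",   "Blood urea nitrogen",                     "mg/dL",  "electrolytes_renal_glucose",
    "cre",   "Creatinine",                              "mg/dL",  "electrolytes_renal_glucose",
    "gfr",   "Estimated glomerular filtration rate",    "mL/min/1.73m2", "electrolytes_renal_glucose",
    "glu",   "Blood glucose",                           "mg/dL",  "electrolytes_renal_glucose",
    "anion", "Anion gap",                               "mmol/L", "electrolytes_renal_glucose",
    "alb",   "Albumin",                                 "g/dL",   "general_chemistries",
    "tbili", "Total bilirubin",                         "mg/dL",  "general_chemistries",
    "ca",    "Calcium",                                 "mg/dL",  "general_chemistries",
    "tp",    "Total protein",                           "g/dL",   "general_chemistries",
    "sgpt",  "Alanine aminotransferase",                "U/L",    "liver_function",
    "sgot",  "Aspartate aminotransferase",              "U/L",    "liver_function",
    "alkp",  "Alkaline phosphatase",                    "U/L",    "liver_function",
    "glob",  "Globulin",                                "g/dL",   "liver_function",
    "wbc",   "White blood cells",                       "K/uL",   "hematological",
    "rbc",   "Red blood cells",                         "M/uL",   "hematological",
    "hgb",   "Hemoglobin",                              "g/dL",   "hematological",
    "hct",   "Hematocrit",                              "%",      "hematological",
    "mcv",   "Mean corpuscular volume",                 "fL",     "hematological",
    "mch",   "Mean corpuscular hemoglobin",             "pg",     "hematological",
    "mchc",  "Mean corpuscular hemoglobin conc.",       "g/dL",   "hematological",
    "plt",   "Platelet count",                          "K/uL",   "hematological",
    "mpv",   "Mean platelet volume",                    "fL",     "hematological",
    "rdw",   "Red cell distribution width",             "%",      "hematological",
    "neut",  "Percent neutrophils",                     "%",      "hematological",
    "anc",   "Absolute neutrophil count",               "K/uL",   "hematological",
    "lymp",  "Percent lymphocytes",                     "%",      "hematological",
    "alc",   "Absolute lymphocyte count",               "K/uL",   "hematological",
    "mon",   "Percent monocytes",                       "%",      "hematological",
    "amc",   "Absolute monocyte count",                 "K/uL",   "hematological",
    "eosp",  "Percent eosinophils",                     "%",      "hematological",
    "ldh",   "Lactate dehydrogenase",                   "U/L",    "hematological"
  )
}

#' Packaged registry data dictionary
#'
#' Builds the default registry dictionary: a repeating `labs` instrument
#' with 35 number-validated lab value fields plus one shared collection
#' date (`lab_date`, M/D/Y) and time (`lab_time`, HH:MM) per instance,
#' and the non-repeating `patient_characteristics` (diagnosis date) and
#' `subject_status` (death / last follow-up dates) instruments consumed
#' by the survival stage. One labs instance corresponds to one
#' blood-draw event, so the same lab captured twice on the same day
#' lands in two instances.
#'
#' @return A [lab_dictionary()].
#' @examples
#' dd <- default_mcc_dictionary()
#' length(dd_lab_fields(dd))
#' @export
default_mcc_dictionary <- function() {
  labs <- lab_field_table()
  fields <- bind_rows(
    tibble(variable_name = "record_id", form_name = "patient_characteristics",
           field_type = "text", validation = "none",
           label = "Record ID", choices = "", required = TRUE),
    tibble(variable_name = "diagnosis_date", form_name = "patient_characteristics",
           field_type = "text", validation = "date_mdy",
           label = "Date of diagnosis", choices = "", required = FALSE),
    tibble(variable_name = "death_date", form_name = "subject_status",
           field_type = "text", validation = "date_mdy",
           label = "Date of death", choices = "", required = FALSE),
    tibble(variable_name = "last_followup_date", form_name = "subject_status",
           field_type = "text", validation = "date_mdy",
           label = "Date of last follow-up", choices = "", required = FALSE),
    tibble(variable_name = "lab_date", form_name = "labs",
           field_type = "text", validation = "date_mdy",
           label = "Lab collection date", choices = "", required = FALSE),
    tibble(variable_name = "lab_time", form_name = "labs",
           field_type = "text", validation = "time_hm",
           label = "Lab collection time", choices = "", required = FALSE),
    tibble(variable_name = labs$field_code, form_name = "labs",
           field_type = "text", validation = "number",
           label = paste0(labs$label, " (", labs$unit, ")"),
           choices = "", required = FALSE)
  )
  lab_dictionary(fields, repeating_forms = "labs")
}

#' Lab value fields of a dictionary
#'
#' The variable names on the repeating labs form that carry measured
#' values, i.e. excluding the shared collection date/time fields.
#'
#' @param dd A [lab_dictionary()].
#' @param form Name of the labs form.
#' @return Character vector of field codes, in dictionary order.
#' @export
dd_lab_fields <- function(dd, form = "labs") {
  f <- dd$fields
  setdiff(f$variable_name[f$form_name == form & f$validation == "number"],
          c("lab_date", "lab_time"))
}

dd_field <- function(dd, variable_name) {
  i <- match(variable_name, dd$fields$variable_name)
  if (is.na(i)) return(NULL)
  as.list(dd$fields[i, ])
}

# ---- REDCap DD CSV dialect -------------------------------------------------

redcap_dd_header <- c(
  "Variable / Field Name", "Form Name", "Section Header", "Field Type",
  "Field Label", "Choices, Calculations, OR Slider Labels", "Field Note",
  "Text Validation Type OR Show Slider Number", "Text Validation Min",
  "Text Validation Max", "Identifier?",
  "Branching Logic (Show field only if...)", "Required Field?",
  "Custom Alignment", "Question Number (surveys only)", "Matrix Group Name",
  "Matrix Ranking?", "Field Annotation")

#' Read / write a REDCap data-dictionary CSV
#'
#' `write_dd_csv()` emits the standard REDCap data-dictionary CSV column
#' set in a stable order; `read_dd_csv()` parses it back. The pair
#' round-trips: `read_dd_csv(write_dd_csv(dd))` equals `dd`. Because the
#' stock REDCap DD CSV does not record which instruments repeat (that is
#' project configuration), the writer marks the first field of each
#' repeating form with `@REPEATING` in the Field Annotation column and
#' the reader recovers the set from there.
#'
#' @param path File path (or, for `write_dd_csv`, `NULL` to return the
#'   CSV text invisibly written nowhere).
#' @param dd A [lab_dictionary()].
#' @return `read_dd_csv()` returns a [lab_dictionary()]; `write_dd_csv()`
#'   returns the CSV text as a character scalar, invisibly when `path`
#'   is given.
#' @export
read_dd_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tab[is.na(tab)] <- ""
  mandatory <- c("Variable / Field Name", "Form Name", "Field Type")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing)) {
    stop_labharbor(paste0("data dictionary CSV is missing column(s): ",
                          paste(missing, collapse = ", ")),
                   "labharbor_schema_error")
  }
  if (anyDuplicated(tab$`Variable / Field Name`)) {
    dup <- tab$`Variable / Field Name`[duplicated(tab$`Variable / Field Name`)][1]
    stop_labharbor(paste0("duplicate variable name in dictionary CSV: ", dup),
                   "labharbor_integrity_error")
  }
  validation <- tab[["Text Validation Type OR Show Slider Number"]]
  if (is.null(validation)) validation <- rep("", nrow(tab))
  validation[validation == ""] <- "none"
  annotation <- tab[["Field Annotation"]]
  if (is.null(annotation)) annotation <- rep("", nrow(tab))
  required <- tab[["Required Field?"]]
  if (is.null(required)) required <- rep("", nrow(tab))
  choices <- tab[["Choices, Calculations, OR Slider Labels"]]
  if (is.null(choices)) choices <- rep("", nrow(tab))
  label <- tab[["Field Label"]]
  if (is.null(label)) label <- rep("", nrow(tab))
  fields <- tibble(
    variable_name = tab$`Variable / Field Name`,
    form_name = tab$`Form Name`,
    field_type = tab$`Field Type`,
    validation = validation,
    label = label,
    choices = choices,
    required = required == "y"
  )
  repeating <- unique(fields$form_name[grepl("@REPEATING", annotation, fixed = TRUE)])
  lab_dictionary(fields, repeating_forms = repeating)
}

#' @rdname read_dd_csv
#' @export
write_dd_csv <- function(dd, path = NULL) {
  validate_dictionary(dd)
  f <- dd$fields
  first_of_form <- !duplicated(f$form_name)
  annotation <- ifelse(first_of_form & f$form_name %in% dd$repeating_forms,
                       "@REPEATING", "")
  out <- tibble(
    `Variable / Field Name` = f$variable_name,
    `Form Name` = f$form_name,
    `Section Header` = "",
    `Field Type` = f$field_type,
    `Field Label` = f$label,
    `Choices, Calculations, OR Slider Labels` = f$choices,
    `Field Note` = "",
    `Text Validation Type OR Show Slider Number` =
      ifelse(f$validation == "none", "", f$validation),
    `Text Validation Min` = "",
    `Text Validation Max` = "",
    `Identifier?` = "",
    `Branching Logic (Show field only if...)` = "",
    `Required Field?` = ifelse(f$required, "y", ""),
    `Custom Alignment` = "",
    `Question Number (surveys only)` = "",
    `Matrix Group Name` = "",
    `Matrix Ranking?` = "",
    `Field Annotation` = annotation
  )
  txt <- readr::format_csv(out)
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

# ---- field-level validation ------------------------------------------------

# Vectorized rule check; the grammar for "number" is a plain decimal
# numeral: optional sign, digits, optional decimal point. No exponent,
# no thousands separators, no comparator prefixes ("<0.01" fails), no
# words — that is exactly what REDCap number validation accepts, and it
# is what turns "refused"/"canceled" tokens into itemized exclusions.
check_valid <- function(validation, raw) {
  raw <- trimws(as.character(raw))
  n <- length(raw)
  ok <- rep(TRUE, n)
  msg <- rep("", n)
  if (validation == "number") {
    ok <- grepl("^[+-]?(\\d+(\\.\\d*)?|\\.\\d+)$", raw)
    msg[!ok] <- "not a number"
  } else if (validation == "date_mdy") {
    shape <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", raw)
    real <- rep(FALSE, n)
    if (any(shape)) {
      real[shape] <- !is.na(as.Date(raw[shape], format = "%m/%d/%Y"))
    }
    ok <- shape & real
    msg[!ok] <- "not a valid M/D/Y date"
  } else if (validation == "time_hm") {
    ok <- grepl("^([01]?\\d|2[0-3]):[0-5]\\d$", raw)
    msg[!ok] <- "not a valid HH:MM time"
  }
  list(ok = ok, message = msg)
}

#' Validate one raw value against a field definition
#'
#' Applies the field's validation rule (after stripping surrounding
#' whitespace, since EHR exports pad cells) and returns a result record
#' rather than throwing: failed validation is data, not an exception.
#' A `number` field accepts exactly decimal numerals, so tokens such as
#' `"refused"` or `"canceled"` fail; a `date_mdy` field requires a real
#' calendar date in M/D/Y.
#'
#' @param field A field definition: one row of `dd$fields` (data frame
#'   or list) with at least `variable_name` and `validation`.
#' @param raw The raw value, as text.
#' @return A list of class `validation_result` with elements `ok`,
#'   `field`, `raw_value`, `message` (empty iff `ok`).
#' @examples
#' dd <- default_mcc_dictionary()
#' k <- dd$fields[dd$fields$variable_name == "k", ]
#' validate_value(k, "4.0")$ok      # TRUE
#' validate_value(k, "refused")$ok  # FALSE
#' @export
validate_value <- function(field, raw) {
  field <- as.list(field)
  res <- check_valid(field$validation %||% "none", raw)
  structure(list(ok = res$ok[1],
                 field = field$variable_name %||% "",
                 raw_value = as.character(raw),
                 message = res$message[1]),
            class = "validation_result")
}
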
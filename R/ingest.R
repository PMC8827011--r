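#' Panel grammar for untidy EHR exports
#'
#' The untidy export packs an entire lab panel into one cell. The default
#' grammar splits the cell on `";"` and reads each token as
#' `NAME VALUE [UNIT]`: the value is the last whitespace-separated word
#' that parses as a decimal numeral (or one of the recognized value words
#' such as `"refused"`/`"canceled"`, which must survive to the cleaning
#' stage so they can be itemized); everything before it is the source
#' test name, everything after it the unit. Tokens that fit neither shape
#' are routed to a reject list, never dropped. Sites whose exports use a
#' different intra-cell syntax override these pieces.
#'
#' @param sep Intra-cell separator between panel entries.
#' @param value_words Non-numeric tokens recognized as values (they fail
#'   number validation later and become itemized exclusions).
#' @return A list of class `panel_grammar`.
#' @export
default_panel_grammar <- function(sep = ";", value_words = c("refused", "canceled")) {
  structure(list(sep = sep, value_words = tolower(value_words)),
            class = "panel_grammar")
}

#' Parse an untidy 4-column EHR export
#'
#' Reads the nontabular EHR lab export: exactly four columns — patient
#' name/MRN, collection date, collection time, and a free-text cell
#' holding one or more lab results. Any line with a different column
#' count is a format error naming the offending line; this keeps a
#' shifted or truncated export from silently mangling the panel cell.
#'
#' @param path Path to the delimited file (or a character vector of
#'   lines).
#' @param delim Field delimiter, default comma.
#' @param header Whether the first line is a header to skip.
#' @return A tibble of raw EHR rows: `patient_key`, `collection_date`,
#'   `collection_time`, `panel_text`, `source_row` (1-based data line).
#' @export
parse_ehr_export <- function(path, delim = ",", header = TRUE) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(patient_key = character(), collection_date = as.Date(character()),
                  collection_time = character(), panel_text = character(),
                  source_row = integer()))
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  nc <- lengths(cells)
  # a trailing empty panel cell drops the 4th element in strsplit
  trailing <- nc == 3 & endsWith(lines, delim)
  cells[trailing] <- lapply(cells[trailing], function(x) c(x, ""))
  nc <- lengths(cells)
  bad <- which(nc != 4)
  if (length(bad)) {
    stop_labharbor(sprintf("expected 4 columns but found %d on line %d",
                           nc[bad[1]], bad[1]),
                   "labharbor_format_error")
  }
  m <- do.call(rbind, cells)
  tibble(
    patient_key = trimws(m[, 1]),
    collection_date = parse_flex_date(m[, 2]),
    collection_time = parse_flex_time(m[, 3]),
    panel_text = trimws(m[, 4]),
    source_row = seq_along(lines)
  )
}

# Parse one panel token under the grammar; NULL when unrecognizable.
parse_panel_token <- function(token, grammar) {
  words <- strsplit(trimws(token), "\\s+")[[1]]
  if (length(words) < 2) return(NULL)
  numeric_word <- grepl("^[+-]?(\\d+(\\.\\d*)?|\\.\\d+)$", words)
  value_word <- tolower(words) %in% grammar$value_words
  cand <- which(numeric_word | value_word)
  cand <- cand[cand > 1]           # the name must be nonempty
  if (!length(cand)) return(NULL)
  vi <- max(cand)
  list(name = paste(words[seq_len(vi - 1)], collapse = " "),
       value = words[vi],
       unit = if (vi < length(words)) paste(words[(vi + 1):length(words)], collapse = " ") else "")
}

#' Explode panel cells into per-result observations
#'
#' Splits each raw row's panel cell under the grammar and yields one raw
#' observation per recognized token, preserving order. Unrecognized
#' tokens are returned as rejects with their source row: records are
#' conserved — every candidate token ends up either an observation or a
#' reject.
#'
#' @param rows Output of [parse_ehr_export()].
#' @param grammar A [default_panel_grammar()].
#' @return A list with `observations` (tibble: `patient_key`,
#'   `collection_date`, `collection_time`, `source_test_name`,
#'   `raw_value`, `raw_unit`, `source_row`) and `rejects` (tibble:
#'   `source_row`, `token`, `reason`).
#' @examples
#' rows <- tibble::tibble(patient_key = "MRN1", collection_date = as.Date("2020-05-01"),
#'   collection_time = "08:00", panel_text = "Sodium 140 mmol/L; Potassium 4.0 mmol/L",
#'   source_row = 1L)
#' explode_panels(rows)$observations
#' @export
explode_panels <- function(rows, grammar = default_panel_grammar()) {
  obs <- vector("list", nrow(rows))
  rej <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    cell <- rows$panel_text[i]
    if (!nzchar(trimws(cell))) next
    tokens <- trimws(strsplit(cell, grammar$sep, fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    parsed <- lapply(tokens, parse_panel_token, grammar = grammar)
    ok <- !vapply(parsed, is.null, logical(1))
    if (any(ok)) {
      p <- parsed[ok]
      obs[[i]] <- tibble(
        patient_key = rows$patient_key[i],
        collection_date = rows$collection_date[i],
        collection_time = rows$collection_time[i],
        source_test_name = vapply(p, `[[`, character(1), "name"),
        raw_value = vapply(p, `[[`, character(1), "value"),
        raw_unit = vapply(p, `[[`, character(1), "unit"),
        source_row = rows$source_row[i]
      )
    }
    if (any(!ok)) {
      rej[[i]] <- tibble(source_row = rows$source_row[i],
                         token = tokens[!ok],
                         reason = "unrecognized_token")
    }
  }
  observations <- bind_rows(obs)
  if (!nrow(observations)) observations <- empty_raw_obs()
  rejects <- bind_rows(rej)
  if (!nrow(rejects)) {
    rejects <- tibble(source_row = integer(), token = character(),
                      reason = character())
  }
  list(observations = observations, rejects = rejects)
}

empty_raw_obs <- function() {
  tibble(patient_key = character(), collection_date = as.Date(character()),
         collection_time = character(), source_test_name = character(),
         raw_value = character(), raw_unit = character(), source_row = integer())
}

#' Column mapping for tabular EDW exports
#'
#' Data-warehouse pulls (e.g. Clarity/Crystal reports or an institutional
#' research patient data repository) arrive one result per row. The
#' column map names which input columns hold each piece.
#'
#' @param mrn,date,time,test,value,unit Input column names.
#' @return A named list of class `edw_colmap`.
#' @export
default_edw_colmap <- function(mrn = "MRN", date = "Collection_Date",
                               time = "Collection_Time", test = "Test_Name",
                               value = "Result", unit = "Units") {
  structure(list(mrn = mrn, date = date, time = time,
                 test = test, value = value, unit = unit),
            class = "edw_colmap")
}

#' Parse a tabular EDW export
#'
#' One raw observation per input row. Rows with an empty test name are
#' rejected with provenance rather than dropped.
#'
#' @param path Path to a delimited file (or a data frame already read).
#' @param colmap A [default_edw_colmap()]; referencing a column absent
#'   from the input is a configuration error.
#' @param delim Field delimiter.
#' @return A list with `observations` and `rejects`, as in
#'   [explode_panels()].
#' @export
parse_edw_export <- function(path, colmap = default_edw_colmap(), delim = ",") {
  tab <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_delim(path, delim = delim, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
  }
  tab[] <- lapply(tab, as.character)
  missing <- setdiff(unlist(colmap), names(tab))
  if (length(missing)) {
    stop_labharbor(paste0("column map references absent column(s): ",
                          paste(missing, collapse = ", ")),
                   "labharbor_config_error")
  }
  tab[is.na(tab)] <- ""
  obs <- tibble(
    patient_key = trimws(tab[[colmap$mrn]]),
    collection_date = parse_flex_date(tab[[colmap$date]]),
    collection_time = parse_flex_time(tab[[colmap$time]]),
    source_test_name = trimws(tab[[colmap$test]]),
    raw_value = trimws(tab[[colmap$value]]),
    raw_unit = trimws(tab[[colmap$unit]]),
    source_row = seq_len(nrow(tab))
  )
  bad <- !nzchar(obs$source_test_name)
  list(observations = obs[!bad, ],
       rejects = tibble(source_row = obs$source_row[bad],
                        token = obs$raw_value[bad],
                        reason = rep("empty_test_name", sum(bad))))
}
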
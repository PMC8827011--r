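#' Derive overall survival from registry instruments
#'
#' Overall survival is the time from diagnosis to death, censored at
#' the last follow-up visit when no death occurred. Inputs are the two
#' non-repeating registry instruments: subject status (death date, last
#' follow-up date) and patient characteristics (diagnosis date).
#' Subjects without a diagnosis date are excluded with a logged reason
#' (see `attr(, "excluded")`); a death before diagnosis is a data error
#' naming the record.
#'
#' @param status Data frame: `record_id`, `death_date` (Date or
#'   M/D/Y / ISO text, `NA` if alive), `last_followup_date`.
#' @param chars Data frame: `record_id`, `diagnosis_date`.
#' @return A tibble: `record_id`, `time_days` (whole days), `event`
#'   (TRUE iff died), with excluded record ids in `attr(, "excluded")`.
#' @examples
#' status <- tibble::tibble(record_id = "A-0001",
#'   death_date = as.Date("2020-12-31"), last_followup_date = as.Date("2020-12-31"))
#' chars <- tibble::tibble(record_id = "A-0001", diagnosis_date = as.Date("2020-01-01"))
#' derive_os(status, chars)$time_days  # 365
#' @export
derive_os <- function(status, chars) {
  status <- as_tibble(status)
  chars <- as_tibble(chars)
  to_date <- function(x) if (inherits(x, "Date")) x else parse_flex_date(x)
  status$death_date <- to_date(status$death_date)
  status$last_followup_date <- to_date(status$last_followup_date)
  chars$diagnosis_date <- to_date(chars$diagnosis_date)
  if (anyDuplicated(chars$record_id)) {
    stop_labharbor("multiple characteristics rows for one record_id",
                   "labharbor_integrity_error")
  }
  m <- left_join(status, chars[c("record_id", "diagnosis_date")],
                 by = "record_id")
  no_dx <- is.na(m$diagnosis_date)
  excluded <- tibble(record_id = m$record_id[no_dx],
                     reason = rep("missing_diagnosis_date", sum(no_dx)))
  m <- m[!no_dx, ]
  bad <- !is.na(m$death_date) & m$death_date < m$diagnosis_date
  if (any(bad)) {
    stop_labharbor(paste0("death precedes diagnosis for record_id ",
                          m$record_id[bad][1]), "labharbor_data_error")
  }
  event <- !is.na(m$death_date)
  end <- dplyr::if_else(event, m$death_date, m$last_followup_date)
  out <- tibble(record_id = m$record_id,
                time_days = as.integer(end - m$diagnosis_date),
                event = event)
  attr(out, "excluded") <- excluded
  out
}

#' Select each subject's baseline value per lab
#'
#' With the date of diagnosis set as baseline, selects for every
#' subject and lab field the single value collected nearest the
#' diagnosis date within the window (default 90 days before to 30 days
#' after). Ties in distance break toward the earlier draw. Subjects
#' with no in-window value for a lab are simply absent for that lab
#' (complete-case per lab).
#'
#' @param obs Long observations (e.g. [import_to_obs()] output or
#'   ground-truth observations): `record_id`, `field_code`, `value`,
#'   `collection_date`.
#' @param chars Patient characteristics with `record_id`,
#'   `diagnosis_date`.
#' @param window Integer pair `c(days_before, days_after)` as offsets
#'   relative to diagnosis, default `c(-90, 30)`.
#' @return A tibble: `record_id`, `field_code`, `value`, `delta_days`.
#' @export
baseline_labs <- function(obs, chars, window = c(-90, 30)) {
  chars <- as_tibble(chars)
  if (!inherits(chars$diagnosis_date, "Date")) {
    chars$diagnosis_date <- parse_flex_date(chars$diagnosis_date)
  }
  m <- inner_join(as_tibble(obs), chars[c("record_id", "diagnosis_date")],
                  by = "record_id")
  m$delta_days <- as.integer(m$collection_date - m$diagnosis_date)
  m <- m[!is.na(m$delta_days) &
           m$delta_days >= window[1] & m$delta_days <= window[2], ]
  if (!nrow(m)) {
    return(tibble(record_id = character(), field_code = character(),
                  value = numeric(), delta_days = integer()))
  }
  m <- m[order(m$record_id, m$field_code, abs(m$delta_days), m$delta_days), ]
  m <- m[!duplicated(paste(m$record_id, m$field_code, sep = "\r")), ]
  m[c("record_id", "field_code", "value", "delta_days")]
}

#' Univariable Cox screen over baseline labs
#'
#' The outcomes stage: joins each lab's baseline values with overall
#' survival and fits one univariable Cox model per lab field, on the
#' lab's original units (per-unit hazard ratios, no standardization).
#' Results are grouped and ordered by the four registry panels
#' (electrolytes/renal/glucose, general chemistries, liver function,
#' hematological). P-values are raw: this is a hypothesis-generating
#' screen, so no multiplicity correction is applied by default;
#' `p_adjust` passes a method name through to [stats::p.adjust()] for
#' sites that want one.
#'
#' @param obs Long lab observations (see [baseline_labs()]).
#' @param status,chars Registry instruments (see [derive_os()]).
#' @param window Baseline window, see [baseline_labs()].
#' @param min_n Minimum usable subjects for a lab to be fit.
#' @param p_adjust `NULL` (default, raw p-values) or a
#'   [stats::p.adjust()] method name.
#' @return A tibble with one row per fitted lab: `panel`, `field_code`,
#'   `label`, `n_used`, `n_events`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `converged`.
#' @export
baselabs_os_table <- function(obs, status, chars, window = c(-90, 30),
                              min_n = 10, p_adjust = NULL) {
  surv <- derive_os(status, chars)
  if (!nrow(surv) || !any(surv$event)) {
    warning("no events in cohort: returning empty results table", call. = FALSE)
    return(tibble(panel = character(), field_code = character(),
                  label = character(), n_used = integer(),
                  n_events = integer(), hazard_ratio = numeric(),
                  ci_low = numeric(), ci_high = numeric(),
                  p_value = numeric(), converged = logical()))
  }
  base <- baseline_labs(obs, chars, window = window)
  fieldtab <- lab_field_table()
  rows <- list()
  for (i in seq_len(nrow(fieldtab))) {
    fc <- fieldtab$field_code[i]
    b <- base[base$field_code == fc, ]
    d <- inner_join(b, surv, by = "record_id")
    d <- d[d$time_days > 0, ]
    if (nrow(d) < min_n || sum(d$event) < 2 || length(unique(d$value)) < 2) next
    fit <- tryCatch(
      suppressWarnings(fit_univariable_cox(d$value, d$time_days, d$event)),
      labharbor_degenerate_fit = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- tibble(
      panel = fieldtab$panel[i], field_code = fc,
      label = fieldtab$label[i], n_used = fit$n_used,
      n_events = fit$n_events, hazard_ratio = fit$hazard_ratio,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      p_value = fit$p_value, converged = fit$converged)
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    warning("no lab reached the minimum usable-subject count", call. = FALSE)
    return(tibble(panel = character(), field_code = character(),
                  label = character(), n_used = integer(),
                  n_events = integer(), hazard_ratio = numeric(),
                  ci_low = numeric(), ci_high = numeric(),
                  p_value = numeric(), converged = logical()))
  }
  if (!is.null(p_adjust)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}

#' Render the screen results as a plain-text table
#'
#' A compact per-panel render of the univariable screen — laboratory
#' test, hazard ratio with 95% CI, and p-value — suitable for a report
#' or terminal.
#'
#' @param results Output of [baselabs_os_table()].
#' @return Character vector of lines, invisibly also printed via `cat`
#'   when `print = TRUE`.
#' @param print Print to the console?
#' @export
render_os_table <- function(results, print = FALSE) {
  panel_titles <- c(electrolytes_renal_glucose = "Electrolytes/renal/glucose",
                    general_chemistries = "General chemistries",
                    liver_function = "Liver function tests",
                    hematological = "Hematological studies")
  lines <- c(sprintf("%-42s %-24s %s", "Laboratory tests",
                     "Hazard ratio (95% CI)", "P value"))
  for (p in unique(results$panel)) {
    lines <- c(lines, panel_titles[[p]])
    sub <- results[results$panel == p, ]
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf(
        "%-42s %-24s %.3g%s",
        paste0(sub$label[i], " (", sub$field_code[i], ")"),
        sprintf("%.4f (%.3g-%.3g)", sub$hazard_ratio[i],
                sub$ci_low[i], sub$ci_high[i]),
        sub$p_value[i],
        if (sub$converged[i]) "" else " [flagged]"))
    }
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' Read the survival instruments from CSV
#'
#' @param path CSV path. Subject status has columns `record_id`,
#'   `death_date` (blank if alive), `last_followup_date`; patient
#'   characteristics has `record_id`, `diagnosis_date`. Dates may be
#'   M/D/Y or ISO.
#' @return A tibble with parsed dates.
#' @export
read_status_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  tibble(record_id = tab$record_id,
         death_date = parse_flex_date(tab$death_date),
         last_followup_date = parse_flex_date(tab$last_followup_date))
}

#' @rdname read_status_csv
#' @export
read_chars_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  tibble(record_id = tab$record_id,
         diagnosis_date = parse_flex_date(tab$diagnosis_date))
}
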
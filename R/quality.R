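#' Compare manually abstracted and automated datasets
#'
#' The data-quality assessment: two datasets of lab observations are
#' matched on `(record_id, field_code, collection_date, collection_time,
#' occurrence)` and every key is compared — no sampling. Values agree
#' when numerically equal (so `"5.0"` and `"5.00"` agree) or within the
#' relative tolerance. A key present in only one dataset is a
#' discrepancy of a distinct kind and counts in the denominator — the
#' conservative choice.
#'
#' @param manual,automated Data frames of observations with at least
#'   `record_id`, `field_code`, `collection_date`, `value`
#'   (`collection_time` optional).
#' @param tolerance Relative tolerance; 0 (default) means exact after
#'   numeric normalization.
#' @return A list of class `agreement_report`: `n_compared`, `n_agree`,
#'   `agreement_pct` (= 100 * n_agree / n_compared), and `discrepancies`
#'   — a tibble with `record_id`, `field_code`, `collection_date`,
#'   `manual_value`, `automated_value`, `kind` (one of
#'   `value_mismatch`, `missing_in_manual`, `missing_in_automated`).
#' @examples
#' x <- tibble::tibble(record_id = "A-1", field_code = "k",
#'   collection_date = as.Date("2020-05-01"), value = 4.0)
#' compare_datasets(x, x)$agreement_pct  # 100
#' @export
compare_datasets <- function(manual, automated, tolerance = 0) {
  keyed <- function(d) {
    d <- as_tibble(d)
    if (!"collection_time" %in% names(d)) d$collection_time <- NA_character_
    base <- paste(d$record_id, d$field_code, d$collection_date,
                  time_sort_key(d$collection_time), sep = "\r")
    ord <- order(base)
    d <- d[ord, ]
    base <- base[ord]
    occ <- stats::ave(seq_along(base), base, FUN = seq_along)
    d$.key <- paste(base, occ, sep = "\r")
    d$.value <- suppressWarnings(as.numeric(d$value))
    d
  }
  m <- keyed(manual)
  a <- keyed(automated)
  all_keys <- union(m$.key, a$.key)
  mi <- match(all_keys, m$.key)
  ai <- match(all_keys, a$.key)
  mv <- m$.value[mi]
  av <- a$.value[ai]
  in_m <- !is.na(mi)
  in_a <- !is.na(ai)
  agree_val <- in_m & in_a &
    ((is.na(mv) & is.na(av)) |
       (!is.na(mv) & !is.na(av) &
          (mv == av | abs(mv - av) <= tolerance * pmax(abs(mv), abs(av)))))
  kind <- rep(NA_character_, length(all_keys))
  kind[in_m & in_a & !agree_val] <- "value_mismatch"
  kind[in_m & !in_a] <- "missing_in_automated"
  kind[!in_m & in_a] <- "missing_in_manual"
  disc_i <- which(!is.na(kind))
  src <- ifelse(in_m, mi, NA)
  parts <- function(d, idx) d[idx, c("record_id", "field_code", "collection_date")]
  ref <- m[0, c("record_id", "field_code", "collection_date")]
  disc <- bind_rows(lapply(disc_i, function(i) {
    d <- if (in_m[i]) parts(m, mi[i]) else parts(a, ai[i])
    d
  }))
  if (!nrow(disc)) disc <- ref
  discrepancies <- bind_cols(disc, tibble(
    manual_value = mv[disc_i], automated_value = av[disc_i],
    kind = kind[disc_i]))
  n_compared <- length(all_keys)
  n_agree <- sum(agree_val)
  structure(list(
    n_compared = n_compared,
    n_agree = n_agree,
    agreement_pct = if (n_compared) 100 * n_agree / n_compared else NA_real_,
    discrepancies = discrepancies), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement: %d/%d values (%.1f%%); %d discrepancies\n",
              x$n_agree, x$n_compared, x$agreement_pct,
              nrow(x$discrepancies)))
  invisible(x)
}

#' Abstraction throughput
#'
#' Values abstracted per minute, to one decimal, from already-measured
#' totals (e.g. REDCap start/stop timestamps around manual abstraction
#' sessions).
#'
#' @param n_values Number of lab values abstracted.
#' @param total_minutes Total minutes spent; must be positive.
#' @return A list of class `throughput_report`: `n_values`,
#'   `total_minutes`, `values_per_minute`.
#' @examples
#' throughput_report(8043, 1458.4)$values_per_minute  # 5.5
#' @export
throughput_report <- function(n_values, total_minutes) {
  if (!is.numeric(total_minutes) || length(total_minutes) != 1 ||
      !is.finite(total_minutes) || total_minutes <= 0) {
    stop_labharbor("total_minutes must be a positive number",
                   "labharbor_argument_error")
  }
  if (!is.numeric(n_values) || length(n_values) != 1 || n_values < 0) {
    stop_labharbor("n_values must be a nonnegative count",
                   "labharbor_argument_error")
  }
  structure(list(n_values = as.integer(n_values),
                 total_minutes = as.numeric(total_minutes),
                 values_per_minute = round(n_values / total_minutes, 1)),
            class = "throughput_report")
}

#' @export
print.throughput_report <- function(x, ...) {
  cat(sprintf("%d values in %.1f minutes: %.1f values/minute\n",
              x$n_values, x$total_minutes, x$values_per_minute))
  invisible(x)
}
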
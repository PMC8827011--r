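# Internal helpers shared across modules.

# Normalize a source test name for lookup: trim, collapse internal
# whitespace, case-fold. No fuzzy matching anywhere downstream.
normalize_test_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Render a numeric lab value for CSV payloads. Never scientific notation
# (REDCap number validation would reject "1e-04").
format_value <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

# M/D/Y rendering without zero padding, the dialect REDCap date_mdy accepts.
format_mdy <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  dd <- as.POSIXlt(d[ok])
  out[ok] <- paste(dd$mon + 1L, dd$mday, dd$year + 1900L, sep = "/")
  out
}

# Parse dates accepting M/D/Y and ISO Y-M-D; anything else (including
# two-digit years) is NA. Failing loudly at the PHI boundary beats a
# silently swapped day/month.
parse_flex_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)
  mdy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  if (any(iso)) out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  if (any(mdy)) out[mdy] <- as.Date(x[mdy], format = "%m/%d/%Y")
  out
}

# Clock time "HH:MM"; empty/NA allowed (untimed draw).
parse_flex_time <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^([01]?\\d|2[0-3]):[0-5]\\d$", x)
  out <- rep(NA_character_, length(x))
  # zero-pad the hour so lexicographic order is chronological
  hh <- sub(":.*$", "", x[ok])
  mm <- sub("^.*:", "", x[ok])
  out[ok] <- sprintf("%02d:%s", as.integer(hh), mm)
  out
}

# Sort key for possibly-missing times: absent sorts before any timed draw.
time_sort_key <- function(x) ifelse(is.na(x), "", x)

# Evaluate code under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_labharbor <- function(message, class) {
  rlang::abort(message, class = c(class, "labharbor_error"))
}
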
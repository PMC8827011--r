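#' Reference ranges used by the cohort simulator
#'
#' Per-field normal distributions (mean, sd), canonical unit and the
#' decimal precision values are rounded to. These are plausibility
#' scaffolding for synthetic data — typical adult reference intervals —
#' not clinical claims.
#'
#' @return A tibble: `field_code`, `mean`, `sd`, `unit`, `digits`.
#' @export
lab_reference_ranges <- function() {
  labs <- lab_field_table()
  rr <- tribble(
    ~field_code, ~mean, ~sd, ~digits,
    "na", 140, 2.5, 0, "k", 4.2, 0.4, 1, "cl", 103, 3, 0,
    "co2", 25, 2.5, 0, "bun", 15, 5, 0, "cre", 0.95, 0.2, 2,
    "gfr", 85, 15, 0, "glu", 95, 15, 0, "anion", 10, 2, 0,
    "alb", 4.2, 0.35, 1, "tbili", 0.7, 0.25, 2, "ca", 9.4, 0.45, 1,
    "tp", 7.0, 0.5, 1, "sgpt", 25, 10, 0, "sgot", 24, 9, 0,
    "alkp", 80, 20, 0, "glob", 2.8, 0.4, 1, "wbc", 7.0, 1.8, 1,
    "rbc", 4.8, 0.5, 2, "hgb", 14.0, 1.4, 1, "hct", 42, 4, 1,
    "mcv", 90, 5, 1, "mch", 30, 2, 1, "mchc", 33.5, 1.1, 1,
    "plt", 250, 60, 0, "mpv", 9.5, 1.1, 1, "rdw", 13.5, 1.2, 1,
    "neut", 60, 8, 1, "anc", 4.2, 1.3, 2, "lymp", 28, 7, 1,
    "alc", 1.9, 0.6, 2, "mon", 8, 2, 1, "amc", 0.55, 0.15, 2,
    "eosp", 2.5, 1.2, 1, "ldh", 180, 35, 0)
  left_join(rr, labs[c("field_code", "unit")], by = "field_code")
}

# Off-dictionary unit spellings used when injecting unit variants.
unit_variant_map <- function() {
  c("mmol/L" = "mEq/L", "mg/dL" = "mg/100mL", "g/dL" = "g/L",
    "%" = "pct", "K/uL" = "10^3/uL", "M/uL" = "10^6/uL",
    "fL" = "um^3", "pg" = "pcg", "U/L" = "IU/L",
    "mL/min/1.73m2" = "mL/min")
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: cohort size, per-subject
#' draw counts, true log hazard ratios per lab (per unit, applied to
#' the value centered at its reference mean), an exponential baseline
#' hazard in events/day, the target censoring fraction, and the
#' corruption rates the renderer uses to emulate messy exports.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed; every downstream rendering derives its RNG
#'   stream from it.
#' @param mean_draws Mean number of collection events per subject
#'   (1 + Poisson(mean_draws - 1)).
#' @param labs_per_draw Number of lab fields measured at each event.
#' @param true_log_hr Named numeric vector of true log hazard ratios by
#'   field code; unnamed fields are null.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param censor_rate Target fraction censored (independent exponential
#'   censoring; 0 means every subject dies).
#' @param corruption List of rates: `refused_rate`, `canceled_rate`,
#'   `unit_variant_rate`, `duplicate_draw_rate`.
#' @param site_prefix Site prefix for generated record ids.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300, seed = 1, mean_draws = 3,
                       labs_per_draw = 12, true_log_hr = numeric(),
                       baseline_hazard = 1 / 1500, censor_rate = 0.3,
                       corruption = list(refused_rate = 0, canceled_rate = 0,
                                         unit_variant_rate = 0,
                                         duplicate_draw_rate = 0),
                       site_prefix = "A") {
  stopifnot(n_subjects >= 1, baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1)
  defaults <- list(refused_rate = 0, canceled_rate = 0,
                   unit_variant_rate = 0, duplicate_draw_rate = 0)
  corruption <- utils::modifyList(defaults, as.list(corruption))
  rates <- unlist(corruption)
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 mean_draws = mean_draws, labs_per_draw = labs_per_draw,
                 true_log_hr = true_log_hr, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, corruption = corruption,
                 site_prefix = site_prefix),
            class = "sim_config")
}

#' Simulate a ground-truth registry cohort
#'
#' Generates a fully consistent registry: per-subject lab values drawn
#' from the packaged reference ranges (constant per subject across
#' draws — no longitudinal trajectories), survival times exponential
#' with hazard `baseline_hazard * exp(sum(beta * (x - ref_mean)))`,
#' independent exponential censoring calibrated to `censor_rate`, and a
#' crosswalk from synthetic MRNs to site-prefixed record ids. Fully
#' reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `cohort_truth`: `observations` (long, with
#'   both `patient_key` and `record_id`), `status`, `chars`,
#'   `crosswalk`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  rr <- lab_reference_ranges()
  n <- cfg$n_subjects
  with_seed(cfg$seed, {
    patient_key <- sprintf("MRN%07d", 1000000 + seq_len(n))
    xwalk <- make_crosswalk(patient_key, site_prefix = cfg$site_prefix)
    record_id <- xwalk$record_id
    diagnosis_date <- as.Date("2016-01-01") + sample(0:1460, n, replace = TRUE)

    vals <- matrix(0, n, nrow(rr), dimnames = list(NULL, rr$field_code))
    for (j in seq_len(nrow(rr))) {
      vals[, j] <- round(rnorm(n, rr$mean[j], rr$sd[j]), rr$digits[j])
    }

    beta <- stats::setNames(rep(0, nrow(rr)), rr$field_code)
    if (length(cfg$true_log_hr)) {
      unknown <- setdiff(names(cfg$true_log_hr), rr$field_code)
      if (length(unknown)) {
        stop_labharbor(paste0("true_log_hr names unknown field: ", unknown[1]),
                       "labharbor_config_error")
      }
      beta[names(cfg$true_log_hr)] <- cfg$true_log_hr
    }
    lp <- as.numeric((vals - matrix(rr$mean, n, nrow(rr), byrow = TRUE)) %*% beta)
    hazard <- cfg$baseline_hazard * exp(lp)
    t_death <- rexp(n, hazard)
    t_censor <- if (cfg$censor_rate > 0) {
      rexp(n, cfg$baseline_hazard * cfg$censor_rate / (1 - cfg$censor_rate))
    } else rep(Inf, n)
    event <- t_death <= t_censor
    time_days <- pmax(1, round(pmin(t_death, t_censor)))

    status <- tibble(
      record_id = record_id,
      death_date = as.Date(ifelse(event, diagnosis_date + time_days, NA),
                           origin = "1970-01-01"),
      last_followup_date = diagnosis_date + time_days)
    chars <- tibble(record_id = record_id, diagnosis_date = diagnosis_date)

    obs <- vector("list", n)
    for (i in seq_len(n)) {
      n_draws <- 1L + rpois(1, max(0, cfg$mean_draws - 1))
      offsets <- c(sample(-30:10, 1),
                   if (n_draws > 1) sample(-90:min(180, time_days[i]),
                                           n_draws - 1, replace = TRUE))
      dates <- diagnosis_date[i] + offsets
      if (runif(1) < cfg$corruption$duplicate_draw_rate) {
        dates <- c(dates, dates[1])        # same-day second draw
      }
      slots <- sample(seq_len(12 * 60) - 1, length(dates))  # 07:00-18:59, unique
      times <- sprintf("%02d:%02d", 7 + slots %/% 60, slots %% 60)
      nf <- min(cfg$labs_per_draw, nrow(rr))
      fields <- unlist(lapply(seq_along(dates),
                              function(j) sample(rr$field_code, nf)))
      obs[[i]] <- tibble(
        patient_key = patient_key[i], record_id = record_id[i],
        field_code = fields,
        value = unname(vals[i, fields]),
        unit = rr$unit[match(fields, rr$field_code)],
        collection_date = rep(dates, each = nf),
        collection_time = rep(times, each = nf))
    }
    observations <- bind_rows(obs)
    observations$source_row <- seq_len(nrow(observations))
    structure(list(observations = observations, status = status,
                   chars = chars, crosswalk = xwalk, config = cfg),
              class = "cohort_truth")
  })
}

#' Render a ground truth directly as an import table
#'
#' The "answer key" for round-trip tests: what the pipeline must
#' reproduce exactly from an uncorrupted rendering of the same truth.
#'
#' @param truth A [simulate_cohort()] result.
#' @param dd The dictionary.
#' @return An import table (see [to_redcap_long()]).
#' @export
truth_import_table <- function(truth, dd = default_mcc_dictionary()) {
  obs <- truth$observations
  obs$patient_key <- NULL
  to_redcap_long(obs, dd = dd)
}

#' Render a ground truth as the untidy 4-column EHR export
#'
#' Groups each subject-datetime's labs into one panel cell, substitutes
#' source test names uniformly among the lookup-table variants for each
#' field, and injects "refused"/"canceled" tokens and off-dictionary
#' unit variants at the configured corruption rates. Every planted
#' corruption is recorded in a sidecar manifest so exclusion accounting
#' can be checked item-for-item. Output is tab-delimited because source
#' test names legitimately contain commas.
#'
#' @param truth A [simulate_cohort()] result.
#' @param lut Lookup table supplying the per-field name variants.
#' @param delim Field delimiter for the 4-column file.
#' @return A list: `lines` (character vector, header first) and
#'   `manifest` (tibble: `source_row`, `field_code`,
#'   `source_test_name`, `kind`, `original_value`).
#' @export
render_untidy <- function(truth, lut = default_lookup(), delim = "\t") {
  cfg <- truth$config
  cor <- cfg$corruption
  uvm <- unit_variant_map()
  obs <- truth$observations
  with_seed(cfg$seed + 104729L, {
    # stable line order: subject, then chronological event
    key <- paste(obs$patient_key, obs$collection_date,
                 time_sort_key(obs$collection_time), sep = "\r")
    ord <- order(obs$patient_key, obs$collection_date,
                 time_sort_key(obs$collection_time), obs$source_row)
    obs <- obs[ord, ]
    key <- key[ord]
    line_of <- match(key, unique(key))

    variants <- split(lut$source_name, lut$field_code)
    nm <- vapply(obs$field_code, function(fc) {
      v <- variants[[fc]]
      v[sample.int(length(v), 1)]
    }, character(1))

    value_str <- format_value(obs$value)
    unit_str <- obs$unit
    kind <- rep(NA_character_, nrow(obs))
    u <- runif(nrow(obs))
    refused <- u < cor$refused_rate
    canceled <- !refused & u < cor$refused_rate + cor$canceled_rate
    uv <- runif(nrow(obs)) < cor$unit_variant_rate & !refused & !canceled &
      obs$unit %in% names(uvm)
    value_str[refused] <- "refused"
    value_str[canceled] <- "canceled"
    unit_str[refused | canceled] <- ""
    unit_str[uv] <- uvm[obs$unit[uv]]
    kind[refused] <- "refused"
    kind[canceled] <- "canceled"
    kind[uv] <- "unit_variant"

    token <- trimws(paste(nm, value_str, unit_str))
    cells <- vapply(split(token, line_of), paste, character(1), collapse = "; ")
    first <- !duplicated(line_of)
    head_tbl <- obs[first, ]
    lines <- paste(head_tbl$patient_key,
                   format_mdy(head_tbl$collection_date),
                   ifelse(is.na(head_tbl$collection_time), "",
                          head_tbl$collection_time),
                   cells[as.character(line_of[first])],
                   sep = delim)
    header <- paste("Patient Name (MRN)", "Collection Date",
                    "Collection Time", "Lab Results", sep = delim)
    planted <- !is.na(kind)
    manifest <- tibble(source_row = line_of[planted],
                       field_code = obs$field_code[planted],
                       source_test_name = nm[planted],
                       kind = kind[planted],
                       original_value = obs$value[planted])
    list(lines = c(header, lines), manifest = manifest)
  })
}

#' Render a ground truth as a tabular EDW export
#'
#' One result per row with MRN, datetime, source test name variant,
#' value and unit — the shape of a Clarity/data-warehouse bulk pull.
#' No corruption is injected.
#'
#' @param truth A [simulate_cohort()] result.
#' @param lut Lookup table supplying name variants.
#' @return A tibble matching [default_edw_colmap()] column names.
#' @export
render_edw <- function(truth, lut = default_lookup()) {
  obs <- truth$observations
  with_seed(truth$config$seed + 7919L, {
    variants <- split(lut$source_name, lut$field_code)
    nm <- vapply(obs$field_code, function(fc) {
      v <- variants[[fc]]
      v[sample.int(length(v), 1)]
    }, character(1))
    tibble(MRN = obs$patient_key,
           Collection_Date = format_mdy(obs$collection_date),
           Collection_Time = ifelse(is.na(obs$collection_time), "",
                                    obs$collection_time),
           Test_Name = nm,
           Result = format_value(obs$value),
           Units = obs$unit)
  })
}

#' Plant exactly k errors in an import table
#'
#' Emulates the error classes seen in manual abstraction: digit typos
#' in numeric cells, malformed dates (rendered ISO instead of M/D/Y),
#' and value swaps from another row of the same column. Exactly `k`
#' cells are perturbed, chosen uniformly without replacement from the
#' eligible cells, and each perturbation is guaranteed to change the
#' cell. The manifest lists every planted error.
#'
#' @param table An import table.
#' @param k Number of cells to perturb; at most the number of eligible
#'   cells.
#' @param seed Integer seed.
#' @param kinds Subset of `c("typo", "date", "swap")` to draw from.
#' @return A list: `table` (corrupted copy) and `manifest` (tibble:
#'   `row`, `column`, `original`, `corrupted`, `kind`).
#' @export
inject_errors <- function(table, k, seed = 1,
                          kinds = c("typo", "date", "swap")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  lab_cols <- setdiff(names(table),
                      c("record_id", "redcap_repeat_instrument",
                        "redcap_repeat_instance", "lab_date", "lab_time"))
  pool <- list()
  if (any(kinds %in% c("typo", "swap"))) {
    for (col in lab_cols) {
      filled <- which(nzchar(trimws(as.character(table[[col]]))))
      if (length(filled)) pool[[length(pool) + 1]] <-
          tibble(row = filled, column = col, cellkind = "numeric")
    }
  }
  if ("date" %in% kinds && "lab_date" %in% names(table)) {
    filled <- which(nzchar(trimws(as.character(table$lab_date))))
    if (length(filled)) pool[[length(pool) + 1]] <-
        tibble(row = filled, column = "lab_date", cellkind = "date")
  }
  pool <- bind_rows(pool)
  if (k > nrow(pool)) {
    stop_labharbor(sprintf("k = %d exceeds the %d eligible cells",
                           k, nrow(pool)), "labharbor_argument_error")
  }
  if (k == 0) {
    return(list(table = table,
                manifest = tibble(row = integer(), column = character(),
                                  original = character(),
                                  corrupted = character(),
                                  kind = character())))
  }
  with_seed(seed, {
    chosen <- pool[sample.int(nrow(pool), k), ]
    manifest <- vector("list", k)
    for (i in seq_len(k)) {
      row <- chosen$row[i]; col <- chosen$column[i]
      original <- as.character(table[[col]][row])
      if (chosen$cellkind[i] == "date") {
        d <- as.Date(original, format = "%m/%d/%Y")
        corrupted <- format(d, "%Y-%m-%d")   # ISO: fails M/D/Y validation
        kind <- "date"
      } else {
        kind <- sample(intersect(kinds, c("typo", "swap")), 1)
        if (kind == "swap") {
          others <- setdiff(unique(as.character(table[[col]])
                                   [nzchar(trimws(as.character(table[[col]])))]),
                            original)
          if (length(others)) {
            corrupted <- others[sample.int(length(others), 1)]
          } else kind <- "typo"
        }
        if (kind == "typo") {
          digits <- gregexpr("[0-9]", original)[[1]]
          pos <- digits[sample.int(length(digits), 1)]
          old <- substr(original, pos, pos)
          new <- sample(setdiff(as.character(0:9), old), 1)
          corrupted <- original
          substr(corrupted, pos, pos) <- new
          # avoid creating a leading zero that normalizes away ("40" -> "04")
          if (suppressWarnings(isTRUE(as.numeric(corrupted) == as.numeric(original)))) {
            corrupted <- paste0(corrupted, "1")
          }
        }
      }
      table[[col]][row] <- corrupted
      manifest[[i]] <- tibble(row = row, column = col, original = original,
                              corrupted = corrupted, kind = kind)
    }
    list(table = table, manifest = bind_rows(manifest))
  })
}

#' Simulate a simple survival dataset with known hazard ratio
#'
#' A minimal generator for calibration checks of the Cox fit:
#' exponential baseline, a single covariate (binary by default), true
#' hazard `baseline_hazard * exp(beta * x)`, independent exponential
#' censoring.
#'
#' @param n Subjects.
#' @param beta True log hazard ratio.
#' @param x Covariate vector, default `rbinom(n, 1, 0.5)`.
#' @param baseline_hazard Events per time unit.
#' @param censor_rate Target censored fraction.
#' @param round_days Round times to whole days (introduces ties).
#' @param seed Optional seed.
#' @return A tibble: `x`, `time`, `event`.
#' @export
simulate_cox_data <- function(n, beta, x = NULL, baseline_hazard = 0.001,
                              censor_rate = 0.3, round_days = FALSE,
                              seed = NULL) {
  gen <- function() {
    if (is.null(x)) x <- rbinom(n, 1, 0.5)
    t_death <- rexp(n, baseline_hazard * exp(beta * x))
    t_censor <- if (censor_rate > 0) {
      rexp(n, baseline_hazard * censor_rate / (1 - censor_rate))
    } else rep(Inf, n)
    time <- pmin(t_death, t_censor)
    if (round_days) time <- pmax(1, round(time))
    tibble(x = x, time = time, event = t_death <= t_censor)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
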
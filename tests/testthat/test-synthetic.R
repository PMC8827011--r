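test_that("cohort simulation is deterministic in the seed", {
  cfg <- sim_config(n_subjects = 12, seed = 404,
                    corruption = list(refused_rate = 0.05))
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1$observations, t2$observations)
  expect_identical(t1$status, t2$status)
  r1 <- render_untidy(t1)
  r2 <- render_untidy(t2)
  expect_identical(r1$lines, r2$lines)
  expect_identical(r1$manifest, r2$manifest)
  t3 <- simulate_cohort(sim_config(n_subjects = 12, seed = 405))
  expect_false(identical(t1$observations$value, t3$observations$value))
})

test_that("ground truth is internally consistent", {
  truth <- simulate_cohort(sim_config(n_subjects = 25, seed = 6,
                                      censor_rate = 0.3))
  expect_true(all(truth$observations$record_id %in% truth$crosswalk$record_id))
  expect_true(all(truth$status$last_followup_date >= truth$chars$diagnosis_date))
  died <- !is.na(truth$status$death_date)
  expect_true(all(truth$status$death_date[died] >=
                    truth$chars$diagnosis_date[died]))
  # zero censoring means every subject has an event
  t0 <- simulate_cohort(sim_config(n_subjects = 25, seed = 6, censor_rate = 0))
  expect_true(all(!is.na(t0$status$death_date)))
})

test_that("same-day duplicate draws appear when configured", {
  truth <- simulate_cohort(sim_config(n_subjects = 40, seed = 15,
                                      corruption = list(duplicate_draw_rate = 0.5)))
  ev <- unique(truth$observations[c("record_id", "collection_date",
                                    "collection_time")])
  per_day <- table(paste(ev$record_id, ev$collection_date))
  expect_true(any(per_day > 1))
})

test_that("rendered corruption is manifested at the configured rates", {
  truth <- simulate_cohort(sim_config(
    n_subjects = 60, seed = 12,
    corruption = list(refused_rate = 0.04, canceled_rate = 0.02,
                      unit_variant_rate = 0.05)))
  r <- render_untidy(truth)
  n <- nrow(truth$observations)
  counts <- table(factor(r$manifest$kind,
                         levels = c("refused", "canceled", "unit_variant")))
  # binomial counts near r * N (4 sd slack)
  for (kind in names(counts)) {
    rate <- switch(kind, refused = 0.04, canceled = 0.02,
                   unit_variant = 0.05)
    expect_lt(abs(counts[[kind]] - rate * n), 4 * sqrt(n * rate) + 1)
  }
})

test_that("null simulations produce null fits", {
  # with all true log hazard ratios zero, CIs should cover 1.0 at ~95%
  cover <- 0
  total <- 0
  for (seed in 1:30) {
    truth <- simulate_cohort(sim_config(n_subjects = 100, seed = seed,
                                        mean_draws = 1.2, labs_per_draw = 8))
    res <- baselabs_os_table(truth$observations, truth$status, truth$chars)
    cover <- cover + sum(res$ci_low <= 1 & 1 <= res$ci_high)
    total <- total + nrow(res)
  }
  expect_gt(total, 200)
  expect_gt(cover / total, 0.90)
  expect_lt(cover / total, 0.99)
})

test_that("error injection perturbs exactly k cells and is invertible by manifest", {
  truth <- simulate_cohort(sim_config(n_subjects = 15, seed = 44))
  tbl <- truth_import_table(truth)
  out0 <- inject_errors(tbl, 0, seed = 1)
  expect_identical(out0$table, tbl)
  expect_equal(nrow(out0$manifest), 0)
  out <- inject_errors(tbl, 12, seed = 2)
  expect_equal(nrow(out$manifest), 12)
  diffs <- 0
  for (i in seq_len(nrow(out$manifest))) {
    m <- out$manifest[i, ]
    expect_equal(as.character(out$table[[m$column]][m$row]), m$corrupted)
    expect_false(identical(m$original, m$corrupted))
  }
  # restoring manifested cells recovers the original table
  fixed <- out$table
  for (i in seq_len(nrow(out$manifest))) {
    m <- out$manifest[i, ]
    fixed[[m$column]][m$row] <- m$original
  }
  expect_identical(as.data.frame(fixed), as.data.frame(tbl))
  # k beyond the filled-cell pool is an argument error
  expect_error(inject_errors(tbl, 10^7, seed = 1),
               class = "labharbor_argument_error")
})
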
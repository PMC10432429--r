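test_that("invalid config fields are rejected by name", {
  expect_error(cohort_config(n_complicated = -1), "n_complicated")
  expect_error(cohort_config(monitoring_days = 0), "monitoring_days")
  expect_error(cohort_config(pre_event_effect = list(step_suppression = 1.2,
                                                     hr_elevation = 10)),
               "pre_event_effect")
  expect_error(
    cohort_config(grade_mix = list(
      complicated = c(I = 0.7, II = 0.2, III = 0.2, IV = 0, V = 0),
      simple = c(I = 0.9, II = 0, III = 0.1, IV = 0, V = 0))),
    "grade_mix")
})

test_that("an event-free patient gets a full monitoring window of summaries", {
  cfg <- cohort_config(
    n_complicated = 1L, n_simple = 0L,
    event_rate = c(complicated = 0, simple = 0), seed = 7L,
    wear_model = list(mean_hours = c(complicated = 12, simple = 12),
                      sd_hours = c(complicated = 0, simple = 0),
                      max_hours = 18, sleep_missing_prob = 0.15))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$patients), 1L)
  expect_equal(nrow(co$events), 0L)
  expect_equal(nrow(co$summaries), 21L)
  expect_setequal(co$summaries$pod, 1:21)
})

test_that("a fixed seed reproduces the cohort and its CSV files byte for byte", {
  cfg <- quick_config(seed = 42L)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$patients, co2$patients)
  expect_identical(co1$events, co2$events)
  expect_identical(co1$minutes, co2$minutes)
  expect_identical(co1$summaries, co2$summaries)

  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort_csv(co1, d1)
  write_cohort_csv(co2, d2)
  for (f in c("patients.csv", "events.csv", "minute_hr.csv",
              "minute_steps.csv", "daily_summary.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort CSV files round-trip through the readers", {
  cfg <- quick_config(seed = 9L, n_complicated = 2L, n_simple = 1L)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(nrow(back$minutes), nrow(co$minutes))
  m1 <- back$minutes[order(patient_id, pod, minute),
                     .(patient_id, pod, minute, hr_bpm, steps)]
  m2 <- co$minutes[order(patient_id, pod, minute),
                   .(patient_id, pod, minute, hr_bpm, steps)]
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  expect_equal(nrow(back$summaries), nrow(co$summaries))
  unlink(dir, recursive = TRUE)
})

test_that("pre-event signal injection rescales the exact prior days", {
  ## day 4 holds 8000 steps in 100 worn minutes; event on POD 5
  st <- rbindlist(lapply(1:6, function(d)
    make_minutes("P1", d, minute = 600:699, hr_bpm = 90L, steps = 80L)))
  ev <- list(patient_id = "P1", pod = 5L)
  out <- inject_event_signal(st, ev, list(step_suppression = 0.5,
                                          hr_elevation = 15))
  expect_equal(out[pod == 4L, sum(steps)], 4000L)
  expect_equal(out[pod == 3L, sum(steps)], 4000L)
  expect_equal(out[pod == 5L, sum(steps)], 8000L)
  expect_equal(out[pod == 6L, sum(steps)], 8000L)
  expect_true(all(out[pod %in% 3:4, hr_bpm] == 105L))
  expect_true(all(out[pod %in% c(1, 2, 5, 6), hr_bpm] == 90L))

  ## zero effect is the identity
  same <- inject_event_signal(st, ev, list(step_suppression = 0,
                                           hr_elevation = 0))
  expect_equal(same, st)

  ## an event on POD 1 has no prior days
  same1 <- inject_event_signal(st, list(patient_id = "P1", pod = 1L),
                               list(step_suppression = 0.9,
                                    hr_elevation = 30))
  expect_equal(same1, st)

  ## events outside the window are rejected
  expect_error(inject_event_signal(st, list(patient_id = "P1", pod = 25L),
                                   list(step_suppression = 0.5,
                                        hr_elevation = 15)),
               "outside monitoring window")
  expect_error(inject_event_signal(st, list(patient_id = "P2", pod = 5L),
                                   list(step_suppression = 0.5,
                                        hr_elevation = 15)),
               "does not own")
})

test_that("daily summaries recompute step totals and intensity minutes from the stream", {
  cfg <- quick_config()
  pat <- make_patient()

  ## worn all zeros: everything is sedentary
  d0 <- make_minutes("P1", 2L, minute = 600:719, hr_bpm = 80L, steps = 0L)
  s0 <- summarize_generator_day(d0, pat, cfg)
  expect_equal(s0$total_steps, 0L)
  expect_equal(s0$sedentary_min, 120L)
  expect_equal(s0$very_active_min + s0$fairly_active_min +
                 s0$lightly_active_min, 0L)

  ## 60 minutes at 100 steps/min crosses the very-active threshold (67)
  d1 <- rbind(make_minutes("P1", 3L, minute = 600:659, hr_bpm = 120L,
                           steps = 100L),
              make_minutes("P1", 3L, minute = 660:719, hr_bpm = 80L,
                           steps = 0L))
  s1 <- summarize_generator_day(d1, pat, cfg)
  expect_equal(s1$total_steps, 6000L)
  expect_equal(s1$very_active_min, 60L)
  expect_equal(s1$sedentary_min, 60L)
  expect_equal(s1$total_distance_km, 6000 * 140 * 5e-6)
})

test_that("generated summaries satisfy the daily-summary invariants", {
  co <- generate_cohort(quick_config(n_complicated = 12L, n_simple = 12L,
                                     seed = 31L))
  s <- co$summaries
  expect_gt(nrow(s), 400)
  num_cols <- setdiff(names(s)[vapply(s, is.numeric, logical(1))], "pod")
  for (cn in num_cols)
    expect_true(all(s[[cn]] >= 0, na.rm = TRUE), label = cn)
  both <- s[!is.na(total_min_asleep) & !is.na(total_min_in_bed)]
  expect_true(all(both$total_min_asleep <= both$total_min_in_bed))
  comp <- c("very_active_distance_km", "moderately_active_distance_km",
            "lightly_active_distance_km", "sedentary_active_distance_km")
  for (cn in comp)
    expect_true(all(s[[cn]] <= s$total_distance_km + 1e-9), label = cn)
  ## minute streams are minute-aligned and strictly increasing within a day
  expect_true(all(co$minutes[, !is.unsorted(minute, strictly = TRUE),
                             by = .(patient_id, pod)]$V1))
})

test_that("realized event counts track the configured rates", {
  ## rate calibration in expectation over many seeds (thin wear keeps
  ## generation cheap; the event draw does not depend on the wear model)
  rate <- 41 / 85
  n_pat <- 40L
  mean_events <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_config(
      n_complicated = n_pat, n_simple = 0L,
      event_rate = c(complicated = rate, simple = 0), seed = s,
      wear_model = list(mean_hours = c(complicated = 0.3, simple = 0.3),
                        sd_hours = c(complicated = 0, simple = 0),
                        max_hours = 18, sleep_missing_prob = 0.15)))
    nrow(co$events) / n_pat
  }, numeric(1))
  expect_lt(abs(mean(mean_events) - rate), 0.1 * rate)
})

test_that("stronger pre-event effects depress pre-event step totals monotonically", {
  pre_event_means <- vapply(c(0, 0.3, 0.6), function(supp) {
    cfg <- cohort_config(
      n_complicated = 10L, n_simple = 0L,
      event_rate = c(complicated = 2, simple = 0), seed = 77L,
      pre_event_effect = list(step_suppression = supp, hr_elevation = 0),
      wear_model = list(mean_hours = c(complicated = 6, simple = 6),
                        sd_hours = c(complicated = 0, simple = 0),
                        max_hours = 18, sleep_missing_prob = 0.15))
    co <- generate_cohort(cfg)
    win <- unique(rbindlist(list(co$events[, .(patient_id, pod = pod - 1L)],
                                 co$events[, .(patient_id, pod = pod - 2L)]))
                  )[pod >= 1L]
    day_steps <- co$minutes[, .(steps = sum(steps)), by = .(patient_id, pod)]
    mean(day_steps[win, on = c("patient_id", "pod"), nomatch = NULL]$steps)
  }, numeric(1))
  expect_true(all(diff(pre_event_means) < 0))
})
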
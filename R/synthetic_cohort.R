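#' Generate a synthetic post-appendectomy cohort
#'
#' Draws a complete synthetic cohort from a [cohort_config()]: a patient
#' roster, a postoperative event log, minute-level heart-rate/step streams
#' (only worn minutes are emitted; absent minutes encode "device not worn"),
#' and per-day activity/sleep summaries. The 1-2 days preceding each
#' postoperative event carry the configured activity suppression and
#' heart-rate elevation, which is the signal the downstream classifier is
#' asked to recover. Days on which the device was never worn produce no
#' minute samples and no daily summary row (no-data days).
#'
#' The same config (including `seed`) reproduces the identical cohort.
#'
#' @param config A `cohort_config` object.
#' @return A list of class `wearable_cohort` with data.tables `patients`,
#'   `events`, `minutes` (`patient_id`, `pod`, `minute` of day 0..1439,
#'   `hr_bpm`, `steps`), and `summaries` (one row per patient-day with data),
#'   plus the `config` used.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_complicated = 3, n_simple = 2,
#'                                         seed = 7))
#' cohort$patients$group
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  patients <- r_patients(config)
  events <- r_events(patients, config)
  minutes <- r_minute_streams(patients, config)
  minutes <- inject_cohort_signal(minutes, events, config$pre_event_effect)
  summaries <- r_daily_summaries(patients, minutes, config)
  out <- list(patients = patients, events = events, minutes = minutes,
              summaries = summaries, config = config)
  class(out) <- "wearable_cohort"
  out
}

#' @export
print.wearable_cohort <- function(x, ...) {
  cat(sprintf(
    "<wearable_cohort> %d patients (%d complicated / %d simple), %d events,\n",
    nrow(x$patients), sum(x$patients$group == "complicated"),
    sum(x$patients$group == "simple"), nrow(x$events)))
  cat(sprintf("  %d worn minutes, %d patient-days with daily summaries\n",
              nrow(x$minutes), nrow(x$summaries)))
  invisible(x)
}

r_patients <- function(config) {
  grp <- c(rep("complicated", config$n_complicated),
           rep("simple", config$n_simple))
  n <- length(grp)
  id <- sprintf("%s%03d", ifelse(grp == "complicated", "C", "S"),
                c(seq_len(config$n_complicated), seq_len(config$n_simple)))
  age <- pmin(pmax(rnorm(n, 10.4, 3.6), 3), 17)
  sex <- ifelse(runif(n) < ifelse(grp == "complicated", 0.518, 0.447),
                "female", "male")
  race_levels <- c("nh_white", "hispanic_latinx", "african_american", "other")
  race_prob <- list(
    complicated = c(19, 53, 7, 4) / 83,
    simple = c(22, 39, 7, 3) / 71
  )
  race <- vapply(grp, function(g) {
    sample(race_levels, 1L, prob = race_prob[[g]])
  }, character(1), USE.NAMES = FALSE)
  height <- 85 + 5.5 * age + rnorm(n, 0, 6)
  weight <- pmax(0.00014 * height^2 * (17 + rnorm(n, 0, 2)) / 10, 10)
  device <- ifelse(runif(n) < config$device_prob_inspire_hr[grp],
                   "inspire_hr", "inspire_2")
  los_mean <- ifelse(grp == "complicated", 4.0, 0.9)
  los_sd <- ifelse(grp == "complicated", 2.6, 0.7)
  los <- pmax(rnorm(n, los_mean, los_sd), 0.2)
  data.table(
    patient_id = id, group = grp, age_years = age, sex = sex,
    race_ethnicity = race, weight_kg = weight, height_cm = height,
    device = device, length_of_stay_days = los,
    monitoring_days = config$monitoring_days,
    surgery_date = config$base_date
  )
}

r_events <- function(patients, config) {
  grades <- c("I", "II", "III", "IV", "V")
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    g <- patients$group[i]
    k <- min(rpois(1L, config$event_rate[[g]]), config$monitoring_days)
    if (k == 0L) return(NULL)
    pods <- sort(sample.int(config$monitoring_days, k))
    grade <- sample(grades, k, replace = TRUE, prob = config$grade_mix[[g]])
    nsqip <- runif(k) < config$nsqip_prob[grade]
    data.table(patient_id = patients$patient_id[i], pod = pods,
               clavien_grade = grade, nsqip = nsqip)
  })
  ev <- rbindlist(rows)
  if (nrow(ev) == 0L) {
    return(data.table(patient_id = character(), pod = integer(),
                      category = character(), clavien_grade = character(),
                      nsqip = logical()))
  }
  ev[, category := classify_event(clavien_grade, nsqip)]
  setcolorder(ev, c("patient_id", "pod", "category", "clavien_grade", "nsqip"))
  ev[]
}

## expected daily step total along the recovery ramp, before noise
recovery_mean_steps <- function(pod, group, age, config) {
  rm_ <- config$recovery_model
  plateau <- rm_$plateau_steps * (0.5 + 0.05 * age)
  frac <- rm_$nadir_frac + (1 - rm_$nadir_frac) /
    (1 + exp(-(pod - rm_$midpoint_pod[group]) / rm_$scale_days[group]))
  plateau * frac
}

r_minute_streams <- function(patients, config) {
  if (nrow(patients) == 0L) {
    return(data.table(patient_id = character(), pod = integer(),
                      minute = integer(), hr_bpm = integer(),
                      steps = integer()))
  }
  wm <- config$wear_model
  days <- CJ(patient_id = patients$patient_id,
             pod = seq_len(config$monitoring_days), sorted = TRUE)
  days <- patients[, .(patient_id, group, age_years)][days, on = "patient_id"]
  setorder(days, patient_id, pod)
  nd <- nrow(days)
  wear_h <- pmin(pmax(rnorm(nd, wm$mean_hours[days$group],
                            wm$sd_hours[days$group]), 0), wm$max_hours)
  days[, worn_min := as.integer(round(wear_h * 60))]
  window_min <- as.integer(round(wm$max_hours * 60))
  days[, start_min := 360L +
         as.integer(floor(runif(nd) * (window_min - worn_min + 1)))]
  days[, target_steps := recovery_mean_steps(pod, group, age_years, config) *
         exp(rnorm(nd, 0, config$recovery_model$noise_sdlog))]
  days[, day_eff := rnorm(nd, 0, 3)]
  ## per-patient resting heart rate declines with age in children
  hr_rest_tab <- patients[, .(patient_id,
                              hr_rest = 110 - 2.5 * age_years +
                                rnorm(nrow(patients), 0, 5))]
  days <- hr_rest_tab[days, on = "patient_id"]
  days <- days[worn_min > 0L]
  if (nrow(days) == 0L) {
    return(data.table(patient_id = character(), pod = integer(),
                      minute = integer(), hr_bpm = integer(),
                      steps = integer()))
  }
  idx <- rep(seq_len(nrow(days)), days$worn_min)
  mins <- data.table(
    patient_id = days$patient_id[idx],
    pod = days$pod[idx],
    minute = days$start_min[idx] +
      (sequence(days$worn_min) - 1L)
  )
  nm <- nrow(mins)
  ## zero-inflated gamma weights distribute the day's steps across minutes
  active <- runif(nm) < 0.4
  w <- ifelse(active, rgamma(nm, shape = 0.8, rate = 1), 0)
  mins[, steps := {
    tw <- sum(w[.I])
    if (tw <= 0) {
      as.integer(round(days$target_steps[.GRP] / .N + numeric(.N)))
    } else {
      as.integer(round(days$target_steps[.GRP] * w[.I] / tw))
    }
  }, by = .(patient_id, pod)]
  mins[, steps := pmin(steps, 220L)]
  hr_base <- days$hr_rest[idx] + days$day_eff[idx]
  mins[, hr_bpm := as.integer(round(pmin(pmax(
    hr_base + 10 + 0.25 * steps + rnorm(nm, 0, 8), 40), 220)))]
  setcolorder(mins, c("patient_id", "pod", "minute", "hr_bpm", "steps"))
  setorder(mins, patient_id, pod, minute)
  mins[]
}

#' Perturb a minute stream on the days preceding a postoperative event
#'
#' Applies the configured pre-event signal to one patient's minute stream:
#' on postoperative days `event$pod - 2` and `event$pod - 1` (those that
#' exist and are >= 1), minute step counts are scaled by
#' `1 - effect$step_suppression` and minute heart rate is raised by
#' `effect$hr_elevation` bpm. All other days are untouched. An event on
#' POD 1 has no prior days and leaves the stream unchanged.
#'
#' @param stream data.table minute stream for a single patient
#'   (`patient_id`, `pod`, `minute`, `hr_bpm`, `steps`).
#' @param event Single event as a list or one-row data.frame with
#'   `patient_id` and `pod`.
#' @param effect List with `step_suppression` (fraction in \[0,1\]) and
#'   `hr_elevation` (bpm).
#' @param monitoring_days Length of the monitoring window; events outside
#'   POD 1..`monitoring_days` are rejected.
#' @return The modified minute stream (a new data.table).
#' @export
inject_event_signal <- function(stream, event, effect, monitoring_days = 21L) {
  stream <- as.data.table(stream)
  pid <- unique(stream$patient_id)
  if (length(pid) > 1L)
    stop("inject_event_signal() expects a single patient's stream")
  if (length(pid) == 1L && !identical(as.character(event$patient_id), pid))
    stop(sprintf("event patient `%s` does not own this stream",
                 event$patient_id))
  pod_k <- as.integer(event$pod)
  if (is.na(pod_k) || pod_k < 1L || pod_k > monitoring_days)
    stop(sprintf("event pod %s outside monitoring window 1..%d",
                 event$pod, monitoring_days))
  target <- (pod_k - 2L):(pod_k - 1L)
  target <- target[target >= 1L]
  if (length(target) == 0L) return(stream[])
  out <- copy(stream)
  out[pod %in% target,
      `:=`(steps = as.integer(round(steps * (1 - effect$step_suppression))),
           hr_bpm = as.integer(round(hr_bpm + effect$hr_elevation)))]
  out[]
}

## vectorized injection across a cohort; a day covered by the windows of
## several events is perturbed once
inject_cohort_signal <- function(minutes, events, effect) {
  if (nrow(events) == 0L || nrow(minutes) == 0L) return(minutes)
  if (effect$step_suppression == 0 && effect$hr_elevation == 0) return(minutes)
  win <- rbindlist(list(
    events[, .(patient_id, pod = pod - 1L)],
    events[, .(patient_id, pod = pod - 2L)]
  ))
  win <- unique(win[pod >= 1L])
  if (nrow(win) == 0L) return(minutes)
  minutes[win, on = c("patient_id", "pod"),
          `:=`(steps = as.integer(round(steps * (1 - effect$step_suppression))),
               hr_bpm = as.integer(round(hr_bpm + effect$hr_elevation)))]
  minutes[]
}

#' Summarize one generated day of minute data into a daily summary row
#'
#' Stand-in for the wearable vendor's proprietary daily aggregation: step and
#' distance totals are recomputed from the minute stream, worn minutes are
#' partitioned into sedentary/light/fairly/very active classes by the
#' configured steps-per-minute thresholds, energy expenditure is derived from
#' weight and steps, resting heart rate is the mean of the lowest decile of
#' worn-minute heart rate, and sleep fields are drawn from the generator's
#' sleep model (so repeated calls consume random numbers).
#'
#' @param stream_day Minute data.table slice covering at most one patient-day.
#' @param patient One-row patient record (needs `height_cm`, `weight_kg`).
#' @param config A `cohort_config`.
#' @return One-row data.table of daily summary fields; a day with no worn
#'   minutes yields zero activity totals and missing heart-rate/sleep fields.
#' @export
summarize_generator_day <- function(stream_day, patient, config) {
  stream_day <- as.data.table(stream_day)
  if (nrow(stream_day) > 0L &&
      (length(unique(stream_day$patient_id)) > 1L ||
       length(unique(stream_day$pod)) > 1L))
    stop("stream_day must cover a single patient-day")
  if (nrow(stream_day) > 1440L)
    stop("stream_day covers more than 1440 minutes")
  pid <- if (nrow(stream_day)) stream_day$patient_id[1] else patient$patient_id
  d <- if (nrow(stream_day)) stream_day$pod[1] else NA_integer_
  day_summary_core(
    data.table(patient_id = pid, pod = d),
    stream_day[!is.na(hr_bpm) & hr_bpm > 0L],
    as.data.table(patient), config
  )
}

## shared daily-summary computation; `days` enumerates the patient-days to
## summarize, `worn` holds only worn minutes
day_summary_core <- function(days, worn, patients, config) {
  th <- config$intensity_thresholds
  agg <- worn[, {
    nlow <- max(1L, as.integer(ceiling(0.1 * .N)))
    .(total_steps = sum(steps),
      very_active_min = sum(steps >= th["very"]),
      fairly_active_min = sum(steps >= th["fairly"] & steps < th["very"]),
      lightly_active_min = sum(steps >= th["light"] & steps < th["fairly"]),
      sedentary_min = sum(steps < th["light"]),
      very_steps = sum(steps[steps >= th["very"]]),
      fairly_steps = sum(steps[steps >= th["fairly"] & steps < th["very"]]),
      light_steps = sum(steps[steps >= th["light"] & steps < th["fairly"]]),
      sed_steps = sum(steps[steps < th["light"]]),
      resting_hr_bpm = round(mean(sort(hr_bpm)[seq_len(nlow)])))
  }, by = .(patient_id, pod)]
  out <- agg[days, on = c("patient_id", "pod")]
  out <- patients[, .(patient_id, height_cm, weight_kg)][out, on = "patient_id"]
  setorder(out, patient_id, pod)
  n <- nrow(out)
  out[is.na(total_steps),
      `:=`(total_steps = 0L, very_active_min = 0L, fairly_active_min = 0L,
           lightly_active_min = 0L, sedentary_min = 0L, very_steps = 0L,
           fairly_steps = 0L, light_steps = 0L, sed_steps = 0L)]
  stride <- out$height_cm * 5e-6  # km per step
  out[, `:=`(
    total_distance_km = total_steps * stride,
    logged_activities_distance_km = 0,
    very_active_distance_km = very_steps * stride,
    moderately_active_distance_km = fairly_steps * stride,
    lightly_active_distance_km = light_steps * stride,
    sedentary_active_distance_km = sed_steps * stride,
    calories_bmr = round(22 * weight_kg + 500),
    marginal_calories = round(0.045 * total_steps)
  )]
  out[, calories := calories_bmr + marginal_calories]
  ## sleep model: time in bed with a beta-distributed sleep efficiency;
  ## a fraction of worn days record no sleep at all
  in_bed <- round(pmin(pmax(rnorm(n, 560, 70), 240), 900))
  eff <- rbeta(n, 35.2, 4.8)
  asleep <- round(in_bed * eff)
  records <- 1L + rpois(n, 0.25)
  missing_sleep <- runif(n) < config$wear_model$sleep_missing_prob
  out[, `:=`(
    total_min_asleep = ifelse(missing_sleep, NA_real_, asleep),
    total_min_in_bed = ifelse(missing_sleep, NA_real_, in_bed),
    total_min_restless = ifelse(missing_sleep, NA_real_, in_bed - asleep),
    sleep_records = ifelse(missing_sleep, NA_integer_, records)
  )]
  out[, c("height_cm", "weight_kg", "very_steps", "fairly_steps",
          "light_steps", "sed_steps") := NULL]
  setcolorder(out, c(
    "patient_id", "pod", "total_steps", "total_distance_km",
    "logged_activities_distance_km", "very_active_distance_km",
    "moderately_active_distance_km", "lightly_active_distance_km",
    "sedentary_active_distance_km", "very_active_min", "fairly_active_min",
    "lightly_active_min", "sedentary_min", "calories", "calories_bmr",
    "marginal_calories", "resting_hr_bpm", "total_min_asleep",
    "total_min_in_bed", "total_min_restless", "sleep_records"
  ))
  out[]
}

r_daily_summaries <- function(patients, minutes, config) {
  worn <- minutes[!is.na(hr_bpm) & hr_bpm > 0L]
  days <- unique(worn[, .(patient_id, pod)])
  setorder(days, patient_id, pod)
  day_summary_core(days, worn, patients, config)
}
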
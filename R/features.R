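## Canonical feature-name sets. Base features follow the daily-summary /
## heart-rate / sleep / demographics / clinical ordering; each flagged
## feature additionally carries five temporal-variant columns.

activity_feature_names <- function() {
  c("total_steps", "total_distance_km", "logged_activities_distance_km",
    "very_active_distance_km", "moderately_active_distance_km",
    "lightly_active_distance_km", "sedentary_active_distance_km",
    "very_active_min", "fairly_active_min", "lightly_active_min",
    "sedentary_min", "calories", "calories_bmr", "marginal_calories")
}

hr_feature_names <- function() {
  c("resting_hr_bpm", "hr_mean", "hr_sd", "hr_min", "hr_max")
}

sleep_feature_names <- function() {
  c("total_min_asleep", "total_min_in_bed", "total_min_restless",
    "sleep_records")
}

#' Names of the demographic feature columns (one-hot encoded)
#' @return Character vector of column names.
#' @export
demographic_feature_names <- function() {
  c("age_years", "weight_kg", "height_cm", "sex_male",
    "race_nh_white", "race_hispanic_latinx", "race_african_american",
    "race_other")
}

#' Names of the clinical-characteristic feature columns
#' @return Character vector of column names.
#' @export
clinical_feature_names <- function() {
  c("days_post_surgery", "days_post_symptom", "days_post_complication",
    "past_symptom", "past_complication", "n_past_symptoms",
    "n_past_complications", "discharged")
}

#' Features that carry the five temporal-variant columns
#' @return Character vector of base feature names.
#' @export
flagged_features <- function() {
  c("total_steps", "total_distance_km", "calories", "resting_hr_bpm",
    "total_min_asleep", "total_min_in_bed", "total_min_restless")
}

variant_suffixes <- function() {
  c("delta", "roll3_diff", "roll3_pct", "max_diff", "min_diff")
}

variant_feature_names <- function() {
  as.vector(t(outer(flagged_features(), variant_suffixes(), paste, sep = "_")))
}

#' Wearable-derived feature columns (activity, heart rate, sleep + variants)
#'
#' The complement of the demographic and clinical columns; these are the
#' columns removed by the "no wearable data" sensitivity analysis.
#' @return Character vector of column names.
#' @export
fitbit_feature_names <- function() {
  c(activity_feature_names(), hr_feature_names(), sleep_feature_names(),
    variant_feature_names())
}

#' Canonical ordered set of all model feature columns
#'
#' 39 base columns (14 activity, 5 heart rate, 4 sleep, 8 demographic after
#' one-hot expansion of race/ethnicity, 8 clinical) plus 35 temporal-variant
#' columns (7 flagged features x 5 variants): 74 columns in total.
#' @return Character vector of column names in canonical order.
#' @export
feature_names <- function() {
  c(activity_feature_names(), hr_feature_names(), sleep_feature_names(),
    demographic_feature_names(), clinical_feature_names(),
    variant_feature_names())
}

#' Compute waking-window wear time for one patient-day
#'
#' The device counts as worn in a given minute iff a heart-rate sample is
#' present and positive; zero or absent heart rate encodes "not worn".
#' Wear time is accumulated only over the potential waking window
#' 06:00-24:00, so it is at most 18 h.
#'
#' @param stream_day Minute data.table slice (`minute`, `hr_bpm`, `steps`)
#'   confined to one patient-day.
#' @return List with `wear_hours_waking` (hours) and `any_data` (TRUE iff
#'   any heart-rate or step sample exists that day, worn or not).
#' @export
#' @examples
#' d <- data.table::data.table(minute = c(300L, 400L, 401L),
#'                             hr_bpm = c(80L, 90L, 0L), steps = 0L)
#' compute_wear_time(d)  # one worn minute falls before 06:00
compute_wear_time <- function(stream_day) {
  stream_day <- as.data.table(stream_day)
  worn_waking <- stream_day[!is.na(hr_bpm) & hr_bpm > 0L &
                              minute >= 360L & minute < 1440L]
  list(
    wear_hours_waking = nrow(worn_waking) / 60,
    any_data = nrow(stream_day[!is.na(hr_bpm) | !is.na(steps)]) > 0L
  )
}

#' Daily heart-rate statistics over worn minutes
#'
#' Minutes with zero or absent heart rate (device not worn) are excluded.
#' The standard deviation uses the sample (n-1) denominator; a day with a
#' single worn minute has missing `hr_sd`, and a day with no worn minutes
#' has all four statistics missing (never zero).
#'
#' @param stream_day Minute data.table slice for one patient-day.
#' @return List with `hr_mean`, `hr_sd`, `hr_min`, `hr_max`.
#' @export
daily_hr_stats <- function(stream_day) {
  stream_day <- as.data.table(stream_day)
  hr <- stream_day[!is.na(hr_bpm) & hr_bpm > 0L, hr_bpm]
  if (length(hr) == 0L) {
    return(list(hr_mean = NA_real_, hr_sd = NA_real_,
                hr_min = NA_real_, hr_max = NA_real_))
  }
  list(hr_mean = mean(hr),
       hr_sd = if (length(hr) > 1L) sd(hr) else NA_real_,
       hr_min = as.numeric(min(hr)),
       hr_max = as.numeric(max(hr)))
}

#' Temporal change variants of one per-day feature series
#'
#' For a series indexed by postoperative day (missing days as `NA`), computes
#' for every day the five change variants used by the model:
#' \describe{
#'   \item{delta}{difference from the previous day's value}
#'   \item{roll3_diff}{difference from the mean of the values present among
#'     the three preceding calendar days (the current day is excluded)}
#'   \item{roll3_pct}{100 * roll3_diff / rolling mean}
#'   \item{max_diff}{difference from the maximum over all previous days}
#'   \item{min_diff}{difference from the minimum over all previous days}
#' }
#' Any quantity without qualifying prior data (POD 1, missing current value,
#' missing previous day for `delta`, zero rolling mean for `roll3_pct`) is
#' missing; missingness is a value, not an error.
#'
#' @param series Numeric vector; element `d` is the feature value on POD `d`.
#' @return data.table with columns `pod`, `delta`, `roll3_diff`, `roll3_pct`,
#'   `max_diff`, `min_diff` and one row per POD.
#' @export
#' @examples
#' temporal_variants(c(10, 20, 30, 40))[pod == 4]
temporal_variants <- function(series) {
  series <- as.numeric(series)
  d <- length(series)
  delta <- roll3_diff <- roll3_pct <- max_diff <- min_diff <-
    rep(NA_real_, d)
  for (k in seq_len(d)[-1]) {
    v <- series[k]
    if (is.na(v)) next
    if (!is.na(series[k - 1L])) delta[k] <- v - series[k - 1L]
    win <- series[max(1L, k - 3L):(k - 1L)]
    win <- win[!is.na(win)]
    if (length(win) > 0L) {
      r3 <- mean(win)
      roll3_diff[k] <- v - r3
      if (r3 != 0) roll3_pct[k] <- 100 * (v - r3) / r3
    }
    prev <- series[seq_len(k - 1L)]
    prev <- prev[!is.na(prev)]
    if (length(prev) > 0L) {
      max_diff[k] <- v - max(prev)
      min_diff[k] <- v - min(prev)
    }
  }
  data.table(pod = seq_len(d), delta = delta, roll3_diff = roll3_diff,
             roll3_pct = roll3_pct, max_diff = max_diff,
             min_diff = min_diff)
}

#' Clinical-characteristic features for one patient-day
#'
#' Derives the event-history and discharge features for a given
#' postoperative day: days since surgery (= `pod`), days since the most
#' recent prior symptom and prior complication, booleans and cumulative
#' counts of prior events, and a discharge indicator
#' (`pod >= ceiling(length_of_stay_days)`). Only events strictly before
#' `pod` count. When the patient has no prior event of a category, the
#' days-since features fall back to `pod` (days since surgery) as the
#' no-prior-event value.
#'
#' @param patient One-row patient record with `length_of_stay_days`.
#' @param events data.table of the patient's events (`pod`, `category`).
#' @param pod Postoperative day (>= 1).
#' @return Named list of the eight clinical features.
#' @export
clinical_features <- function(patient, events, pod) {
  pod <- as.integer(pod)
  if (is.na(pod) || pod < 1L) stop("pod must be >= 1")
  events <- as.data.table(events)
  is_prior <- events[["pod"]] < pod
  prior_sym <- events[["pod"]][is_prior & events[["category"]] == "symptom"]
  prior_cmp <- events[["pod"]][is_prior &
                                 events[["category"]] == "complication"]
  list(
    days_post_surgery = pod,
    days_post_symptom = if (length(prior_sym)) pod - max(prior_sym) else pod,
    days_post_complication = if (length(prior_cmp)) pod - max(prior_cmp)
                             else pod,
    past_symptom = as.integer(length(prior_sym) > 0L),
    past_complication = as.integer(length(prior_cmp) > 0L),
    n_past_symptoms = length(prior_sym),
    n_past_complications = length(prior_cmp),
    discharged = as.integer(pod >= ceiling(patient$length_of_stay_days))
  )
}

#' Build the per-day feature matrix and wear-time table for a cohort
#'
#' Produces one feature row per patient-day on which any wearable data were
#' recorded (worn minutes or a daily summary row); days with no data at all
#' are omitted. Each row contains the daily summary fields, heart-rate
#' statistics from the minute stream, temporal change variants of the seven
#' flagged features (computed over the calendar POD series, so missing days
#' are skipped rather than shifted), one-hot demographics, and the clinical
#' features. The wear table covers every patient-day of the monitoring
#' window, including no-data days.
#'
#' @param patients Patient roster data.table.
#' @param events Event log data.table.
#' @param minutes Minute stream data.table (`patient_id`, `pod`, `minute`,
#'   `hr_bpm`, `steps`).
#' @param summaries Daily summary data.table.
#' @return List with `features` (one row per patient-day with data; columns
#'   `patient_id`, `pod`, then [feature_names()]) and `wear` (`patient_id`,
#'   `pod`, `wear_hours_waking`, `any_data`).
#' @export
build_feature_matrix <- function(patients, events, minutes, summaries) {
  patients <- as.data.table(patients)
  events <- as.data.table(events)
  minutes <- as.data.table(minutes)
  summaries <- as.data.table(summaries)
  unknown <- setdiff(unique(c(minutes$patient_id, summaries$patient_id)),
                     patients$patient_id)
  if (length(unknown))
    stop(sprintf("patients present in streams but absent from roster: %s",
                 paste(unknown, collapse = ", ")))

  grid <- patients[, .(pod = seq_len(monitoring_days[1])),
                   by = .(patient_id)]

  ## wear table over the full monitoring window
  worn <- minutes[!is.na(hr_bpm) & hr_bpm > 0L]
  wear <- worn[minute >= 360L & minute < 1440L,
               .(wear_hours_waking = .N / 60), by = .(patient_id, pod)]
  wear <- wear[grid, on = c("patient_id", "pod")]
  wear[is.na(wear_hours_waking), wear_hours_waking := 0]
  with_min <- unique(minutes[!is.na(hr_bpm) | !is.na(steps),
                             .(patient_id, pod)])[, any_data := TRUE]
  with_sum <- unique(summaries[, .(patient_id, pod)])[, any_data := TRUE]
  got <- unique(rbindlist(list(with_min, with_sum)))
  wear <- got[wear, on = c("patient_id", "pod")]
  wear[is.na(any_data), any_data := FALSE]
  setcolorder(wear, c("patient_id", "pod", "wear_hours_waking", "any_data"))
  setorder(wear, patient_id, pod)

  ## heart-rate statistics per worn day
  hrstats <- worn[, .(
    hr_mean = mean(hr_bpm),
    hr_sd = if (.N > 1L) sd(hr_bpm) else NA_real_,
    hr_min = as.numeric(min(hr_bpm)),
    hr_max = as.numeric(max(hr_bpm))
  ), by = .(patient_id, pod)]

  feats <- wear[any_data == TRUE, .(patient_id, pod)]
  summary_cols <- c(activity_feature_names(), "resting_hr_bpm",
                    sleep_feature_names())
  feats <- summaries[, c("patient_id", "pod", summary_cols),
                     with = FALSE][feats, on = c("patient_id", "pod")]
  feats <- hrstats[feats, on = c("patient_id", "pod")]

  ## temporal variants over calendar-POD series of each flagged feature
  full <- feats[grid, on = c("patient_id", "pod")]
  setorder(full, patient_id, pod)
  variants <- full[, {
    res <- lapply(flagged_features(), function(f) {
      tv <- temporal_variants(.SD[[f]])
      setnames(tv, variant_suffixes(), paste(f, variant_suffixes(),
                                             sep = "_"))
      tv[, !"pod"]
    })
    c(list(pod = pod), do.call(cbind, res))
  }, by = .(patient_id)]
  feats <- variants[feats, on = c("patient_id", "pod")]

  ## demographics, one-hot
  demo <- patients[, .(
    patient_id, age_years, weight_kg, height_cm,
    sex_male = as.integer(sex == "male"),
    race_nh_white = as.integer(race_ethnicity == "nh_white"),
    race_hispanic_latinx = as.integer(race_ethnicity == "hispanic_latinx"),
    race_african_american = as.integer(race_ethnicity == "african_american"),
    race_other = as.integer(race_ethnicity == "other")
  )]
  feats <- demo[feats, on = "patient_id"]

  ## clinical features, vectorized over the event log
  clin <- clinical_feature_table(patients, events, feats[, .(patient_id, pod)])
  feats <- clin[feats, on = c("patient_id", "pod")]

  keep <- c("patient_id", "pod", feature_names())
  feats <- feats[, ..keep]
  setorder(feats, patient_id, pod)
  list(features = feats[], wear = wear[])
}

clinical_feature_table <- function(patients, events, days) {
  days <- copy(days)
  los <- patients[, .(patient_id, los = ceiling(length_of_stay_days))]
  days <- los[days, on = "patient_id"]
  days[, `:=`(days_post_surgery = pod,
              days_post_symptom = pod, days_post_complication = pod,
              past_symptom = 0L, past_complication = 0L,
              n_past_symptoms = 0L, n_past_complications = 0L,
              discharged = as.integer(pod >= los))]
  if (nrow(events)) {
    for (cat in c("symptom", "complication")) {
      ev <- events[category == cat, .(patient_id, epod = pod)]
      if (!nrow(ev)) next
      agg <- ev[days, on = .(patient_id, epod < pod),
                .(last = if (any(!is.na(epod))) max(epod, na.rm = TRUE)
                         else NA_integer_,
                  n = sum(!is.na(epod))),
                by = .EACHI]
      setnames(agg, "epod", "pod")
      if (cat == "symptom") {
        days[, days_post_symptom := ifelse(agg$n > 0, pod - agg$last, pod)]
        days[, past_symptom := as.integer(agg$n > 0)]
        days[, n_past_symptoms := as.integer(agg$n)]
      } else {
        days[, days_post_complication := ifelse(agg$n > 0, pod - agg$last,
                                                pod)]
        days[, past_complication := as.integer(agg$n > 0)]
        days[, n_past_complications := as.integer(agg$n)]
      }
    }
  }
  days[, los := NULL]
  days[]
}
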
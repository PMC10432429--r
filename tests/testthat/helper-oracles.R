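## Independent oracles and small fixture builders used across the suite.

library(data.table)

## Exhaustive rule interpreter for ground-truth labels: walks every day and
## applies the labeling rules literally, with precedence
## excluded > abnormal > normal.
oracle_labels <- function(event_pods, monitoring_days = 21L) {
  vapply(seq_len(monitoring_days), function(d) {
    if (d %in% event_pods) return("excluded")
    if (any((event_pods - d) %in% c(1L, 2L))) return("abnormal")
    "normal"
  }, character(1))
}

## Brute-force AUROC: concordance counted over every (positive, negative)
## pair, ties worth one half.
oracle_auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

## Brute-force temporal variants for one POD, written from the definitions
## with explicit subsetting (independent of the package's rolling loop).
oracle_variants <- function(series, k) {
  v <- series[k]
  na5 <- list(delta = NA_real_, roll3_diff = NA_real_, roll3_pct = NA_real_,
              max_diff = NA_real_, min_diff = NA_real_)
  if (k == 1L || is.na(v)) return(na5)
  out <- na5
  if (!is.na(series[k - 1L])) out$delta <- v - series[k - 1L]
  win_idx <- (k - 3L):(k - 1L)
  win <- series[win_idx[win_idx >= 1L]]
  win <- win[!is.na(win)]
  if (length(win)) {
    m <- sum(win) / length(win)
    out$roll3_diff <- v - m
    if (m != 0) out$roll3_pct <- 100 * (v - m) / m
  }
  prior <- series[seq_len(k - 1L)]
  prior <- prior[!is.na(prior)]
  if (length(prior)) {
    out$max_diff <- v - max(prior)
    out$min_diff <- v - min(prior)
  }
  out
}

## Minute-stream builder for one patient-day.
make_minutes <- function(patient_id = "P1", pod = 1L, minute, hr_bpm,
                         steps = 0L) {
  data.table(patient_id = patient_id, pod = as.integer(pod),
             minute = as.integer(minute),
             hr_bpm = as.integer(hr_bpm),
             steps = as.integer(rep_len(steps, length(minute))))
}

## One-row patient roster with sensible defaults.
make_patient <- function(patient_id = "P1", group = "complicated",
                         age_years = 10, sex = "female",
                         race_ethnicity = "hispanic_latinx",
                         weight_kg = 35, height_cm = 140,
                         device = "inspire_hr", length_of_stay_days = 2.6,
                         monitoring_days = 21L) {
  data.table(patient_id = patient_id, group = group, age_years = age_years,
             sex = sex, race_ethnicity = race_ethnicity,
             weight_kg = weight_kg, height_cm = height_cm, device = device,
             length_of_stay_days = length_of_stay_days,
             monitoring_days = as.integer(monitoring_days),
             surgery_date = as.Date("2021-03-01"))
}

empty_events <- function() {
  data.table(patient_id = character(), pod = integer(),
             category = character(), clavien_grade = character(),
             nsqip = logical())
}

make_events <- function(patient_id, pod, category = "symptom",
                        clavien_grade = "I", nsqip = FALSE) {
  data.table(patient_id = patient_id, pod = as.integer(pod),
             category = rep_len(category, length(pod)),
             clavien_grade = rep_len(clavien_grade, length(pod)),
             nsqip = rep_len(nsqip, length(pod)))
}

## A small config that generates quickly: few patients, thin wear.
quick_config <- function(..., n_complicated = 4L, n_simple = 3L, seed = 1L) {
  cohort_config(
    n_complicated = n_complicated, n_simple = n_simple, seed = seed,
    wear_model = list(mean_hours = c(complicated = 3, simple = 3),
                      sd_hours = c(complicated = 0.5, simple = 0.5),
                      max_hours = 18, sleep_missing_prob = 0.15),
    ...
  )
}

## Fully-worn config: every day has 18 h of wear, so no day fails any
## wear-time filter and no day is missing.
full_wear_config <- function(..., seed = 1L) {
  cohort_config(
    seed = seed,
    wear_model = list(mean_hours = c(complicated = 18, simple = 18),
                      sd_hours = c(complicated = 0, simple = 0),
                      max_hours = 18, sleep_missing_prob = 0),
    ...
  )
}
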
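#' Write a cohort to Fitabase-style CSV files
#'
#' Serializes a cohort (synthetic or otherwise) to five CSV files in `dir`:
#' `patients.csv`, `events.csv`, `minute_hr.csv`
#' (`patient_id,timestamp,hr_bpm`), `minute_steps.csv`
#' (`patient_id,timestamp,steps`) and `daily_summary.csv` (one row per
#' patient-day with the daily activity/sleep fields). Timestamps are
#' ISO-8601 local at minute resolution, derived from each patient's surgery
#' date (POD d, minute m maps to `surgery_date + d` days at minute m).
#' Output is deterministic: the same cohort writes byte-identical files.
#'
#' @param cohort A `wearable_cohort` or a list with `patients`, `events`,
#'   `minutes`, `summaries`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @seealso [read_cohort_csv()]
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- as.data.table(cohort$patients)
  stamp <- function(m) {
    base <- pat[match(m$patient_id, pat$patient_id), surgery_date]
    sprintf("%sT%02d:%02d:00", format(base + m$pod), m$minute %/% 60L,
            m$minute %% 60L)
  }
  minutes <- as.data.table(cohort$minutes)
  hr <- minutes[, .(patient_id, timestamp = stamp(.SD), hr_bpm)]
  st <- minutes[, .(patient_id, timestamp = stamp(.SD), steps)]
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    events = file.path(dir, "events.csv"),
    minute_hr = file.path(dir, "minute_hr.csv"),
    minute_steps = file.path(dir, "minute_steps.csv"),
    daily_summary = file.path(dir, "daily_summary.csv")
  )
  fwrite(pat, paths["patients"])
  fwrite(as.data.table(cohort$events), paths["events"])
  fwrite(hr, paths["minute_hr"])
  fwrite(st, paths["minute_steps"])
  fwrite(as.data.table(cohort$summaries), paths["daily_summary"])
  invisible(paths)
}

#' Read a cohort from Fitabase-style CSV files
#'
#' Inverse of [write_cohort_csv()]: reads the five-file CSV dialect back into
#' the in-memory representation (minute timestamps are converted to
#' postoperative day + minute-of-day using each patient's surgery date).
#'
#' @param dir Directory containing the CSV files.
#' @return A `wearable_cohort`-shaped list (without a config).
#' @export
read_cohort_csv <- function(dir) {
  patients <- fread(file.path(dir, "patients.csv"),
                    colClasses = list(character = "patient_id"))
  patients[, surgery_date := as.Date(surgery_date)]
  events <- fread(file.path(dir, "events.csv"),
                  colClasses = list(character = "patient_id"))
  unstamp <- function(x) {
    base <- patients[match(x$patient_id, patients$patient_id), surgery_date]
    d <- as.Date(substr(x$timestamp, 1, 10))
    x[, pod := as.integer(d - base)]
    x[, minute := as.integer(substr(timestamp, 12, 13)) * 60L +
        as.integer(substr(timestamp, 15, 16))]
    x[, timestamp := NULL]
    x
  }
  hr <- unstamp(fread(file.path(dir, "minute_hr.csv"),
                      colClasses = list(character = c("patient_id",
                                                      "timestamp"))))
  st <- unstamp(fread(file.path(dir, "minute_steps.csv"),
                      colClasses = list(character = c("patient_id",
                                                      "timestamp"))))
  minutes <- merge(hr, st, by = c("patient_id", "pod", "minute"),
                   all = TRUE)
  setorder(minutes, patient_id, pod, minute)
  summaries <- fread(file.path(dir, "daily_summary.csv"),
                     colClasses = list(character = "patient_id"))
  structure(list(patients = patients, events = events, minutes = minutes,
                 summaries = summaries),
            class = "wearable_cohort")
}
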
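#' Classify a postoperative event as symptom or complication
#'
#' An event counts as a confirmed complication iff it is on the NSQIP
#' complication list; every other reported event is an abnormal symptom.
#' Both categories are "postoperative events" and generate ground-truth
#' abnormal windows identically. Grade IV/V events are accepted but flagged
#' with a warning, as they are exceedingly rare after appendectomy.
#'
#' @param clavien_grade Character vector of Clavien-Dindo grades
#'   (`"I"`..`"V"`).
#' @param nsqip Logical vector: is the event an NSQIP-defined complication?
#' @return Character vector, `"symptom"` or `"complication"`.
#' @export
#' @examples
#' classify_event(c("I", "III"), c(FALSE, TRUE))
classify_event <- function(clavien_grade, nsqip) {
  if (!all(clavien_grade %in% c("I", "II", "III", "IV", "V")))
    stop("clavien_grade must be one of I, II, III, IV, V")
  if (any(clavien_grade %in% c("IV", "V")))
    warning("Grade IV/V events are exceedingly rare after appendectomy")
  ifelse(nsqip, "complication", "symptom")
}

#' Ground-truth day labels from a postoperative event log
#'
#' Labels every postoperative day of every patient as `normal`, `abnormal`,
#' or `excluded`. For an event reported on POD k, the 1-2 preceding days
#' that exist (PODs k-2 and k-1, those >= 1) are `abnormal` and the event
#' day itself is `excluded` from training and testing; an event on POD 2
#' yields a single abnormal day (POD 1), and an event on POD 1 yields none.
#' All remaining days are `normal`. When rules collide the precedence is
#' `excluded` > `abnormal` > `normal`, so a day that is both an event day
#' and inside another event's pre-event window stays excluded. Duplicate
#' event records (same patient, POD, category) are collapsed with a warning.
#'
#' @param events Event log data.table (`patient_id`, `pod`, `category`).
#' @param monitoring_days Days in the monitoring window (POD 1..n).
#' @param patient_ids Patients to label; defaults to those present in
#'   `events`, but pass the full roster so event-free patients receive
#'   all-normal labels.
#' @return data.table (`patient_id`, `pod`, `label`) with exactly one row
#'   per patient-day.
#' @export
#' @examples
#' ev <- data.table::data.table(patient_id = "A", pod = 5L,
#'                              category = "symptom")
#' table(label_days(ev, 21L)$label)
label_days <- function(events, monitoring_days = 21L, patient_ids = NULL) {
  events <- as.data.table(events)
  if (is.null(patient_ids)) patient_ids <- unique(events$patient_id)
  if (nrow(events)) {
    if (any(events$pod < 1L | events$pod > monitoring_days))
      stop(sprintf("event pod outside monitoring window 1..%d",
                   monitoring_days))
    dup <- duplicated(events[, .(patient_id, pod, category)])
    if (any(dup)) {
      warning(sprintf("collapsed %d duplicate event record(s)", sum(dup)))
      events <- events[!dup]
    }
  }
  labels <- CJ(patient_id = unique(patient_ids),
               pod = seq_len(monitoring_days))
  labels[, label := "normal"]
  if (nrow(events)) {
    abn <- rbindlist(list(events[, .(patient_id, pod = pod - 1L)],
                          events[, .(patient_id, pod = pod - 2L)]))
    abn <- unique(abn[pod >= 1L])
    labels[abn, on = c("patient_id", "pod"), label := "abnormal"]
    labels[unique(events[, .(patient_id, pod)]), on = c("patient_id", "pod"),
           label := "excluded"]
  }
  setorder(labels, patient_id, pod)
  labels[]
}

#' Assemble the modeling table from features, wear records, and labels
#'
#' Joins the feature matrix with its ground-truth labels and keeps the
#' patient-days eligible for model training and testing: days on which any
#' wearable data were recorded and whose label is not `excluded`. When
#' `min_wear_hours` is set (the wear-time sensitivity analysis), days below
#' the threshold are additionally dropped, while days with sufficient wear
#' before and after an excluded or dropped day keep their original labels.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param wear Wear table from [build_feature_matrix()].
#' @param labels Label table from [label_days()].
#' @param min_wear_hours Optional minimum waking-window wear time (hours).
#' @return data.table with `patient_id`, `pod`, `label`
#'   (`"normal"`/`"abnormal"`), `wear_hours_waking`, then all feature
#'   columns.
#' @export
assemble_dataset <- function(features, wear, labels, min_wear_hours = NULL) {
  features <- as.data.table(features)
  wear <- as.data.table(wear)
  labels <- as.data.table(labels)
  out <- copy(features)
  out[labels, on = c("patient_id", "pod"), label := i.label]
  if (anyNA(out$label))
    stop("label missing for an included patient-day")
  out[wear, on = c("patient_id", "pod"),
      wear_hours_waking := i.wear_hours_waking]
  out <- out[label != "excluded"]
  if (!is.null(min_wear_hours))
    out <- out[wear_hours_waking >= min_wear_hours]
  setcolorder(out, c("patient_id", "pod", "label", "wear_hours_waking"))
  setorder(out, patient_id, pod)
  out[]
}

#' Per-group day and abnormal-day counts of a modeling table
#'
#' @param dataset Modeling table from [assemble_dataset()].
#' @param patients Patient roster (for the group assignment).
#' @return data.table with `group`, `n_days`, `n_abnormal`.
#' @export
dataset_summary <- function(dataset, patients) {
  patients <- as.data.table(patients)
  d <- as.data.table(dataset)[patients[, .(patient_id, group)],
                              on = "patient_id", nomatch = NULL]
  d[, .(n_days = .N, n_abnormal = sum(label == "abnormal")), by = .(group)]
}
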
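#' Configuration for the synthetic post-appendectomy cohort generator
#'
#' Builds and validates the full parameter set used by [generate_cohort()].
#' Defaults emulate a 21-day postoperative monitoring study of children
#' (ages 3-17) after laparoscopic appendectomy, with two disease-severity
#' groups: `complicated` (perforation/phlegmon/abscess at surgery; slower
#' recovery, longer stay, more postoperative events) and `simple`.
#'
#' Default event rates are 41/85 events per complicated patient and 10/76 per
#' simple patient; Clavien-Dindo grade mixes default to 22/14/5 (I/II/III) for
#' complicated and 9/0/1 for simple. Daily wear time is drawn around
#' 12.8 h (complicated) and 12.3 h (simple). Device assignment defaults to
#' 69/85 and 43/76 Inspire HR. Activity recovers along a group-specific
#' logistic ramp from a postoperative nadir toward an age-scaled plateau.
#'
#' @param n_complicated,n_simple Number of patients per severity group.
#' @param monitoring_days Length of the postoperative monitoring window in
#'   days (POD 1..`monitoring_days`; POD 0 is the day of surgery).
#' @param event_rate Named numeric, expected postoperative events per patient
#'   for `complicated` and `simple` patients (Poisson counts, event days
#'   uniform over the monitoring window).
#' @param grade_mix Named list with one probability vector per group over
#'   Clavien-Dindo grades `I`..`V`.
#' @param nsqip_prob Named numeric, probability that an event of each grade is
#'   an NSQIP-defined complication (grade I events never are; grade III
#'   interventions always are).
#' @param pre_event_effect List with `step_suppression` (fraction in \[0,1\]
#'   removed from step counts on the 1-2 days before each event) and
#'   `hr_elevation` (bpm added to minute heart rate on those days). The study
#'   data carry no published effect size for this perturbation; the defaults
#'   (0.5 / 15 bpm) are the package's canonical strong-signal demonstration
#'   and are free parameters.
#' @param wear_model List with per-group `mean_hours`/`sd_hours` of daily wear
#'   time, `max_hours` (the 06:00-24:00 waking window is 18 h), and
#'   `sleep_missing_prob` (chance a worn day has no sleep record).
#' @param recovery_model List with `nadir_frac` (activity floor as a fraction
#'   of plateau), `plateau_steps` (daily steps at full recovery for a
#'   10-year-old; scaled by age), per-group logistic `midpoint_pod` and
#'   `scale_days`, and `noise_sdlog` (log-normal day-to-day variability).
#' @param device_prob_inspire_hr Named numeric, per-group probability of the
#'   Inspire HR device (the remainder wear the Inspire 2).
#' @param intensity_thresholds Steps-per-minute cut points `light`, `fairly`,
#'   `very` used to partition worn minutes into intensity classes.
#' @param base_date Calendar date of surgery (shared across patients; used
#'   only to render ISO-8601 timestamps in CSV output).
#' @param seed Integer seed; a fixed seed makes the generated cohort
#'   bit-identical across runs.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_complicated = 4, n_simple = 3, seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$patients)
cohort_config <- function(n_complicated = 85L,
                          n_simple = 76L,
                          monitoring_days = 21L,
                          event_rate = c(complicated = 41 / 85, simple = 10 / 76),
                          grade_mix = list(
                            complicated = c(I = 22, II = 14, III = 5, IV = 0, V = 0) / 41,
                            simple = c(I = 9, II = 0, III = 1, IV = 0, V = 0) / 10
                          ),
                          nsqip_prob = c(I = 0, II = 0.75, III = 1, IV = 1, V = 1),
                          pre_event_effect = list(step_suppression = 0.5,
                                                  hr_elevation = 15),
                          wear_model = list(
                            mean_hours = c(complicated = 12.8, simple = 12.3),
                            sd_hours = c(complicated = 6.0, simple = 6.3),
                            max_hours = 18,
                            sleep_missing_prob = 0.15
                          ),
                          recovery_model = list(
                            nadir_frac = 0.2,
                            plateau_steps = 10000,
                            midpoint_pod = c(complicated = 10, simple = 4),
                            scale_days = c(complicated = 2.5, simple = 1.5),
                            noise_sdlog = 0.25
                          ),
                          device_prob_inspire_hr = c(complicated = 69 / 85,
                                                     simple = 43 / 76),
                          intensity_thresholds = c(light = 4, fairly = 33, very = 67),
                          base_date = as.Date("2021-03-01"),
                          seed = 1L) {
  cfg <- list(
    n_complicated = as.integer(n_complicated),
    n_simple = as.integer(n_simple),
    monitoring_days = as.integer(monitoring_days),
    event_rate = event_rate,
    grade_mix = grade_mix,
    nsqip_prob = nsqip_prob,
    pre_event_effect = pre_event_effect,
    wear_model = wear_model,
    recovery_model = recovery_model,
    device_prob_inspire_hr = device_prob_inspire_hr,
    intensity_thresholds = intensity_thresholds,
    base_date = as.Date(base_date),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_config field `%s`: %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_complicated) || cfg$n_complicated < 0L)
    stop_field("n_complicated", "must be a non-negative integer")
  if (is.na(cfg$n_simple) || cfg$n_simple < 0L)
    stop_field("n_simple", "must be a non-negative integer")
  if (cfg$n_complicated + cfg$n_simple < 1L)
    stop_field("n_complicated", "cohort must contain at least one patient")
  if (is.na(cfg$monitoring_days) || cfg$monitoring_days < 1L)
    stop_field("monitoring_days", "must be >= 1")
  for (g in c("complicated", "simple")) {
    if (!g %in% names(cfg$event_rate) || cfg$event_rate[[g]] < 0)
      stop_field("event_rate", sprintf("missing or negative rate for `%s`", g))
    mix <- cfg$grade_mix[[g]]
    if (is.null(mix) || !all(c("I", "II", "III", "IV", "V") %in% names(mix)))
      stop_field("grade_mix", sprintf("grades I..V required for `%s`", g))
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      stop_field("grade_mix", sprintf("probabilities for `%s` must sum to 1", g))
    p <- cfg$device_prob_inspire_hr[[g]]
    if (is.null(p) || p < 0 || p > 1)
      stop_field("device_prob_inspire_hr", sprintf("`%s` must be in [0,1]", g))
  }
  eff <- cfg$pre_event_effect
  if (is.null(eff$step_suppression) || eff$step_suppression < 0 ||
      eff$step_suppression > 1)
    stop_field("pre_event_effect", "step_suppression must be in [0,1]")
  if (is.null(eff$hr_elevation) || eff$hr_elevation < 0)
    stop_field("pre_event_effect", "hr_elevation must be >= 0")
  wm <- cfg$wear_model
  if (is.null(wm$max_hours) || wm$max_hours <= 0 || wm$max_hours > 24)
    stop_field("wear_model", "max_hours must be in (0,24]")
  if (any(wm$mean_hours < 0) || any(wm$sd_hours < 0))
    stop_field("wear_model", "mean_hours/sd_hours must be non-negative")
  rm_ <- cfg$recovery_model
  if (rm_$nadir_frac < 0 || rm_$nadir_frac > 1)
    stop_field("recovery_model", "nadir_frac must be in [0,1]")
  if (rm_$plateau_steps <= 0)
    stop_field("recovery_model", "plateau_steps must be positive")
  th <- cfg$intensity_thresholds
  if (!all(c("light", "fairly", "very") %in% names(th)) ||
      !(th["light"] < th["fairly"] && th["fairly"] < th["very"]))
    stop_field("intensity_thresholds", "need light < fairly < very")
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  invisible(cfg)
}
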
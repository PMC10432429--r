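#' Run the full analysis pipeline end to end
#'
#' Orchestrates simulate -> features -> label -> train/evaluate for a
#' synthetic cohort: generates the cohort from `config`, builds the feature
#' matrix and wear table, derives ground-truth labels, fits the balanced
#' random forest under leave-one-subject-out cross-validation separately
#' for the complicated and simple groups (the default; a pooled model is
#' sensitivity analysis 4), and evaluates each group. When `out_dir` is
#' given, all tables, per-group reports, and a run manifest with file
#' digests are written there; re-running with the same config reproduces
#' identical digests.
#'
#' @param config A [cohort_config()].
#' @param params A [model_params()].
#' @param out_dir Optional output directory.
#' @param groups Patient groups to model.
#' @param sensitivity Character vector of [run_sensitivity()] variants to
#'   run after the main models.
#' @param ci_reps Bootstrap repetitions for report CIs.
#' @return List with `cohort`, `features`, `wear`, `labels`, `reports`
#'   (per group), `sensitivity` (per variant), and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         params = model_params(seed = config$seed),
                         out_dir = NULL,
                         groups = c("complicated", "simple"),
                         sensitivity = character(),
                         ci_reps = 1000L) {
  stage <- "simulate"
  result <- tryCatch({
    cohort <- generate_cohort(config)
    stage <- "features"
    fm <- build_feature_matrix(cohort$patients, cohort$events,
                               cohort$minutes, cohort$summaries)
    stage <- "label"
    labels <- label_days(cohort$events, config$monitoring_days,
                         patient_ids = cohort$patients$patient_id)
    stage <- "train-eval"
    reports <- setNames(lapply(groups, function(g) {
      run_group_analysis(fm$features, fm$wear, labels, cohort$events,
                         cohort$patients, params, group = g,
                         ci_reps = ci_reps)
    }), groups)
    stage <- "sensitivity"
    sens <- setNames(lapply(sensitivity, function(v) {
      run_sensitivity(v, fm$features, fm$wear, labels, cohort$events,
                      cohort$patients, params, groups = groups,
                      ci_reps = ci_reps)
    }), sensitivity)
    list(cohort = cohort, features = fm$features, wear = fm$wear,
         labels = labels, reports = reports, sensitivity = sens)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(result$cohort, out_dir)
    fwrite(result$features, file.path(out_dir, "features.csv"))
    fwrite(result$wear, file.path(out_dir, "wear.csv"))
    fwrite(result$labels, file.path(out_dir, "labels.csv"))
    for (g in names(result$reports)) {
      rp <- result$reports[[g]]
      if (is.null(rp)) next
      write_report(rp, file.path(out_dir, sprintf("report_%s.json", g)))
    }
    result$manifest <- write_manifest(config, params, out_dir)
  }
  result
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$missed_events <- if (nrow(x$missed_events)) as.data.frame(x$missed_events)
  x$importance <- if (!is.null(x$importance)) as.data.frame(x$importance)
  x$auroc_ci <- as.numeric(x$auroc_ci)
  x$auprc_ci <- as.numeric(x$auprc_ci)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

write_manifest <- function(config, params, out_dir) {
  files <- sort(list.files(out_dir, pattern = "\\.(csv|json)$",
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "base_date")],
    base_date = format(config$base_date),
    params = unclass(params),
    digests = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Validate a directory of cohort CSV files
#'
#' Schema and invariant checks over the five-file CSV dialect: required
#' columns, id uniqueness and referential integrity, age and monitoring
#' windows, event PODs inside the window, non-negative counts, sleep-time
#' consistency, and minute-timestamp alignment. Problems are collected and
#' returned, not thrown.
#'
#' @param dir Directory holding `patients.csv`, `events.csv`,
#'   `minute_hr.csv`, `minute_steps.csv`, `daily_summary.csv`.
#' @return data.table of diagnostics (`file`, `row`, `problem`); zero rows
#'   means the directory is valid.
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory `%s` does not exist", dir))
  diags <- list()
  note <- function(file, rows, problem) {
    if (length(rows) == 0L) return(invisible())
    diags[[length(diags) + 1L]] <<- data.table(file = file,
                                               row = as.integer(rows),
                                               problem = problem)
  }
  read_or_note <- function(name, required) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      note(name, NA, "file missing")
      return(NULL)
    }
    chr_cols <- intersect(c("patient_id", "timestamp"), required)
    x <- tryCatch(fread(path, colClasses = list(character = chr_cols)),
                  error = function(e) {
                    note(name, NA, paste("malformed CSV:",
                                         conditionMessage(e)))
                    NULL
                  })
    if (!is.null(x)) {
      miss <- setdiff(required, names(x))
      if (length(miss)) {
        note(name, NA, paste("missing column(s):",
                             paste(miss, collapse = ", ")))
        return(NULL)
      }
    }
    x
  }
  pat <- read_or_note("patients.csv",
                      c("patient_id", "group", "age_years",
                        "length_of_stay_days", "monitoring_days"))
  if (!is.null(pat)) {
    note("patients.csv", which(duplicated(pat$patient_id)),
         "duplicate patient_id")
    note("patients.csv", which(pat$age_years < 3 | pat$age_years > 17),
         "age_years outside [3,17]")
    note("patients.csv", which(pat$length_of_stay_days < 0),
         "negative length_of_stay_days")
    note("patients.csv", which(pat$monitoring_days < 1),
         "monitoring_days < 1")
  }
  ev <- read_or_note("events.csv",
                     c("patient_id", "pod", "category", "clavien_grade",
                       "nsqip"))
  if (!is.null(ev) && !is.null(pat)) {
    mwin <- pat$monitoring_days[match(ev$patient_id, pat$patient_id)]
    note("events.csv", which(is.na(mwin)), "patient_id not in roster")
    note("events.csv", which(!is.na(mwin) & (ev$pod < 1 | ev$pod > mwin)),
         "event pod outside monitoring window")
    note("events.csv", which(ev$nsqip & ev$category != "complication"),
         "nsqip event not categorized as complication")
    note("events.csv",
         which(!ev$clavien_grade %in% c("I", "II", "III", "IV", "V")),
         "invalid clavien_grade")
  }
  summ <- read_or_note("daily_summary.csv",
                       c("patient_id", "pod", "total_steps"))
  if (!is.null(summ)) {
    num_cols <- setdiff(names(summ)[vapply(summ, is.numeric, logical(1))],
                        "pod")
    for (cn in num_cols)
      note("daily_summary.csv", which(summ[[cn]] < 0),
           sprintf("negative %s", cn))
    if (all(c("total_min_asleep", "total_min_in_bed") %in% names(summ))) {
      note("daily_summary.csv",
           which(!is.na(summ$total_min_asleep) &
                   !is.na(summ$total_min_in_bed) &
                   summ$total_min_asleep > summ$total_min_in_bed),
           "total_min_asleep > total_min_in_bed")
    }
  }
  for (name in c("minute_hr.csv", "minute_steps.csv")) {
    valcol <- if (name == "minute_hr.csv") "hr_bpm" else "steps"
    m <- read_or_note(name, c("patient_id", "timestamp", valcol))
    if (is.null(m)) next
    note(name, which(m[[valcol]] < 0), sprintf("negative %s", valcol))
    if (!is.null(pat))
      note(name, which(!m$patient_id %in% pat$patient_id),
           "patient_id not in roster")
    note(name,
         which(!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:00$",
                      m$timestamp)),
         "timestamp not minute-aligned ISO-8601")
  }
  if (length(diags)) rbindlist(diags) else
    data.table(file = character(), row = integer(), problem = character())
}
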
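#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Equals the probability that a randomly chosen abnormal day outscores a
#' randomly chosen normal day, with ties counted one half; computed from
#' midranks, which is exact for any tie structure.
#'
#' @param scores Numeric scores (higher = more abnormal).
#' @param labels Logical/0-1/`"abnormal"` indicator of the positive class.
#' @return AUROC in \[0,1\]; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  pos <- as_positive(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Interpolation-free step integration: summing
#' `(recall_k - recall_{k-1}) * precision_k` over distinct score thresholds
#' in decreasing order. A random scorer has expected AUPRC equal to the
#' positive-class prevalence.
#'
#' @inheritParams auroc
#' @return Average precision in \[0,1\]; `NA` if no positives are present.
#' @export
auprc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (sum(pos) == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last_of_threshold <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_threshold]
  fp <- fp[last_of_threshold]
  recall <- tp / sum(pos)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

as_positive <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.character(labels) == "abnormal"
  else as.logical(labels)
}

#' Confusion matrix and percent-correct rates over included days
#'
#' @param predicted Predicted labels (`"normal"`/`"abnormal"`).
#' @param truth Ground-truth labels; `excluded` days must be filtered out
#'   upstream and are rejected here.
#' @return List with counts `tn`, `fp`, `fn`, `tp` and
#'   `pct_normal_correct`, `pct_abnormal_correct` (percentages; `NA` when a
#'   class is empty).
#' @export
confusion_and_rates <- function(predicted, truth) {
  if (any(truth == "excluded"))
    stop("excluded days must be filtered out before evaluation")
  pos <- as_positive(truth)
  hat <- as_positive(predicted)
  tp <- sum(pos & hat); fn <- sum(pos & !hat)
  tn <- sum(!pos & !hat); fp <- sum(!pos & hat)
  list(tn = tn, fp = fp, fn = fn, tp = tp,
       pct_normal_correct = if (tn + fp > 0) 100 * tn / (tn + fp)
                            else NA_real_,
       pct_abnormal_correct = if (tp + fn > 0) 100 * tp / (tp + fn)
                              else NA_real_)
}

#' Patient-level bootstrap confidence interval for a pooled metric
#'
#' Resamples patients with replacement, pools their out-of-fold day scores,
#' and takes the percentile interval of the metric over the resamples. This
#' respects the within-patient correlation of days. Degenerate resamples in
#' which only one class is present are skipped; if more than half of the
#' resamples are degenerate the interval is reported missing.
#'
#' @param predictions data.table with `patient_id`, `score`, `label`.
#' @param metric `"auroc"` or `"auprc"` (or a function
#'   `(scores, labels) -> number`).
#' @param level Confidence level (default 0.90).
#' @param reps Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`, with attribute `n_degenerate`.
#' @export
bootstrap_ci <- function(predictions, metric = "auroc", level = 0.90,
                         reps = 1000L, seed = 1L) {
  predictions <- as.data.table(predictions)
  fn <- if (is.function(metric)) metric else
    switch(metric, auroc = auroc, auprc = auprc,
           stop("unknown metric: ", metric))
  by_pat <- split(predictions[, .(score, label)], predictions$patient_id)
  pats <- names(by_pat)
  set.seed(seed)
  vals <- rep(NA_real_, reps)
  for (b in seq_len(reps)) {
    take <- sample(pats, length(pats), replace = TRUE)
    pool <- rbindlist(by_pat[take])
    pos <- as_positive(pool$label)
    if (all(pos) || !any(pos)) next
    vals[b] <- fn(pool$score, pool$label)
  }
  n_bad <- sum(is.na(vals))
  if (n_bad > reps / 2) {
    ci <- c(NA_real_, NA_real_)
  } else {
    ci <- unname(quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE))
  }
  attr(ci, "n_degenerate") <- n_bad
  ci
}

#' Event-level early-detection rates (d-2, d-1, d_ANY)
#'
#' An event on POD k is detected at d-2 (d-1) iff the model predicted
#' abnormal on POD k-2 (k-1) and that day exists in the modeling table.
#' Only events with at least one existing labeled prior day enter any
#' denominator; additionally the d-2 denominator excludes events on
#' POD <= 2 and the d-1 denominator excludes events on POD 1 (no such prior
#' day exists after surgery). Events in the d_ANY denominator that are
#' detected on neither prior day are listed as missed with their
#' Clavien-Dindo grade.
#'
#' @param predictions data.table with `patient_id`, `pod`, `predicted` for
#'   every included day.
#' @param events Event log (`patient_id`, `pod`, `clavien_grade`).
#' @return List with `d_minus2_pct`, `d_minus1_pct`, `d_any_pct` (each with
#'   explicit `n`/`den` entries), `n_events_missed`, and `missed`
#'   (data.table of missed events).
#' @export
event_detection <- function(predictions, events) {
  predictions <- as.data.table(predictions)
  events <- as.data.table(events)
  bad <- setdiff(unique(events$patient_id), unique(predictions$patient_id))
  if (length(bad))
    stop(sprintf("event patient(s) absent from predictions: %s",
                 paste(bad, collapse = ", ")))
  if (nrow(events) == 0L) {
    return(list(d_minus2_pct = NA_real_, d_minus1_pct = NA_real_,
                d_any_pct = NA_real_,
                d_minus2 = c(n = 0L, den = 0L),
                d_minus1 = c(n = 0L, den = 0L),
                d_any = c(n = 0L, den = 0L),
                n_events_missed = 0L,
                missed = events))
  }
  abn <- predictions[predicted == "abnormal", .(patient_id, pod)]
  present <- predictions[, .(patient_id, pod)]
  ev <- copy(events)
  day_exists <- function(offset) {
    q <- ev[, .(patient_id, pod = pod - offset)]
    !is.na(present[q, on = c("patient_id", "pod"), which = TRUE])
  }
  day_hit <- function(offset) {
    q <- ev[, .(patient_id, pod = pod - offset)]
    !is.na(abn[q, on = c("patient_id", "pod"), which = TRUE])
  }
  ev[, `:=`(exists2 = day_exists(2L) & pod - 2L >= 1L,
            exists1 = day_exists(1L) & pod - 1L >= 1L)]
  ev[, `:=`(hit2 = day_hit(2L) & exists2, hit1 = day_hit(1L) & exists1)]
  ev[, eligible := exists2 | exists1]
  den2 <- ev[eligible & pod > 2L]
  den1 <- ev[eligible & pod > 1L]
  dena <- ev[eligible == TRUE]
  missed <- dena[!(hit2 | hit1),
                 .(patient_id, pod, category, clavien_grade)]
  pct <- function(n, den) if (den > 0L) 100 * n / den else NA_real_
  list(
    d_minus2_pct = pct(sum(den2$hit2), nrow(den2)),
    d_minus1_pct = pct(sum(den1$hit1), nrow(den1)),
    d_any_pct = pct(sum(dena$hit2 | dena$hit1), nrow(dena)),
    d_minus2 = c(n = sum(den2$hit2), den = nrow(den2)),
    d_minus1 = c(n = sum(den1$hit1), den = nrow(den1)),
    d_any = c(n = sum(dena$hit2 | dena$hit1), den = nrow(dena)),
    n_events_missed = nrow(missed),
    missed = missed
  )
}

#' Average Gini importance across cross-validation folds
#'
#' Means the per-fold Gini importances over folds (features pruned in a
#' fold contribute 0 there), normalizes the means to sum to one, and ranks
#' features in decreasing order.
#'
#' @param importance data.table (`fold_id`, `feature`, `importance`) as
#'   returned by [loso_cv()].
#' @param top_k Optionally keep only the `top_k` highest-ranked features.
#' @return data.table (`feature`, `importance`) sorted decreasing.
#' @export
average_importance <- function(importance, top_k = NULL) {
  imp <- as.data.table(importance)[, .(importance = mean(importance)),
                                   by = .(feature)]
  tot <- sum(imp$importance)
  if (tot > 0) imp[, importance := importance / tot]
  setorder(imp, -importance)
  if (!is.null(top_k)) imp <- head(imp, top_k)
  imp[]
}

#' Full performance report for a set of out-of-fold predictions
#'
#' Computes the pooled confusion matrix and percent-correct rates, pooled
#' AUROC and AUPRC with patient-level bootstrap confidence intervals, the
#' prevalence baseline (the AUPRC of a random scorer), event-level
#' d-2/d-1/d_ANY detection rates with the missed-event list, and the
#' averaged Gini feature-importance ranking.
#'
#' @param result A `loso_result` from [loso_cv()], or a predictions
#'   data.table with `patient_id`, `pod`, `label`, `score`, `predicted`.
#' @param events Event log for the evaluated patients.
#' @param ci_level,ci_reps,ci_seed Bootstrap CI parameters.
#' @param importance Optional importance table when `result` is a plain
#'   predictions table.
#' @return List of class `eval_report`.
#' @export
evaluate_predictions <- function(result, events, ci_level = 0.90,
                                 ci_reps = 1000L, ci_seed = 1L,
                                 importance = NULL) {
  if (inherits(result, "loso_result")) {
    predictions <- result$predictions
    importance <- result$importance
  } else {
    predictions <- as.data.table(result)
  }
  conf <- confusion_and_rates(predictions$predicted, predictions$label)
  n_days <- nrow(predictions)
  n_abn <- sum(as_positive(predictions$label))
  det <- event_detection(predictions, events)
  rep_ <- list(
    n_included_days = n_days,
    n_abnormal_days = n_abn,
    confusion = conf[c("tn", "fp", "fn", "tp")],
    pct_normal_correct = conf$pct_normal_correct,
    pct_abnormal_correct = conf$pct_abnormal_correct,
    auroc = auroc(predictions$score, predictions$label),
    auroc_ci = bootstrap_ci(predictions, "auroc", ci_level, ci_reps, ci_seed),
    auprc = auprc(predictions$score, predictions$label),
    auprc_ci = bootstrap_ci(predictions, "auprc", ci_level, ci_reps, ci_seed),
    baseline_auprc = if (n_days > 0L) n_abn / n_days else NA_real_,
    d_minus2_pct = det$d_minus2_pct,
    d_minus1_pct = det$d_minus1_pct,
    d_any_pct = det$d_any_pct,
    d_minus2 = det$d_minus2,
    d_minus1 = det$d_minus1,
    d_any = det$d_any,
    n_events_missed = det$n_events_missed,
    missed_events = det$missed,
    importance = if (!is.null(importance)) average_importance(importance)
  )
  class(rep_) <- "eval_report"
  rep_
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  included days: %d (%d abnormal; baseline AUPRC %.3f)\n",
              x$n_included_days, x$n_abnormal_days, x$baseline_auprc))
  cat(sprintf("  confusion: TN=%d FP=%d FN=%d TP=%d\n",
              x$confusion$tn, x$confusion$fp, x$confusion$fn,
              x$confusion$tp))
  cat(sprintf("  %% correct: normal %.0f%%, abnormal %.0f%%\n",
              x$pct_normal_correct, x$pct_abnormal_correct))
  cat(sprintf("  AUROC %.3f [%.3f, %.3f]; AUPRC %.3f [%.3f, %.3f]\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2],
              x$auprc, x$auprc_ci[1], x$auprc_ci[2]))
  cat(sprintf("  events detected: d-2 %.0f%% (%d/%d), d-1 %.0f%% (%d/%d), d_ANY %.0f%% (%d/%d); %d missed\n",
              x$d_minus2_pct, x$d_minus2["n"], x$d_minus2["den"],
              x$d_minus1_pct, x$d_minus1["n"], x$d_minus1["den"],
              x$d_any_pct, x$d_any["n"], x$d_any["den"],
              x$n_events_missed))
  if (!is.null(x$importance)) {
    top <- head(x$importance, 5L)
    cat("  top features:", paste(sprintf("%s (%.3f)", top$feature,
                                         top$importance),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the LOSO analysis and evaluation for one patient group
#'
#' Convenience wrapper: subsets the modeling inputs to one severity group
#' (or pools both), assembles the dataset, runs [loso_cv()], and evaluates
#' against that group's events.
#'
#' @param features,wear,labels Tables from [build_feature_matrix()] and
#'   [label_days()].
#' @param events Event log.
#' @param patients Patient roster.
#' @param params A [model_params()].
#' @param group `"complicated"`, `"simple"`, or `"combined"`.
#' @param feature_cols Optional feature subset (e.g. clinical + demographics
#'   only).
#' @param min_wear_hours Optional wear-time threshold for day inclusion.
#' @param device Optional device filter (`"inspire_hr"` or `"inspire_2"`).
#' @param ci_reps Bootstrap repetitions for the report CIs.
#' @return An `eval_report`, or `NULL` with a message if the group is
#'   degenerate (fewer than 2 patients or a single class).
#' @export
run_group_analysis <- function(features, wear, labels, events, patients,
                               params = model_params(),
                               group = "complicated",
                               feature_cols = NULL,
                               min_wear_hours = NULL,
                               device = NULL,
                               ci_reps = 1000L) {
  patients <- as.data.table(patients)
  sel <- if (group == "combined") rep(TRUE, nrow(patients)) else
    patients[["group"]] == group
  if (!is.null(device)) sel <- sel & patients[["device"]] == device
  ids <- patients[["patient_id"]][sel]
  features <- as.data.table(features)[patient_id %in% ids]
  wear <- as.data.table(wear)[patient_id %in% ids]
  labels <- as.data.table(labels)[patient_id %in% ids]
  events <- as.data.table(events)[patient_id %in% ids]
  dataset <- assemble_dataset(features, wear, labels, min_wear_hours)
  n_classes <- length(unique(dataset$label))
  if (length(unique(dataset$patient_id)) < 2L || n_classes < 2L ||
      sum(dataset$label == "abnormal") < 2L) {
    message(sprintf(
      "group `%s`: degenerate dataset (%d patients, %d abnormal days); skipped",
      group, length(unique(dataset$patient_id)),
      sum(dataset$label == "abnormal")))
    return(NULL)
  }
  res <- loso_cv(dataset, params, feature_cols = feature_cols)
  evaluate_predictions(res, events, ci_reps = ci_reps,
                       ci_seed = params$seed)
}

#' Sensitivity analyses of the detection model
#'
#' Re-runs the full leave-one-subject-out pipeline under one of four
#' perturbations of the analysis:
#' \describe{
#'   \item{no_fitbit}{drop all wearable-derived features; train on clinical
#'     characteristics and demographics only}
#'   \item{min_wear_10h}{drop days with under 10 h of wear within the
#'     06:00-24:00 waking window}
#'   \item{device_inspire_hr / device_inspire_2}{restrict to patients with
#'     one device generation}
#'   \item{combined_groups}{pool both severity groups into one model}
#' }
#'
#' @param variant One of `"no_fitbit"`, `"min_wear_10h"`,
#'   `"device_inspire_hr"`, `"device_inspire_2"`, `"combined_groups"`.
#' @inheritParams run_group_analysis
#' @param groups Groups to run (ignored for `combined_groups`).
#' @return Named list of `eval_report`s (one per group; a single `combined`
#'   entry for `combined_groups`), tagged with the variant name.
#' @export
run_sensitivity <- function(variant, features, wear, labels, events,
                            patients, params = model_params(),
                            groups = c("complicated", "simple"),
                            ci_reps = 1000L) {
  variant <- match.arg(variant, c("no_fitbit", "min_wear_10h",
                                  "device_inspire_hr", "device_inspire_2",
                                  "combined_groups"))
  args <- list(features = features, wear = wear, labels = labels,
               events = events, patients = patients, params = params,
               ci_reps = ci_reps)
  if (variant == "no_fitbit")
    args$feature_cols <- c(demographic_feature_names(),
                           clinical_feature_names())
  if (variant == "min_wear_10h") args$min_wear_hours <- 10
  if (variant == "device_inspire_hr") args$device <- "inspire_hr"
  if (variant == "device_inspire_2") args$device <- "inspire_2"
  run_one <- function(g) do.call(run_group_analysis, c(args, group = g))
  out <- if (variant == "combined_groups")
    list(combined = run_one("combined"))
  else setNames(lapply(groups, run_one), groups)
  attr(out, "variant") <- variant
  out
}
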
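test_that("confusion rates follow from the counts", {
  perfect <- confusion_and_rates(c("abnormal", "normal"),
                                 c("abnormal", "normal"))
  expect_equal(perfect$pct_normal_correct, 100)
  expect_equal(perfect$pct_abnormal_correct, 100)

  truth <- rep(c("normal", "abnormal"), each = 4)
  pred <- c("normal", "normal", "normal", "abnormal",
            "abnormal", "abnormal", "abnormal", "normal")
  cr <- confusion_and_rates(pred, truth)
  expect_equal(unlist(cr[c("tn", "fp", "fn", "tp")]),
               c(tn = 3L, fp = 1L, fn = 1L, tp = 3L))
  expect_equal(cr$pct_normal_correct, 75)
  expect_equal(cr$pct_abnormal_correct, 75)

  no_pos <- confusion_and_rates(rep("normal", 3), rep("normal", 3))
  expect_true(is.na(no_pos$pct_abnormal_correct))
  expect_error(confusion_and_rates("normal", "excluded"), "excluded")
})

test_that("AUROC equals pairwise concordance, with tie and boundary handling", {
  expect_equal(auroc(c(0.1, 0.9, 0.8, 0.2), c(FALSE, TRUE, TRUE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)),
               0.5)
  expect_true(is.na(auroc(c(0.2, 0.4), c(TRUE, TRUE))))

  set.seed(404)
  for (trial in 1:100) {
    n <- sample(3:12, 1)
    scores <- round(runif(n), 1)      # coarse grid forces ties
    pos <- runif(n) < 0.4
    if (all(pos) || !any(pos)) pos[c(1, n)] <- c(TRUE, FALSE)
    expect_equal(auroc(scores, pos), oracle_auroc(scores, pos),
                 tolerance = 1e-12)
  }

  ## independent library cross-check on a larger tied dataset
  set.seed(405)
  scores <- round(runif(300), 2)
  pos <- runif(300) < 0.2
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(auroc(scores, pos), ref, tolerance = 1e-12)
})

test_that("average precision behaves like an AUPRC with a prevalence baseline", {
  expect_equal(auprc(c(0.2, 0.8, 0.5), rep(TRUE, 3)), 1)
  expect_true(is.na(auprc(c(0.2, 0.8), c(FALSE, FALSE))))
  ## perfectly ranked: precision 1 at every positive
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)

  ## a random scorer's expected AUPRC approaches the positive prevalence
  ## (average precision carries a small positive finite-sample bias, so the
  ## check uses a sample large enough for the bias to be negligible)
  set.seed(505)
  n <- 1000
  pos <- rep(c(TRUE, FALSE), c(100, 900))
  ap <- vapply(1:200, function(i) auprc(runif(n), pos), numeric(1))
  expect_lt(abs(mean(ap) - 0.1), 0.02)
})

test_that("patient-level bootstrap intervals are sane", {
  set.seed(7)
  preds <- data.table(
    patient_id = rep(sprintf("P%d", 1:10), each = 10),
    score = runif(100),
    label = sample(rep(c("abnormal", "normal"), c(20, 80)))
  )
  preds[label == "abnormal", score := score + 0.5]
  ci <- bootstrap_ci(preds, "auroc", reps = 500, seed = 3)
  pt <- auroc(preds$score, preds$label)
  expect_true(ci[1] >= 0 && ci[2] <= 1)
  expect_true(ci[1] <= pt && pt <= ci[2])

  ## a constant metric collapses the interval
  cmet <- function(scores, labels) 0.7
  ci0 <- bootstrap_ci(preds, cmet, reps = 100, seed = 1)
  expect_equal(unname(ci0[1]), unname(ci0[2]))

  ## resampling stability on a fixed dataset
  ci_a <- bootstrap_ci(preds, "auroc", reps = 2000, seed = 11)
  ci_b <- bootstrap_ci(preds, "auroc", reps = 4000, seed = 12)
  expect_lt(max(abs(ci_a - ci_b)), 0.02)
})

test_that("event detection applies the day offsets, denominators, and missed list", {
  preds <- data.table(
    patient_id = "A",
    pod = c(1:4, 6:21),                  # POD 5 excluded (event day)
    predicted = "normal"
  )
  preds[pod == 3L, predicted := "abnormal"]
  ev <- make_events("A", 5L, clavien_grade = "II")
  det <- event_detection(preds, ev)
  expect_equal(det$d_minus2_pct, 100)
  expect_equal(det$d_minus1_pct, 0)
  expect_equal(det$d_any_pct, 100)
  expect_equal(det$n_events_missed, 0L)

  ## POD-1 events have no prior days and leave every denominator
  det1 <- event_detection(preds, make_events("A", 1L))
  expect_equal(unname(det1$d_any["den"]), 0L)
  expect_true(is.na(det1$d_any_pct))

  ## an undetected event is listed with its grade
  miss <- event_detection(data.table(patient_id = "A", pod = 1:21,
                                     predicted = "normal"),
                          ev)
  expect_equal(miss$n_events_missed, 1L)
  expect_equal(miss$missed$clavien_grade, "II")
  expect_equal(miss$d_any_pct, 0)

  ## a POD-2 event only has a d-1 chance
  det2 <- event_detection(data.table(patient_id = "A", pod = 1:21,
                                     predicted = "abnormal"),
                          make_events("A", 2L))
  expect_equal(unname(det2$d_minus2["den"]), 0L)
  expect_equal(det2$d_minus1_pct, 100)
  expect_equal(det2$d_any_pct, 100)

  expect_error(event_detection(preds, make_events("GHOST", 4L)), "GHOST")
})

test_that("importances average across folds and rank", {
  imp <- data.table(
    fold_id = rep(c("f1", "f2"), each = 2),
    feature = rep(c("a", "b"), 2),
    importance = c(0.6, 0.4, 0.2, 0.8)
  )
  avg <- average_importance(imp)
  expect_equal(avg[feature == "a"]$importance, 0.4)
  expect_equal(avg[feature == "b"]$importance, 0.6)
  expect_equal(avg$feature[1], "b")
  expect_equal(nrow(average_importance(imp, top_k = 1)), 1L)
})

test_that("evaluation reports are internally consistent and serialize", {
  set.seed(15)
  preds <- data.table(
    patient_id = rep(sprintf("P%d", 1:6), each = 20),
    pod = rep(1:20, 6),
    label = "normal", score = runif(120)
  )
  preds[pod %in% c(7, 8), `:=`(label = "abnormal", score = runif(12, 0.6, 1))]
  preds[, predicted := ifelse(score >= 0.5, "abnormal", "normal")]
  ev <- make_events(sprintf("P%d", 1:6), 9L)
  rep_ <- evaluate_predictions(preds, ev, ci_reps = 200)
  expect_s3_class(rep_, "eval_report")
  expect_equal(with(rep_$confusion, tn + fp + fn + tp), nrow(preds))
  expect_equal(rep_$baseline_auprc, 12 / 120)
  expect_equal(rep_$pct_abnormal_correct,
               100 * rep_$confusion$tp /
                 (rep_$confusion$tp + rep_$confusion$fn))
  ## every event detected at d-2 or d-1 is counted in d_any
  expect_gte(unname(rep_$d_any["n"]),
             max(unname(rep_$d_minus2["n"]), unname(rep_$d_minus1["n"])))

  path <- tempfile(fileext = ".json")
  write_report(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$auroc, rep_$auroc)
  expect_equal(parsed$n_included_days, rep_$n_included_days)
  unlink(path)
})

test_that("sensitivity variants filter as specified and conserve day counts", {
  co <- generate_cohort(full_wear_config(
    n_complicated = 7L, n_simple = 6L,
    event_rate = c(complicated = 1.5, simple = 1.5), seed = 19L))
  fm <- build_feature_matrix(co$patients, co$events, co$minutes,
                             co$summaries)
  labs <- label_days(co$events, 21L, co$patients$patient_id)
  params <- model_params(seed = 19)

  base_c <- run_group_analysis(fm$features, fm$wear, labs, co$events,
                               co$patients, params, group = "complicated",
                               ci_reps = 50)
  base_s <- run_group_analysis(fm$features, fm$wear, labs, co$events,
                               co$patients, params, group = "simple",
                               ci_reps = 50)

  ## the 10 h wear filter is a no-op on a fully worn cohort
  sens <- run_sensitivity("min_wear_10h", fm$features, fm$wear, labs,
                          co$events, co$patients, params, ci_reps = 50)
  expect_equal(sens$complicated, base_c)

  ## pooled model day totals add up across groups
  comb <- run_sensitivity("combined_groups", fm$features, fm$wear, labs,
                          co$events, co$patients, params, ci_reps = 50)
  expect_equal(comb$combined$n_included_days,
               base_c$n_included_days + base_s$n_included_days)

  ## clinical-only model never sees wearable columns
  nf <- run_sensitivity("no_fitbit", fm$features, fm$wear, labs, co$events,
                        co$patients, params, ci_reps = 50)
  used <- nf$complicated$importance$feature
  expect_true(all(used %in% c(demographic_feature_names(),
                              clinical_feature_names())))
})
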
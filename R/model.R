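#' Balanced random forest hyperparameters
#'
#' @param n_trees Number of trees in the ensemble.
#' @param max_depth Maximum tree depth; `NULL` grows trees to purity.
#' @param mtry Candidate features per split; `NULL` means
#'   `floor(sqrt(n_features))`.
#' @param vote_threshold Fraction of tree votes at or above which a day is
#'   predicted abnormal. A tie at the threshold counts as abnormal,
#'   favoring sensitivity.
#' @param corr_threshold Pairwise Pearson correlation above which the later
#'   of two features (in canonical column order) is pruned.
#' @param paper_faithful If `TRUE`, correlation pruning and imputation are
#'   fit once on the full dataset before cross-validation (the single-pass
#'   description of the analysis); the default `FALSE` re-fits both inside
#'   every fold from training patients only, so no information from the
#'   held-out patient reaches the model.
#' @param seed Integer seed controlling bootstrap draws and tree growing.
#' @return List of class `brf_params`.
#' @export
model_params <- function(n_trees = 100L, max_depth = NULL, mtry = NULL,
                         vote_threshold = 0.5, corr_threshold = 0.95,
                         paper_faithful = FALSE, seed = 1L) {
  stopifnot(n_trees >= 1L, vote_threshold > 0, vote_threshold < 1,
            corr_threshold > 0)
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 mtry = mtry, vote_threshold = vote_threshold,
                 corr_threshold = corr_threshold,
                 paper_faithful = isTRUE(paper_faithful),
                 seed = as.integer(seed)),
            class = "brf_params")
}

#' Greedy pruning of highly correlated features
#'
#' Scans features in canonical column order and drops a feature if its
#' absolute pairwise-complete Pearson correlation with any already-retained
#' feature exceeds the threshold. Zero-variance features have undefined
#' correlations; they are retained and reported in the `flagged` attribute.
#' The scan is deterministic and order-stable.
#'
#' @param x Numeric matrix or data.table of features (missing values
#'   allowed).
#' @param threshold Correlation threshold (default 0.95).
#' @return Character vector of retained feature names, with attribute
#'   `flagged` naming zero-variance features.
#' @export
prune_correlated <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) <= 1L) {
    out <- colnames(x)
    attr(out, "flagged") <- character()
    return(out)
  }
  suppressWarnings(cmat <- cor(x, use = "pairwise.complete.obs"))
  keep <- logical(ncol(x))
  keep[1L] <- TRUE
  for (j in seq.int(2L, ncol(x))) {
    r <- abs(cmat[j, keep])
    keep[j] <- !any(r > threshold, na.rm = TRUE)
  }
  out <- colnames(x)[keep]
  sds <- apply(x, 2, sd, na.rm = TRUE)
  attr(out, "flagged") <-
    colnames(x)[keep & (is.na(sds) | sds == 0)]
  out
}

#' Impute missing feature values with per-patient means
#'
#' Each missing cell is replaced by that patient's mean of the feature over
#' their included days. A patient with no observed value for a feature falls
#' back to the supplied grand means (computed from the training split during
#' cross-validation); with `grand_means = NULL` the grand means are computed
#' from `x` itself. A feature with no observed value anywhere is dropped
#' with a warning.
#'
#' @param x Numeric matrix or data.table of features.
#' @param patient_id Character vector aligning rows of `x` to patients.
#' @param grand_means Optional named vector of fallback means.
#' @return List with `x` (complete matrix, possibly fewer columns) and
#'   `grand_means` (the fallback means used, for reuse on held-out data).
#' @export
impute_patient_mean <- function(x, patient_id, grand_means = NULL) {
  x <- as.matrix(x)
  if (is.null(grand_means)) {
    grand_means <- colMeans(x, na.rm = TRUE)
    all_missing <- !is.finite(grand_means)
    if (any(all_missing)) {
      warning(sprintf("dropping feature(s) with no observed values: %s",
                      paste(colnames(x)[all_missing], collapse = ", ")))
      x <- x[, !all_missing, drop = FALSE]
      grand_means <- grand_means[!all_missing]
    }
  } else {
    x <- x[, names(grand_means), drop = FALSE]
  }
  for (p in unique(patient_id)) {
    rows <- which(patient_id == p)
    xp <- x[rows, , drop = FALSE]
    nas <- which(is.na(xp), arr.ind = TRUE)
    if (nrow(nas) == 0L) next
    pm <- colMeans(xp, na.rm = TRUE)
    fill <- ifelse(is.finite(pm), pm, grand_means)
    xp[nas] <- fill[nas[, "col"]]
    x[rows, ] <- xp
  }
  list(x = x, grand_means = grand_means)
}

#' Balanced bootstrap sample of row indices
#'
#' Draws `n_minority` indices with replacement from each class, yielding an
#' exactly class-balanced sample of size `2 * n_minority`. This is the
#' per-tree resampling scheme of the balanced random forest.
#'
#' @param labels Factor or character vector of class labels (two classes
#'   must both be present).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Integer vector of row indices.
#' @export
balanced_bootstrap <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop(sprintf("need exactly 2 classes, got: %s",
                 paste(classes, collapse = ", ")))
  idx <- split(seq_along(labels), labels)
  n_min <- min(lengths(idx))
  unlist(lapply(idx[order(names(idx))], function(i)
    i[sample.int(length(i), n_min, replace = TRUE)]), use.names = FALSE)
}

#' Fit a balanced random forest
#'
#' Fits `n_trees` decision trees, each on an independent bootstrap that
#' draws `n_minority` rows with replacement from each class (exact class
#' balance per tree), with `mtry` random candidate features per node and
#' per-feature Gini (impurity) importance. Tree induction is delegated to
#' \pkg{ranger} with class-wise resampling fractions, which realizes exactly
#' this balanced bootstrap.
#'
#' @param x Complete numeric feature matrix (impute first).
#' @param y Labels, coerced to a factor with levels
#'   `c("normal", "abnormal")`.
#' @param params A [model_params()] object.
#' @return Object of class `brf_model`.
#' @export
train_brf <- function(x, y, params = model_params()) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("normal", "abnormal"))
  if (anyNA(x)) stop("x contains missing values; impute before training")
  counts <- table(y)
  if (any(counts == 0L))
    stop(sprintf("class `%s` absent from training labels",
                 names(counts)[counts == 0L][1]))
  if (counts[["abnormal"]] < 2L)
    stop("fewer than 2 abnormal training days; refusing to fit")
  n_min <- min(counts)
  mtry <- if (is.null(params$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    min(params$mtry, ncol(x))
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = params$n_trees,
    mtry = mtry,
    min.node.size = 1L,
    max.depth = if (is.null(params$max_depth)) 0L else params$max_depth,
    replace = TRUE,
    sample.fraction = rep(n_min / length(y), 2L),
    importance = "impurity",
    seed = params$seed,
    num.threads = 1L,
    keep.inbag = TRUE
  )
  structure(list(fit = fit, features = colnames(x), params = params,
                 levels = levels(y)),
            class = "brf_model")
}

#' Predict day scores from a balanced random forest
#'
#' @param object A `brf_model`.
#' @param newdata Complete numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return data.table with `score` (fraction of trees voting abnormal) and
#'   `predicted` (`"abnormal"` iff `score >= vote_threshold`).
#' @export
predict.brf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  pr <- predict(object$fit, data = as.data.frame(newdata),
                predict.all = TRUE, num.threads = 1L)$predictions
  score <- rowMeans(pr == 2L)  # level 2 = abnormal
  data.table(score = score,
             predicted = ifelse(score >= object$params$vote_threshold,
                                "abnormal", "normal"))
}

#' Gini importance of a fitted balanced random forest
#' @param object A `brf_model`.
#' @return Named numeric vector (one entry per retained feature).
#' @export
brf_importance <- function(object) {
  object$fit$variable.importance
}

#' Leave-one-subject-out cross-validation of the balanced random forest
#'
#' One fold per patient: the model is trained on all other patients' days
#' and scores every included day of the held-out patient. By default,
#' correlation pruning and imputation are re-fit inside each fold from the
#' training patients only; `params$paper_faithful = TRUE` fits them once on
#' the full table instead. The held-out patient's missing values are always
#' filled from their own per-feature means first, then from the training
#' grand means. Folds whose held-out patient has no included days are
#' skipped; folds are seeded deterministically from `params$seed`.
#'
#' @param dataset Modeling table from [assemble_dataset()].
#' @param params A [model_params()] object.
#' @param feature_cols Feature columns to use (default: all of
#'   [feature_names()] present in `dataset`).
#' @return List of class `loso_result` with `predictions` (`patient_id`,
#'   `pod`, `label`, `score`, `predicted`, `fold_id`), `importance`
#'   (`fold_id`, `feature`, `importance`; pruned features carry 0), and
#'   `params`.
#' @export
loso_cv <- function(dataset, params = model_params(), feature_cols = NULL) {
  dataset <- as.data.table(dataset)
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_names(), names(dataset))
  pats <- sort(unique(dataset$patient_id))
  if (length(pats) < 2L) stop("leave-one-subject-out CV needs >= 2 patients")
  xfull <- as.matrix(dataset[, ..feature_cols])
  storage.mode(xfull) <- "double"
  y <- dataset$label

  global_retained <- NULL
  global_imputed <- NULL
  if (params$paper_faithful) {
    obs <- colSums(!is.na(xfull)) > 0L
    imp <- impute_patient_mean(xfull[, obs, drop = FALSE],
                               dataset$patient_id)
    global_retained <- prune_correlated(imp$x, params$corr_threshold)
    global_imputed <- imp$x[, global_retained, drop = FALSE]
  }

  preds <- vector("list", length(pats))
  imps <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    p <- pats[i]
    test_rows <- which(dataset$patient_id == p)
    if (length(test_rows) == 0L) next
    train_rows <- which(dataset$patient_id != p)
    fold_seed <- (params$seed + 7919L * i) %% .Machine$integer.max
    fold_params <- params
    fold_params$seed <- as.integer(fold_seed)

    if (params$paper_faithful) {
      retained <- global_retained
      xtr <- global_imputed[train_rows, , drop = FALSE]
      xte <- global_imputed[test_rows, , drop = FALSE]
    } else {
      xtr0 <- xfull[train_rows, , drop = FALSE]
      obs <- colSums(!is.na(xtr0)) > 0L
      imp_tr <- impute_patient_mean(xtr0[, obs, drop = FALSE],
                                    dataset$patient_id[train_rows])
      retained <- prune_correlated(imp_tr$x, params$corr_threshold)
      xtr <- imp_tr$x[, retained, drop = FALSE]
      xte <- impute_patient_mean(
        xfull[test_rows, retained, drop = FALSE],
        dataset$patient_id[test_rows],
        grand_means = imp_tr$grand_means[retained]
      )$x
    }
    model <- train_brf(xtr, y[train_rows], fold_params)
    pr <- predict(model, xte)
    preds[[i]] <- data.table(patient_id = p,
                             pod = dataset$pod[test_rows],
                             label = y[test_rows],
                             score = pr$score, predicted = pr$predicted,
                             fold_id = p)
    imp_vec <- setNames(numeric(length(feature_cols)), feature_cols)
    gi <- brf_importance(model)
    imp_vec[names(gi)] <- gi
    imps[[i]] <- data.table(fold_id = p, feature = feature_cols,
                            importance = as.numeric(imp_vec))
  }
  structure(list(predictions = rbindlist(preds),
                 importance = rbindlist(imps),
                 params = params),
            class = "loso_result")
}
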
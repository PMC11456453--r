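## Repeated stratified-split classification protocol: recursive feature
## elimination, grid-search-tuned SVM / KNN / RF, test-set metrics and
## importance aggregation.

#' Control parameters for the classification protocol
#'
#' Defaults reproduce the full protocol: 10 stratified 70/30 train-test
#' splits; RFE scored by accuracy under 10-fold cross-validation repeated 5
#' times over subset sizes 1..p; hyperparameters tuned by AUC under 5-fold
#' cross-validation repeated 10 times over a grid of 10 values per tunable
#' parameter (SVM cost log-spaced over 0.25-128 and kernel width spanning
#' 0.1-10 times a median-heuristic estimate; KNN neighbour counts odd 5-23;
#' RF mtry integer-spaced over 1..p). Smaller values keep simulation studies
#' affordable.
#'
#' @param n_repeats Number of stratified train/test splits.
#' @param train_fraction Fraction of each class assigned to training.
#' @param rfe_folds,rfe_repeats Cross-validation design inside RFE.
#' @param tune_folds,tune_repeats Cross-validation design for tuning.
#' @param grid_size Values per tunable hyperparameter.
#' @param rf_ntree Trees for final random forests.
#' @param rf_nodesize Minimum terminal-node size for random forests. The
#'   conventional 1 grows trees to purity; larger values smooth the vote
#'   fractions, which matters when the forest's continuous score (not just
#'   its hard label) is the quantity of interest, e.g. in low-dimensional
#'   probability-recovery studies.
#' @param rfe_ntree Trees for the quick forests used to rank features in RFE.
#' @param n_permutations Permutations per feature for KNN importance.
#' @param positive Positive class label.
#' @return List of class `classification_control`.
#' @export
classification_control <- function(n_repeats = 10, train_fraction = 0.7,
                                   rfe_folds = 10, rfe_repeats = 5,
                                   tune_folds = 5, tune_repeats = 10,
                                   grid_size = 10, rf_ntree = 500,
                                   rf_nodesize = 1,
                                   rfe_ntree = 200, n_permutations = 10,
                                   positive = "early_AD") {
  structure(as.list(environment()), class = "classification_control")
}

## Splits ---------------------------------------------------------------------

#' Build repeated stratified train/test splits
#'
#' Each repeat assigns `round(train_fraction * n_class)` members of every
#' class to training (at least one per class on each side) and the rest to
#' testing, so class proportions match the cohort within rounding. Train and
#' test are disjoint and exhaust the cohort.
#'
#' @param y Class labels (factor or character).
#' @param n_repeats Number of independent splits.
#' @param train_fraction Training fraction per class.
#' @param seed Integer seed; identical seeds give identical plans.
#' @return Object of class `split_plan`: list with `train`/`test` index lists.
#' @export
make_splits <- function(y, n_repeats = 10, train_fraction = 0.7, seed = 1) {
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts < 4L)) {
    stop("every class needs at least 4 members for a stratified split")
  }
  set.seed(seed)
  train <- vector("list", n_repeats)
  test <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    tr <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      n_tr <- min(max(round(length(idx) * train_fraction), 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }))
    train[[r]] <- sort(tr)
    test[[r]] <- setdiff(seq_along(y), tr)
  }
  structure(list(train = train, test = test, n_repeats = n_repeats,
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

## stratified k-fold assignment, repeated
cv_folds <- function(y, k, repeats) {
  folds <- vector("list", k * repeats)
  pos <- 1L
  for (r in seq_len(repeats)) {
    assign_id <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      assign_id[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      folds[[pos]] <- which(assign_id == f)
      pos <- pos + 1L
    }
  }
  folds
}

## Model fitting --------------------------------------------------------------

median_heuristic_gamma <- function(x) {
  n <- nrow(x)
  if (n > 120L) x <- x[sample.int(n, 120L), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1 / max(ncol(x), 1L))
  1 / stats::median(d2)
}

default_hyper <- function(method, x) {
  switch(method,
         svm = list(cost = 1, gamma = median_heuristic_gamma(scale(x))),
         knn = list(k = min(5L, nrow(x) - 1L)),
         rf = list(mtry = max(1L, floor(sqrt(ncol(x))))),
         glm = list())
}

#' Fit a classifier with standardized inputs
#'
#' Centers and scales predictors using statistics from the training data only
#' (stored in the fit and re-applied at prediction time). SVM decision values
#' are mapped to class scores through a logistic calibration fit on the
#' training data.
#'
#' @param method One of `"svm"`, `"knn"`, `"rf"`, `"glm"`.
#' @param x Numeric predictor matrix (training rows).
#' @param y Class labels.
#' @param hyper Named list of hyperparameters (`cost`/`gamma`, `k`, `mtry`).
#' @param control A [classification_control()].
#' @return Object of class `speech_classifier`.
#' @export
fit_classifier <- function(method, x, y, hyper = NULL,
                           control = classification_control()) {
  method <- match.arg(method, c("svm", "knn", "rf", "glm"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("outcome is degenerate: only one class present")
  if (is.null(hyper)) hyper <- default_hyper(method, x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pos <- if (control$positive %in% levels(y)) control$positive else levels(y)[2]
  fit <- switch(method,
    svm = {
      m <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                      cost = hyper$cost, gamma = hyper$gamma, scale = FALSE)
      dv <- as.numeric(attr(predict(m, xs, decision.values = TRUE),
                            "decision.values"))
      cal <- suppressWarnings(
        stats::glm.fit(cbind(1, dv), as.numeric(y == pos),
                       family = stats::binomial()))
      list(model = m, calibration = cal$coefficients)
    },
    knn = list(train_x = xs, train_y = y, k = hyper$k),
    rf = list(model = randomForest::randomForest(
      xs, y, mtry = hyper$mtry, ntree = control$rf_ntree,
      nodesize = control$rf_nodesize)),
    glm = {
      g <- suppressWarnings(
        stats::glm.fit(cbind(1, xs), as.numeric(y == pos),
                       family = stats::binomial()))
      cf <- g$coefficients
      cf[is.na(cf)] <- 0  # aliased (collinear) columns drop out
      list(coefficients = cf)
    })
  structure(list(method = method, fit = fit, hyper = hyper,
                 center = ctr, scale = scl, levels = levels(y), positive = pos,
                 features = colnames(x)),
            class = "speech_classifier")
}

#' Predict positive-class scores from a fitted classifier
#' @param object A [fit_classifier()] result.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]` for the positive class.
#' @export
predict.speech_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  } else if (ncol(x) != length(object$features)) {
    stop("newdata must carry the training columns")
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pos <- object$positive
  switch(object$method,
    svm = {
      dv <- as.numeric(attr(predict(object$fit$model, xs, decision.values = TRUE),
                            "decision.values"))
      cal <- object$fit$calibration
      ## degenerate calibration (perfect separation) keeps monotone ordering
      if (anyNA(cal)) cal <- c(0, 1)
      stats::plogis(cal[1] + cal[2] * dv)
    },
    knn = {
      tr <- object$fit$train_x
      k <- min(object$fit$k, nrow(tr))
      d2 <- outer(rowSums(xs^2), rep(1, nrow(tr))) +
            outer(rep(1, nrow(xs)), rowSums(tr^2)) - 2 * xs %*% t(tr)
      apply(d2, 1, function(d) {
        nn <- order(d)[seq_len(k)]
        mean(object$fit$train_y[nn] == pos)
      })
    },
    rf = unname(predict(object$fit$model, xs, type = "prob")[, pos]),
    glm = as.numeric(stats::plogis(cbind(1, xs) %*% object$fit$coefficients))
  )
}

## Metrics --------------------------------------------------------------------

#' Rank-statistic AUC
#'
#' The probability that a random positive case outscores a random negative
#' one, computed from ranks; tied score pairs count one half. Equals the
#' brute-force count of concordant pairs over all pairs.
#'
#' @param scores Numeric scores.
#' @param labels Class labels.
#' @param positive Positive class label.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels, positive = "early_AD") {
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Test-set classification metrics
#'
#' AUC by the rank statistic plus threshold metrics at score >= 0.5:
#' specificity TN/(TN+FP), precision TP/(TP+FP), recall TP/(TP+FN) and the F1
#' harmonic mean.
#'
#' @param scores Numeric positive-class scores.
#' @param labels True class labels.
#' @param positive Positive class label.
#' @param threshold Hard-label threshold.
#' @return Named numeric vector `c(AUC, specificity, precision, recall, F1)`.
#' @export
evaluate_predictions <- function(scores, labels, positive = "early_AD",
                                 threshold = 0.5) {
  is_pos <- labels == positive
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & is_pos)
  fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos)
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(AUC = auc_rank(scores, labels, positive), specificity = specificity,
    precision = precision, recall = recall, F1 = f1)
}

## Importance -----------------------------------------------------------------

scale_importance <- function(x) {
  if (!length(x)) return(x)
  if (max(x) == min(x)) return(stats::setNames(rep(100, length(x)), names(x)))
  if (min(x) < 0) x <- x - min(x)
  100 * x / max(x)
}

#' Per-feature importance scores, scaled to a maximum of 100
#'
#' Model-specific measures: random forests use the accumulated decrease in
#' Gini impurity; the SVM uses the drop in training AUC when each predictor is
#' removed and the model refit at fixed hyperparameters; KNN (and any model
#' without an intrinsic measure) uses the mean training-accuracy drop over
#' random permutations of each feature column. Scores are linearly scaled so
#' the largest is 100 and the smallest is nonnegative.
#'
#' @param fit A [fit_classifier()] result.
#' @param x,y The training data the model was fit on.
#' @param control A [classification_control()] (permutation count).
#' @return Named numeric vector of importances in `[0, 100]`.
#' @export
feature_importance <- function(fit, x, y, control = classification_control()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- fit$features
  x <- x[, fit$features, drop = FALSE]
  y <- droplevels(as.factor(y))
  p <- ncol(x)
  raw <- switch(fit$method,
    rf = {
      imp <- fit$fit$model$importance[, "MeanDecreaseGini"]
      stats::setNames(as.numeric(imp), rownames(fit$fit$model$importance))
    },
    svm = {
      full_auc <- auc_rank(predict(fit, x), y, fit$positive)
      if (p == 1L) {
        stats::setNames(full_auc, colnames(x))
      } else {
        drops <- vapply(seq_len(p), function(j) {
          sub <- fit_classifier("svm", x[, -j, drop = FALSE], y,
                                hyper = fit$hyper, control = control)
          full_auc - auc_rank(predict(sub, x[, -j, drop = FALSE]), y, fit$positive)
        }, numeric(1))
        stats::setNames(drops, colnames(x))
      }
    },
    {
      ## model-independent permutation importance
      n_perm <- control$n_permutations
      if (n_perm < 1L) stop("permutation importance needs at least 1 permutation")
      base_acc <- mean((predict(fit, x) >= 0.5) == (y == fit$positive))
      drops <- vapply(seq_len(p), function(j) {
        accs <- vapply(seq_len(n_perm), function(b) {
          xp <- x
          xp[, j] <- xp[sample.int(nrow(x)), j]
          mean((predict(fit, xp) >= 0.5) == (y == fit$positive))
        }, numeric(1))
        base_acc - mean(accs)
      }, numeric(1))
      stats::setNames(drops, colnames(x))
    })
  scale_importance(raw)
}

## RFE ------------------------------------------------------------------------

## ranking criterion used inside the elimination loop: model-specific where it
## is cheap (RF Gini, logistic |z|), univariate AUC otherwise
rank_features <- function(method, x, y, control) {
  p <- ncol(x)
  scores <- switch(method,
    rf = {
      m <- randomForest::randomForest(x, y, ntree = control$rfe_ntree,
                                      mtry = max(1L, floor(sqrt(p))))
      as.numeric(m$importance[, "MeanDecreaseGini"])
    },
    glm = {
      xs <- scale(x)
      xs[is.na(xs)] <- 0
      g <- suppressWarnings(
        stats::glm.fit(cbind(1, xs), as.numeric(y == levels(y)[2]),
                       family = stats::binomial()))
      se <- sqrt(diag(chol2inv(qr.R(g$qr))))
      abs(g$coefficients[-1] / se[-1])
    },
    {
      ## univariate AUC filter, folded about 0.5
      vapply(seq_len(p), function(j) {
        a <- auc_rank(x[, j], y, levels(y)[2])
        max(a, 1 - a)
      }, numeric(1))
    })
  scores[is.na(scores)] <- 0
  stats::setNames(scores, colnames(x))
}

## backward elimination on one data set down to `target` features
eliminate_to <- function(method, x, y, target, control) {
  feats <- colnames(x)
  while (length(feats) > target) {
    rk <- rank_features(method, x[, feats, drop = FALSE], y, control)
    feats <- feats[-which.min(rk)]
  }
  feats
}

#' Recursive feature elimination with repeated cross-validation
#'
#' For every candidate subset size s in 1..p, estimates the cross-validated
#' accuracy of the model restricted to the top-s features — the ranking being
#' recomputed at each elimination step within each training fold — using
#' stratified k-fold cross-validation (10-fold repeated 5 times by default).
#' Returns the feature set of the size with the best mean accuracy; ties go
#' to the smaller size. The returned set is obtained by eliminating on the
#' full training data down to the chosen size.
#'
#' @param x Numeric predictor matrix.
#' @param y Class labels (two classes).
#' @param method Model used to score subsets (`"svm"`, `"knn"`, `"rf"`,
#'   `"glm"`); it is fit at fixed default hyperparameters inside RFE.
#' @param control A [classification_control()].
#' @param seed Integer seed for the fold draws.
#' @return Character vector of selected feature names.
#' @export
rfe_select <- function(x, y, method = "rf", control = classification_control(),
                       seed = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("outcome is degenerate: only one class present")
  p <- ncol(x)
  if (p < 1L) stop("need at least one predictor")
  if (p == 1L) return(colnames(x))
  set.seed(seed)
  folds <- cv_folds(y, control$rfe_folds, control$rfe_repeats)
  acc <- matrix(NA_real_, nrow = length(folds), ncol = p)
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    if (length(hold) == 0L || length(hold) == length(y)) next
    xa <- x[-hold, , drop = FALSE]
    ya <- droplevels(y[-hold])
    if (nlevels(ya) < 2L) next
    feats <- colnames(x)
    for (s in p:1) {
      fit <- fit_classifier(method, xa[, feats, drop = FALSE], ya,
                            control = control)
      sc <- predict(fit, x[hold, feats, drop = FALSE])
      acc[f, s] <- mean((sc >= 0.5) == (y[hold] == fit$positive))
      if (s > 1L) {
        rk <- rank_features(method, xa[, feats, drop = FALSE], ya, control)
        feats <- feats[-which.min(rk)]
      }
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  mean_acc[!is.finite(mean_acc)] <- -Inf
  best <- which(mean_acc >= max(mean_acc) - 1e-12)[1]  # ties -> smaller size
  eliminate_to(method, x, y, best, control)
}

## Tuning ---------------------------------------------------------------------

hyper_grid <- function(method, x, control) {
  g <- control$grid_size
  switch(method,
    svm = {
      gamma0 <- median_heuristic_gamma(scale(x))
      expand.grid(cost = 2^seq(log2(0.25), log2(128), length.out = g),
                  gamma = gamma0 * 10^seq(-1, 1, length.out = g))
    },
    knn = data.frame(k = pmin(seq(5L, by = 2L, length.out = g),
                              nrow(x) - 1L)),
    rf = data.frame(mtry = unique(pmax(1L, round(seq(1, ncol(x),
                                                     length.out = g))))),
    glm = data.frame(dummy = 0))
}

#' Grid-search tuning and final fit
#'
#' Evaluates each grid point by mean cross-validated AUC (5-fold repeated 10
#' times by default) and refits the best combination on the full training
#' data. Ties keep the first (least complex) grid entry. Predictors are
#' standardized inside every fit using the fitting rows only.
#'
#' @param x Training predictor matrix (selected features).
#' @param y Class labels.
#' @param method `"svm"`, `"knn"`, `"rf"` or `"glm"`.
#' @param control A [classification_control()].
#' @param seed Integer seed for fold draws.
#' @return A [fit_classifier()] object with attributes `best_hyper` and
#'   `cv_auc`.
#' @export
tune_and_train <- function(x, y, method = "svm",
                           control = classification_control(), seed = 1) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("selected feature set is empty")
  y <- droplevels(as.factor(y))
  grid <- hyper_grid(method, x, control)
  set.seed(seed)
  if (nrow(grid) > 1L) {
    folds <- cv_folds(y, control$tune_folds, control$tune_repeats)
    cv_auc <- vapply(seq_len(nrow(grid)), function(i) {
      hy <- as.list(grid[i, , drop = FALSE])
      aucs <- vapply(folds, function(hold) {
        ya <- droplevels(y[-hold])
        if (nlevels(ya) < 2L) return(NA_real_)
        fit <- fit_classifier(method, x[-hold, , drop = FALSE], ya,
                              hyper = hy, control = control)
        auc_rank(predict(fit, x[hold, , drop = FALSE]), y[hold], fit$positive)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which(cv_auc >= max(cv_auc, na.rm = TRUE) - 1e-12)[1]
    best_hyper <- as.list(grid[best, , drop = FALSE])
    best_auc <- cv_auc[best]
  } else {
    best_hyper <- if (method == "glm") list() else as.list(grid[1, , drop = FALSE])
    best_auc <- NA_real_
  }
  fit <- fit_classifier(method, x, y, hyper = best_hyper, control = control)
  attr(fit, "best_hyper") <- best_hyper
  attr(fit, "cv_auc") <- best_auc
  fit
}

## Protocol driver ------------------------------------------------------------

#' Predictor sets used by the classification protocol
#'
#' `linguistic` is the 15 linguistic features, `biomarkers` is SUVR and
#' hippocampal volume, `combined` their union; age and years of education are
#' included as covariates in every set (and compete in RFE like any other
#' predictor).
#'
#' @param sets Which sets to build.
#' @return Named list of predictor-name vectors.
#' @export
predictor_sets <- function(sets = c("linguistic", "biomarkers", "combined")) {
  sets <- match.arg(sets, several.ok = TRUE)
  covars <- c("age", "education")
  all_sets <- list(
    linguistic = c(feature_names(), covars),
    biomarkers = c("suvr", "hippocampus_cm3", covars),
    combined = c(feature_names(), "suvr", "hippocampus_cm3", covars))
  all_sets[sets]
}

#' Run the full classification protocol on a cohort
#'
#' For each of `n_repeats` stratified 70/30 splits, each predictor set and
#' each model: RFE selects a feature subset on the training data, the model is
#' grid-tuned by cross-validated AUC and refit, test-set metrics are computed,
#' and per-feature importances are recorded for the selected features. Rows
#' with missing biomarkers are excluded from biomarker-containing sets only.
#'
#' @param cohort Cohort table containing the 15 features, biomarkers,
#'   covariates and `group`.
#' @param models Models to run (`"svm"`, `"knn"`, `"rf"`, `"glm"`).
#' @param sets Predictor sets (see [predictor_sets()]).
#' @param control A [classification_control()].
#' @param seed Master seed; the whole report is reproducible from it.
#' @return A `classification_report` (see [aggregate_report()]).
#' @export
run_classification <- function(cohort, models = c("svm", "knn", "rf"),
                               sets = c("linguistic", "biomarkers", "combined"),
                               control = classification_control(), seed = 1) {
  models <- match.arg(models, c("svm", "knn", "rf", "glm"), several.ok = TRUE)
  psets <- predictor_sets(sets)
  miss <- setdiff(unique(unlist(psets)), names(cohort))
  if (length(miss)) stop("cohort is missing predictors: ", paste(miss, collapse = ", "))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, control$n_repeats * length(psets) *
                        length(models) * 3)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  runs <- list()
  for (set_name in names(psets)) {
    cols <- psets[[set_name]]
    keep <- stats::complete.cases(cohort[, cols, drop = FALSE]) &
      !is.na(cohort$group)
    dat <- cohort[keep, , drop = FALSE]
    y <- factor(dat$group, levels = c("NC", "early_AD"))
    x <- as.matrix(dat[, cols, drop = FALSE])
    plan <- make_splits(y, control$n_repeats, control$train_fraction,
                        seed = next_seed())
    for (model in models) {
      for (r in seq_len(control$n_repeats)) {
        tr <- plan$train[[r]]
        te <- plan$test[[r]]
        selected <- rfe_select(x[tr, , drop = FALSE], y[tr], model,
                               control = control, seed = next_seed())
        fit <- tune_and_train(x[tr, selected, drop = FALSE], y[tr], model,
                              control = control, seed = next_seed())
        scores <- predict(fit, x[te, selected, drop = FALSE])
        metrics <- evaluate_predictions(scores, y[te],
                                        positive = control$positive)
        imp <- feature_importance(fit, x[tr, selected, drop = FALSE], y[tr],
                                  control = control)
        runs[[length(runs) + 1L]] <- list(
          set = set_name, model = model, repeat_id = r,
          selected = selected, metrics = metrics, importance = imp,
          test_scores = scores, test_labels = as.character(y[te]),
          candidates = cols, n_train = length(tr), n_test = length(te))
      }
    }
  }
  aggregate_report(runs, n_repeats = control$n_repeats)
}

#' Aggregate per-repeat classification runs into a report
#'
#' Metrics are averaged over repeats per model and predictor set. Importance
#' is averaged over the repeats in which RFE selected the feature; selection
#' frequency is the percentage of repeats in which it was selected; features
#' never selected are excluded. The top-5 features per model and set are
#' ranked by mean importance.
#'
#' @param runs List of per-repeat run records (see [run_classification()]).
#' @param n_repeats Number of repeats each run block was aggregated over.
#' @return Object of class `classification_report` with elements `metrics`,
#'   `importance`, `top_features` and `runs`.
#' @export
aggregate_report <- function(runs, n_repeats) {
  if (!length(runs)) stop("no completed runs to aggregate")
  key <- vapply(runs, function(r) paste(r$set, r$model, sep = "|"), character(1))
  metric_rows <- list()
  imp_rows <- list()
  top <- list()
  for (k in unique(key)) {
    rr <- runs[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    mm <- do.call(rbind, lapply(rr, function(r) r$metrics))
    metric_rows[[k]] <- data.frame(
      set = parts[1], model = parts[2], n_repeats = length(rr),
      as.list(colMeans(mm, na.rm = TRUE)))
    feats <- unique(unlist(lapply(rr, function(r) r$selected)))
    if (length(feats)) {
      imp <- vapply(feats, function(f) {
        vals <- unlist(lapply(rr, function(r) r$importance[f]))
        mean(vals, na.rm = TRUE)
      }, numeric(1))
      freq <- vapply(feats, function(f) {
        100 * mean(vapply(rr, function(r) f %in% r$selected, logical(1)))
      }, numeric(1))
      ord <- order(-imp)
      imp_rows[[k]] <- data.frame(
        set = parts[1], model = parts[2], feature = feats[ord],
        mean_importance = unname(imp[ord]), selection_frequency = unname(freq[ord]))
      top[[k]] <- utils::head(feats[ord], 5L)
    }
  }
  structure(list(metrics = do.call(rbind, c(metric_rows, make.row.names = FALSE)),
                 importance = do.call(rbind, c(imp_rows, make.row.names = FALSE)),
                 top_features = top,
                 runs = runs,
                 n_repeats = n_repeats),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  m <- x$metrics
  m[] <- lapply(m, function(col) if (is.numeric(col)) round(col, 3) else col)
  print(m, row.names = FALSE)
  invisible(x)
}
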
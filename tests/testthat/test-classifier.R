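test_that("stratified splits preserve class balance and exhaust the cohort", {
  y <- rep(c("NC", "early_AD"), each = 10)
  plan <- make_splits(y, n_repeats = 5, train_fraction = 0.7, seed = 3)
  for (r in 1:5) {
    tr <- plan$train[[r]]; te <- plan$test[[r]]
    expect_equal(sort(c(tr, te)), 1:20)
    expect_equal(as.vector(table(y[tr])), c(7L, 7L))
    expect_equal(as.vector(table(y[te])), c(3L, 3L))
  }
  # 32 + 48 rounds to 22 + 34 in training
  y2 <- rep(c("NC", "early_AD"), c(32, 48))
  plan2 <- make_splits(y2, n_repeats = 3, seed = 4)
  expect_equal(as.vector(table(y2[plan2$train[[1]]])[c("NC", "early_AD")]),
               c(22L, 34L))
  expect_equal(as.vector(table(y2[plan2$test[[1]]])[c("NC", "early_AD")]),
               c(10L, 14L))
  # determinism
  expect_identical(make_splits(y2, 3, seed = 4), plan2)
  expect_error(make_splits(rep(c("NC", "early_AD"), c(3, 40))), "at least 4")
})

test_that("rank AUC matches its definition on small frozen cases", {
  lab <- c("NC", "NC", "early_AD", "early_AD")
  expect_equal(auc_rank(c(.1, .2, .8, .9), lab), 1)
  expect_equal(auc_rank(c(.6, .2, .8, .4), lab), 0.75)  # 3 of 4 pairs concordant
  expect_equal(auc_rank(rep(0.3, 4), lab), 0.5)         # ties count one half
  expect_true(is.na(auc_rank(1:3, rep("early_AD", 3))))
  m <- evaluate_predictions(c(.1, .2, .8, .9), lab)
  expect_equal(unname(m[c("AUC", "precision", "recall", "F1")]), rep(1, 4))
  expect_equal(unname(m["specificity"]), 1)
})

test_that("rank AUC equals brute-force pairwise concordance", {
  brute_auc <- function(scores, labels, positive = "early_AD") {
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    total <- 0
    for (a in pos) for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
    total / (length(pos) * length(neg))
  }
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:120, 1)
    labels <- sample(c("NC", "early_AD"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(auc_rank(scores, labels), brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("classifiers separate separable data and predict deterministically", {
  set.seed(5)
  x <- cbind(f = c(rnorm(30, -2), rnorm(30, 2)), g = rnorm(60))
  y <- rep(c("NC", "early_AD"), each = 30)
  for (m in c("svm", "rf", "glm")) {
    fit <- fit_classifier(m, x, y)
    expect_equal(auc_rank(predict(fit, x), y), 1,
                 tolerance = 1e-8, label = m)
  }
  # a 5-nearest-neighbour vote can blur one boundary point
  expect_gte(auc_rank(predict(fit_classifier("knn", x, y), x), y), 0.99)
  ctl <- classification_control(tune_folds = 3, tune_repeats = 2, grid_size = 5)
  f1 <- tune_and_train(x, y, "knn", ctl, seed = 9)
  f2 <- tune_and_train(x, y, "knn", ctl, seed = 9)
  expect_identical(attr(f1, "best_hyper"), attr(f2, "best_hyper"))
  # the chosen k is a grid member
  expect_true(attr(f1, "best_hyper")$k %in% seq(5, by = 2, length.out = 5))
  expect_error(tune_and_train(x[, 0], y, "svm", ctl), "empty")
})

test_that("RFE keeps a planted separating predictor and never returns empty", {
  set.seed(11)
  n <- 100
  x <- cbind(sep = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  y <- rep(c("NC", "early_AD"), each = n / 2)
  ctl <- classification_control(rfe_folds = 5, rfe_repeats = 2)
  hits <- 0L
  for (r in 1:10) {
    sel <- rfe_select(x, y, "glm", ctl, seed = 100 + r)
    hits <- hits + ("sep" %in% sel)
  }
  expect_gte(hits, 9L)
  # single predictor: returned as-is
  expect_identical(rfe_select(x[, 1, drop = FALSE], y, "glm", ctl), "sep")
  # duplicated separating predictor: set of size 1 or 2, never empty
  x2 <- cbind(sep1 = x[, "sep"], sep2 = x[, "sep"])
  sel2 <- rfe_select(x2, y, "glm", ctl, seed = 12)
  expect_gte(length(sel2), 1L)
  expect_lte(length(sel2), 2L)
  expect_error(rfe_select(x, rep("early_AD", n), "glm", ctl), "degenerate")
})

test_that("importance scales to 100 and ranks signal above noise", {
  set.seed(21)
  x <- cbind(sig = c(rnorm(40, -1.5), rnorm(40, 1.5)), noise = rnorm(80))
  y <- rep(c("NC", "early_AD"), each = 40)
  # single-feature model scores 100
  fit1 <- fit_classifier("rf", x[, "sig", drop = FALSE], y)
  expect_equal(unname(feature_importance(fit1, x[, "sig", drop = FALSE], y)),
               100)
  wins <- 0L
  for (r in 1:10) {
    set.seed(30 + r)
    x_r <- cbind(sig = c(rnorm(40, -1.5), rnorm(40, 1.5)), noise = rnorm(80))
    for (m in c("rf", "svm", "knn")) {
      fit <- fit_classifier(m, x_r, y)
      imp <- feature_importance(fit, x_r, y)
      expect_equal(max(imp), 100)
      expect_gte(min(imp), 0)
      wins <- wins + (imp["sig"] > imp["noise"])
    }
  }
  expect_gte(wins, 28L)  # >= ~95% of seeded replicates
  # permutation importance refuses zero permutations
  fit <- fit_classifier("knn", x, y)
  expect_error(feature_importance(fit, x, y,
                                  classification_control(n_permutations = 0)),
               "permutation")
})

test_that("report aggregation averages importance over selected repeats", {
  runs <- list(
    list(set = "linguistic", model = "svm", repeat_id = 1,
         selected = c("LPR", "MLU"), metrics = c(AUC = 0.9, specificity = 0.8,
         precision = 0.8, recall = 0.9, F1 = 0.85),
         importance = c(LPR = 80, MLU = 50)),
    list(set = "linguistic", model = "svm", repeat_id = 2,
         selected = c("LPR"), metrics = c(AUC = 0.8, specificity = 0.7,
         precision = 0.7, recall = 0.8, F1 = 0.75),
         importance = c(LPR = 100)))
  rep <- aggregate_report(runs, n_repeats = 2)
  imp <- rep$importance
  expect_equal(imp$mean_importance[imp$feature == "LPR"], 90)
  expect_equal(imp$selection_frequency[imp$feature == "LPR"], 100)
  expect_equal(imp$mean_importance[imp$feature == "MLU"], 50)
  expect_equal(imp$selection_frequency[imp$feature == "MLU"], 50)
  expect_false("TW" %in% imp$feature)  # never selected -> excluded
  expect_equal(rep$metrics$AUC, 0.85)
  expect_error(aggregate_report(list(), 2), "no completed")
})

test_that("the full protocol runs deterministically on a small cohort", {
  df <- gaussian_cohort(20, delta = 2, seed = 31, n_noise = 2)
  df$suvr <- rnorm(40, 1.2, 0.2) + 0.3 * (df$group == "early_AD")
  df$hippocampus_cm3 <- rnorm(40, 4.8, 0.5)
  names(df)[names(df) == "feat"] <- "MLU"
  for (f in setdiff(feature_names(), c("MLU"))) {
    if (!f %in% names(df)) df[[f]] <- rnorm(40)
  }
  ctl <- classification_control(n_repeats = 2, rfe_folds = 3, rfe_repeats = 1,
                                tune_folds = 3, tune_repeats = 1,
                                grid_size = 2, rf_ntree = 100,
                                n_permutations = 3)
  r1 <- run_classification(df, models = "rf", sets = c("linguistic", "combined"),
                           control = ctl, seed = 77)
  r2 <- run_classification(df, models = "rf", sets = c("linguistic", "combined"),
                           control = ctl, seed = 77)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$importance, r2$importance)
  expect_true(all(r1$metrics$AUC >= 0 & r1$metrics$AUC <= 1))
  # combined should be at least roughly as good as linguistic here
  expect_true(all(c("linguistic", "combined") %in% r1$metrics$set))
})
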
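## VIF screening, per-score linear models with covariates, RFE by RMSE, and
## residual diagnostics.

#' Compute variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j on
#' all the others. Perfect collinearity gives `Inf`.
#'
#' @param x Numeric predictor matrix or data frame (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif_values <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("VIF needs at least two predictors")
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, colnames(x))
}

#' Iterative VIF screening
#'
#' Repeatedly removes the predictor with the largest variance inflation
#' factor while that VIF exceeds the threshold (strictly greater than five by
#' default, so a VIF of exactly 5 is retained). Among perfectly collinear
#' predictors (infinite VIF) the later-listed one is removed, with a warning.
#' Survivors are returned in input order. The screen is invariant to affine
#' rescaling of any predictor.
#'
#' @param x Numeric predictor matrix or data frame.
#' @param threshold Removal threshold (strict inequality).
#' @return Character vector of retained column names, with the per-step VIF
#'   history in attribute `"history"`.
#' @export
vif_filter <- function(x, threshold = 5) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("VIF screening needs at least two predictors")
  keep <- colnames(x)
  history <- list()
  repeat {
    if (length(keep) < 2L) break
    v <- vif_values(x[, keep, drop = FALSE])
    history[[length(history) + 1L]] <- v
    ## strictly greater than the threshold, robust to float rounding: a VIF
    ## of exactly `threshold` is retained
    if (all(v <= threshold * (1 + 1e-8))) break
    if (any(is.infinite(v))) {
      drop_name <- keep[max(which(is.infinite(v)))]
      warning("perfectly collinear predictor removed: ", drop_name)
    } else {
      drop_name <- keep[which.max(v)]
    }
    keep <- setdiff(keep, drop_name)
  }
  structure(keep, history = history)
}

#' Fit a linear model of a cognitive score on standardized predictors
#'
#' Ordinary least squares of the outcome (on its native scale) on z-scored
#' predictors and covariates, computed on complete cases for this outcome.
#' Reports standardized coefficients with standard errors, R-squared and
#' AIC/BIC under the Gaussian log-likelihood convention (constant included,
#' matching standard statistical software).
#'
#' @param outcome Numeric outcome vector.
#' @param predictors Data frame or matrix of candidate predictors.
#' @param covariates Optional data frame of covariates (standardized and
#'   fitted alongside the predictors); use `NULL` for none.
#' @return Object of class `score_model`: coefficient table, `r_squared`,
#'   `aic`, `bic`, `n`, and the underlying `lm` fit.
#' @export
fit_score_model <- function(outcome, predictors, covariates = NULL) {
  predictors <- as.data.frame(predictors)
  dat <- if (is.null(covariates)) predictors else cbind(predictors, covariates)
  ok <- !is.na(outcome) & stats::complete.cases(dat)
  n <- sum(ok)
  p <- ncol(dat)
  if (n <= p + 2L) stop("too few complete cases (n = ", n, ") for ", p, " predictors")
  z <- as.data.frame(lapply(dat[ok, , drop = FALSE], function(col) {
    s <- stats::sd(col)
    if (s == 0) col - mean(col) else (col - mean(col)) / s
  }))
  z$.outcome <- outcome[ok]
  fit <- stats::lm(.outcome ~ ., data = z)
  co <- summary(fit)$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co),
                                   estimate = co[, "Estimate"],
                                   std_error = co[, "Std. Error"],
                                   p_value = co[, "Pr(>|t|)"],
                                   row.names = NULL),
         r_squared = summary(fit)$r.squared,
         aic = stats::AIC(fit), bic = stats::BIC(fit),
         n = n, fit = fit),
    class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> n = %d, R^2 = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$n, x$r_squared, x$aic, x$bic))
  co <- x$coefficients
  co$estimate <- round(co$estimate, 3)
  co$std_error <- round(co$std_error, 3)
  co$p_value <- signif(co$p_value, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Recursive feature elimination for regression, minimizing RMSE
#'
#' Backward elimination over subset sizes 1..p: within each cross-validation
#' fold the candidate predictors are ranked by the absolute t-statistic of a
#' linear fit (re-ranked after every elimination), and the held-out RMSE of
#' the top-s subset is recorded for every size. The size with the smallest
#' mean cross-validated RMSE wins; ties go to the smaller subset. The
#' returned set comes from eliminating on the full data down to that size.
#'
#' @param outcome Numeric outcome vector (complete cases only).
#' @param x Candidate predictor matrix (already VIF-screened).
#' @param folds,repeats Cross-validation design.
#' @param seed Integer seed for fold draws.
#' @return Character vector of selected predictor names.
#' @export
rfe_regression <- function(outcome, x, folds = 10, repeats = 5, seed = 1) {
  x <- as.matrix(x)
  ok <- !is.na(outcome) & stats::complete.cases(x)
  y <- outcome[ok]
  x <- x[ok, , drop = FALSE]
  p <- ncol(x)
  if (p < 1L) stop("need at least one predictor")
  if (p == 1L) return(colnames(x))
  lm_rank <- function(xx, yy) {
    fit <- stats::lm(yy ~ ., data = as.data.frame(xx))
    co <- summary(fit)$coefficients
    tt <- rep(0, ncol(xx))
    names(tt) <- colnames(xx)
    present <- intersect(rownames(co), make.names(colnames(xx)))
    tt[match(present, make.names(colnames(xx)))] <-
      abs(co[present, "t value"])
    tt
  }
  set.seed(seed)
  fold_sets <- lapply(seq_len(repeats), function(r) {
    assign_id <- rep_len(seq_len(folds), length(y))[sample.int(length(y))]
    lapply(seq_len(folds), function(f) which(assign_id == f))
  })
  fold_sets <- unlist(fold_sets, recursive = FALSE)
  rmse <- matrix(NA_real_, nrow = length(fold_sets), ncol = p)
  for (f in seq_along(fold_sets)) {
    hold <- fold_sets[[f]]
    if (!length(hold) || length(hold) == length(y)) next
    xa <- x[-hold, , drop = FALSE]
    ya <- y[-hold]
    feats <- colnames(x)
    for (s in p:1) {
      fit <- stats::lm(ya ~ ., data = as.data.frame(xa[, feats, drop = FALSE]))
      pred <- predict(fit, newdata = as.data.frame(x[hold, feats, drop = FALSE]))
      rmse[f, s] <- sqrt(mean((y[hold] - pred)^2))
      if (s > 1L) {
        rk <- lm_rank(xa[, feats, drop = FALSE], ya)
        feats <- feats[-which.min(rk)]
      }
    }
  }
  mean_rmse <- colMeans(rmse, na.rm = TRUE)
  best <- which(mean_rmse <= min(mean_rmse) + 1e-12)[1]  # ties -> smaller size
  feats <- colnames(x)
  while (length(feats) > best) {
    rk <- lm_rank(x[, feats, drop = FALSE], y)
    feats <- feats[-which.min(rk)]
  }
  feats
}

#' Residual diagnostics for a fitted score model
#'
#' Reports residual skewness and excess kurtosis, a Shapiro-Wilk normality
#' test, the linear trend of residuals on fitted values (zero by construction
#' in OLS; reported as a sanity check) and the quadratic curvature term of
#' residuals on fitted values, whose significance flags a violated linearity
#' assumption. Diagnostics flag problems only; no refitting is performed.
#'
#' @param fit A `score_model` or `lm` object.
#' @return List with `skewness`, `kurtosis_excess`, `normality_p`,
#'   `trend_slope`, `curvature`, `curvature_p` and logical flags
#'   `non_normal`, `curved`.
#' @export
residual_diagnostics <- function(fit) {
  if (inherits(fit, "score_model")) fit <- fit$fit
  res <- stats::residuals(fit)
  ftd <- stats::fitted(fit)
  n <- length(res)
  s <- stats::sd(res)
  if (!is.finite(s) || s < 1e-10 * max(stats::sd(ftd), 1)) {
    return(list(skewness = NA_real_, kurtosis_excess = NA_real_,
                normality_p = NA_real_, trend_slope = 0,
                curvature = NA_real_, curvature_p = NA_real_,
                non_normal = FALSE, curved = FALSE, degenerate = TRUE))
  }
  z <- (res - mean(res)) / s
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  norm_p <- if (n >= 3 && n <= 5000) stats::shapiro.test(res)$p.value else NA_real_
  trend <- stats::coef(stats::lm(res ~ ftd))[2]
  curv_fit <- if (stats::sd(ftd) > 0) {
    summary(stats::lm(res ~ stats::poly(ftd, 2)))$coefficients
  } else NULL
  curvature <- if (!is.null(curv_fit) && nrow(curv_fit) >= 3) curv_fit[3, "Estimate"] else NA_real_
  curvature_p <- if (!is.null(curv_fit) && nrow(curv_fit) >= 3) curv_fit[3, "Pr(>|t|)"] else NA_real_
  list(skewness = skew, kurtosis_excess = kurt, normality_p = norm_p,
       trend_slope = unname(trend), curvature = unname(curvature),
       curvature_p = unname(curvature_p),
       non_normal = isTRUE(norm_p < 0.05),
       curved = isTRUE(curvature_p < 0.05), degenerate = FALSE)
}

#' Run the full regression protocol over the cognitive outcomes
#'
#' A single global VIF screen over the 15 linguistic features plus age and
#' education, then, per outcome: RFE by cross-validated RMSE over the
#' surviving candidates (covariates compete like any predictor), a
#' standardized-predictor linear fit on the outcome's complete cases, and
#' residual diagnostics.
#'
#' @param cohort Cohort table with features, covariates and score columns.
#' @param outcomes Score columns to model (default all nine).
#' @param vif_threshold VIF removal threshold.
#' @param folds,repeats Cross-validation design for RFE.
#' @param seed Master seed.
#' @return Object of class `regression_report`: `retained` (post-screen
#'   candidates), `vif` (pre-screen VIFs) and per-outcome `models`.
#' @export
run_regressions <- function(cohort, outcomes = score_names(), vif_threshold = 5,
                            folds = 10, repeats = 5, seed = 1) {
  candidates <- c(feature_names(), "age", "education")
  miss <- setdiff(candidates, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  x_all <- as.matrix(cohort[, candidates, drop = FALSE])
  cc <- stats::complete.cases(x_all)
  vif_pre <- vif_values(x_all[cc, , drop = FALSE])
  retained <- as.character(vif_filter(x_all[cc, , drop = FALSE],
                                      threshold = vif_threshold))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(outcomes))
  models <- list()
  for (i in seq_along(outcomes)) {
    oc <- outcomes[i]
    if (!oc %in% names(cohort)) stop("outcome not in cohort: ", oc)
    y <- cohort[[oc]]
    ok <- !is.na(y) & cc
    selected <- rfe_regression(y[ok], x_all[ok, retained, drop = FALSE],
                               folds = folds, repeats = repeats,
                               seed = seeds[i])
    fit <- fit_score_model(y[ok], as.data.frame(x_all[ok, selected, drop = FALSE]))
    models[[oc]] <- list(outcome = oc, selected = selected, model = fit,
                         diagnostics = residual_diagnostics(fit))
  }
  structure(list(retained = retained, vif = vif_pre, models = models),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report>\n")
  cat("retained after VIF screen:", paste(x$retained, collapse = ", "), "\n")
  for (m in x$models) {
    cat(sprintf("  %-7s n=%3d R^2=%.3f AIC=%8.2f BIC=%8.2f  predictors: %s\n",
                m$outcome, m$model$n, m$model$r_squared, m$model$aic,
                m$model$bic, paste(m$selected, collapse = ", ")))
  }
  invisible(x)
}
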
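## Covariate-adjusted group comparison of each linguistic feature.

#' Compare linguistic features between groups, adjusting for age and education
#'
#' For each feature, fits ordinary least squares
#' `feature ~ group + age + education` and reports the group term (early_AD
#' versus NC). Features are standardized (z-scored) before fitting so
#' coefficients are comparable across features; p-values are unaffected by the
#' rescaling. Rows with a missing value for a feature are dropped for that
#' feature only. No multiple-testing correction is applied by default, since
#' per-feature raw p-values are the conventional report; set `adjust = "BH"`
#' for Benjamini-Hochberg adjusted values in an extra column.
#'
#' @param cohort A cohort table (see [read_cohort()]) whose columns include
#'   the features to compare, `group`, `age` and `education`.
#' @param features Character vector of feature columns; defaults to the 15
#'   linguistic features.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per feature: `feature`,
#'   `group_coefficient` (standardized effect of early_AD), `standard_error`,
#'   `p_value`, `n_used` (and `p_adjusted` when requested).
#' @export
compare_groups <- function(cohort, features = feature_names(),
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  miss <- setdiff(c(features, "group", "age", "education"), names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  grp <- factor(cohort$group, levels = c("NC", "early_AD"))
  if (any(table(grp) < 5L)) stop("need at least 5 participants per group")
  rows <- lapply(features, function(f) {
    y <- cohort[[f]]
    ok <- !is.na(y) & !is.na(cohort$age) & !is.na(cohort$education) & !is.na(grp)
    n_used <- sum(ok)
    if (n_used < 10L || stats::sd(y[ok]) == 0) {
      if (n_used >= 10L) warning("feature ", f, " is constant; p-value undefined")
      return(data.frame(feature = f, group_coefficient = NA_real_,
                        standard_error = NA_real_, p_value = NA_real_,
                        n_used = n_used))
    }
    z <- as.numeric(scale(y[ok]))
    fit <- stats::lm(z ~ g + a + e,
                     data = data.frame(z = z, g = grp[ok],
                                       a = cohort$age[ok], e = cohort$education[ok]))
    co <- summary(fit)$coefficients
    row <- co["gearly_AD", ]
    data.frame(feature = f, group_coefficient = unname(row["Estimate"]),
               standard_error = unname(row["Std. Error"]),
               p_value = unname(row["Pr(>|t|)"]), n_used = n_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
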
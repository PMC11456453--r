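test_that("VIF values match the definitional regression and car::vif", {
  set.seed(1)
  x <- matrix(rnorm(1500), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  v <- vif_values(x)
  expect_true(all(abs(v - 1) < 0.05))       # independent predictors
  # cross-check against the established implementation
  y <- rnorm(500)
  vcar <- car::vif(lm(y ~ ., data = as.data.frame(x)))
  expect_equal(unname(v), unname(vcar), tolerance = 1e-8)
})

test_that("iterative screening removes exactly the right predictors", {
  set.seed(2)
  x1 <- rnorm(400); x2 <- rnorm(400)
  x3 <- x1 + x2 + rnorm(400, 0, 0.01)       # near-collinear triple
  x <- cbind(x1 = x1, x2 = x2, x3 = x3)
  expect_gt(max(vif_values(x)), 5)
  kept <- vif_filter(x)
  expect_length(kept, 2L)                    # exactly one member removed
  expect_true(all(vif_values(x[, kept]) <= 5))
  # independent set is retained whole
  set.seed(3)
  xi <- matrix(rnorm(2000), 500, 4, dimnames = list(NULL, paste0("v", 1:4)))
  expect_identical(as.character(vif_filter(xi)), paste0("v", 1:4))
  # perfectly collinear pair: the later-listed one goes, with a warning
  xp <- cbind(p1 = x1, p2 = 2 * x1)
  expect_warning(keptp <- vif_filter(xp), "p2")
  expect_identical(as.character(keptp), "p1")
})

test_that("a VIF of exactly five is retained (strictly greater than)", {
  set.seed(4)
  n <- 200
  a <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ a))
  e <- as.numeric(scale(e))
  # sample correlation exactly sqrt(0.8): R^2 = 0.8 -> VIF = 5.0
  b <- sqrt(0.8) * a + sqrt(0.2) * e
  x <- cbind(a = a, b = b)
  v <- vif_values(x)
  expect_equal(unname(v), c(5, 5), tolerance = 1e-9)
  expect_identical(as.character(vif_filter(x)), c("a", "b"))
})

test_that("the VIF screen is invariant to affine predictor rescaling", {
  set.seed(5)
  x1 <- rnorm(300); x2 <- rnorm(300); x3 <- x1 + x2 + rnorm(300, 0, 0.05)
  x <- cbind(u = x1, v = x2, w = x3)
  k1 <- as.character(vif_filter(x))
  x_scaled <- x
  x_scaled[, "w"] <- 1000 * x_scaled[, "w"] - 77
  x_scaled[, "u"] <- x_scaled[, "u"] / 3 + 5
  expect_identical(as.character(vif_filter(x_scaled)), k1)
})

test_that("score models recover exact and orthonormal-design solutions", {
  set.seed(6)
  z1 <- as.numeric(scale(rnorm(100)))
  m <- suppressWarnings(fit_score_model(2 * z1, data.frame(z1 = z1)))
  expect_equal(m$coefficients$estimate[m$coefficients$term == "z1"], 2,
               tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # with mutually orthogonal standardized predictors the standardized
  # coefficients equal the per-predictor covariances with the outcome
  q <- qr.Q(qr(scale(matrix(rnorm(300 * 3), 300, 3), center = TRUE,
                     scale = FALSE)))
  xo <- scale(q) # mean-zero, mutually orthogonal, unit-variance columns
  colnames(xo) <- c("o1", "o2", "o3")
  yo <- rnorm(300)
  mo <- fit_score_model(yo, as.data.frame(xo))
  co <- mo$coefficients
  for (j in colnames(xo)) {
    cov_j <- sum((xo[, j] - mean(xo[, j])) * (yo - mean(yo))) / (300 - 1)
    expect_equal(co$estimate[co$term == j], cov_j, tolerance = 1e-6)
  }
  # AIC/BIC relationship at n = 10 with k = 4 parameters
  set.seed(7)
  d <- data.frame(a = rnorm(10), b = rnorm(10))
  m10 <- fit_score_model(rnorm(10), d)
  expect_equal(m10$bic - m10$aic, 4 * (log(10) - 2), tolerance = 1e-10)
  expect_error(fit_score_model(rnorm(5), data.frame(a = rnorm(5),
                                                    b = rnorm(5),
                                                    c = rnorm(5))),
               "too few")
})

test_that("confidence intervals achieve close to nominal coverage", {
  covered <- 0L; total <- 0L
  for (r in 1:30) {
    set.seed(500 + r)
    n <- 300
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    beta <- c(1.5, -0.8, 0.3)
    y <- x %*% beta + rnorm(n, 0, sqrt(sum(beta^2)))  # R^2 about 0.5
    m <- fit_score_model(as.numeric(y), as.data.frame(x))
    co <- m$coefficients
    for (j in 1:3) {
      row <- co[co$term == c("a", "b", "c")[j], ]
      # predictors are standardized inside the fit; rescale the truth
      truth <- beta[j] * sd(x[, j])
      covered <- covered + (abs(row$estimate - truth) < 1.96 * row$std_error)
      total <- total + 1L
    }
  }
  expect_gt(covered / total, 0.88)
  expect_lt(covered / total, 1.0)
})

test_that("regression RFE finds planted predictors and prefers small subsets", {
  hits <- 0L
  for (r in 1:15) {
    set.seed(700 + r)
    x <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("p", 1:10)))
    y <- 2 * x[, 3] - 1.5 * x[, 7] + rnorm(200)
    sel <- rfe_regression(y, x, folds = 5, repeats = 2, seed = r)
    hits <- hits + all(c("p3", "p7") %in% sel)
  }
  expect_gte(hits, 13L)
  # pure-noise outcome: subset sizes concentrate low
  sizes <- integer(10)
  for (r in 1:10) {
    set.seed(800 + r)
    x <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("q", 1:8)))
    sizes[r] <- length(rfe_regression(rnorm(150), x, folds = 5, repeats = 2,
                                      seed = r))
  }
  expect_lte(median(sizes), 4)
  # single candidate: returned unchanged
  x1 <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "only"))
  expect_identical(rfe_regression(rnorm(50), x1), "only")
})

test_that("residual diagnostics flag curvature but pass Gaussian fits", {
  set.seed(9)
  x <- rnorm(500)
  ok <- fit_score_model(2 * x + rnorm(500), data.frame(x = x))
  d <- residual_diagnostics(ok)
  expect_lt(abs(d$trend_slope), 1e-8)   # OLS residuals are orthogonal to fitted
  expect_gt(d$normality_p, 0.001)
  expect_false(d$curved)
  # y = x^2 fit linearly: curvature must be flagged
  y2 <- x^2
  bad <- fit_score_model(y2, data.frame(x = x))
  d2 <- residual_diagnostics(bad)
  expect_true(d2$curved)
  # perfect fit: degenerate, reported as such
  d3 <- residual_diagnostics(suppressWarnings(
    fit_score_model(3 * x, data.frame(x = x))))
  expect_true(d3$degenerate)
})

test_that("the outcome-by-outcome driver screens once and fits each score", {
  set.seed(10)
  n <- 120
  df <- data.frame(participant_id = as.character(1:n),
                   group = rep(c("NC", "early_AD"), each = n / 2),
                   age = rnorm(n, 74, 6), education = rnorm(n, 12, 4))
  for (f in feature_names()) df[[f]] <- rnorm(n)
  df$TW <- df$UW / (0.5 + 0.01 * rnorm(n))  # force collinearity pressure
  df$MMSE <- 25 + 2 * scale(df$MLU)[, 1] + rnorm(n)
  df$CDR_SB <- 2 - 0.8 * scale(df$MLU)[, 1] + rnorm(n)
  rep <- run_regressions(df, outcomes = c("MMSE", "CDR_SB"), folds = 4,
                         repeats = 1, seed = 5)
  expect_true(all(c("MMSE", "CDR_SB") %in% names(rep$models)))
  expect_true(all(rep$models$MMSE$selected %in% rep$retained))
  expect_true("MLU" %in% rep$models$MMSE$selected)
  m <- rep$models$MMSE$model
  expect_true(m$r_squared > 0.5 && m$r_squared <= 1)
  expect_gt(m$bic, m$aic)
})
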
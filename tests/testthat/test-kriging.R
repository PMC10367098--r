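test_that("the SSPE calibration constant comes from the chi-squared median", {
  expect_equal(sspe_expected_median(), qchisq(0.5, 1))
  expect_equal(round(sspe_expected_median(), 3), 0.455)
})

test_that("kriging interpolates exactly at data points with zero nugget", {
  m <- variogram_model("exponential", c0 = 0, c1 = 10, a = 3)
  rec <- data.frame(x = c(0, 4, 1), y = c(0, 0, 3), se = c(5, 9, 7))
  at_datum <- krige(m, rec, c(4, 0))
  expect_equal(at_datum$prediction, 9, tolerance = 1e-10)
  expect_equal(at_datum$variance, 0, tolerance = 1e-10)
})

test_that("a pure-nugget model predicts the arithmetic mean everywhere", {
  m <- variogram_model("nugget", c0 = 6, c1 = 0)
  set.seed(3)
  rec <- data.frame(x = runif(10, 0, 5), y = runif(10, 0, 5), se = rnorm(10))
  for (target in list(c(2, 2), c(-10, 40))) {
    kr <- krige(m, rec, target, keep_weights = TRUE)
    expect_equal(kr$prediction, mean(rec$se), tolerance = 1e-10)
    expect_equal(drop(attr(kr, "weights")), rep(0.1, 10), tolerance = 1e-10)
    # prediction variance of a new observation against the mean of n
    expect_equal(kr$variance, 6 * (1 + 1 / 10), tolerance = 1e-10)
  }
})

test_that("a 3-point configuration matches the hand-built bordered system", {
  m <- variogram_model("exponential", c0 = 2, c1 = 8, a = 5)
  rec <- data.frame(x = c(0, 6, 2), y = c(0, 0, 5), se = c(10, 14, 11))
  target <- c(3, 2)
  g <- function(h) 2 + 8 * (1 - exp(-h / 5))
  d <- function(p, q) sqrt(sum((p - q)^2))
  pts <- list(c(0, 0), c(6, 0), c(2, 5))
  A <- matrix(1, 4, 4); A[4, 4] <- 0
  for (i in 1:3) for (j in 1:3) A[i, j] <- if (i == j) 0 else g(d(pts[[i]], pts[[j]]))
  b <- c(vapply(pts, function(p) g(d(p, target)), numeric(1)), 1)
  sol <- solve(A, b)
  kr <- krige(m, rec, target)
  expect_equal(kr$prediction, sum(sol[1:3] * rec$se), tolerance = 1e-10)
  expect_equal(kr$variance, sum(sol[1:3] * b[1:3]) + sol[4], tolerance = 1e-10)
})

test_that("weights sum to one and predictions are translation-equivariant", {
  set.seed(97)
  m <- variogram_model("spherical", c0 = 3, c1 = 12, a = 8)
  rec <- data.frame(x = runif(30, 0, 20), y = runif(30, 0, 20),
                    se = rnorm(30, 50, 5))
  targets <- cbind(runif(15, 5, 15), runif(15, 5, 15))  # inside the data hull
  kr <- krige(m, rec, targets, keep_weights = TRUE)
  expect_equal(colSums(attr(kr, "weights")), rep(1, 15), tolerance = 1e-10)
  rec2 <- rec; rec2$se <- rec$se + 42
  kr2 <- krige(m, rec2, targets)
  expect_equal(kr2$prediction, kr$prediction + 42, tolerance = 1e-8)
  expect_equal(kr2$variance, kr$variance, tolerance = 1e-10)
  # extrapolation flagging
  far <- krige(m, rec, c(100, 100))
  expect_true(far$extrapolated)
  expect_false(any(kr$extrapolated))
})

test_that("duplicate locations under zero nugget break the system", {
  m <- variogram_model("exponential", c0 = 0, c1 = 5, a = 2)
  rec <- data.frame(x = c(1, 1, 3), y = c(1, 1, 2), se = c(4, 6, 5))
  expect_error(krige(m, rec, c(2, 2)), "singular")
  # a nugget restores solvability
  m2 <- variogram_model("exponential", c0 = 1, c1 = 5, a = 2)
  expect_silent(krige(m2, rec, c(2, 2)))
})

test_that("LOO cross-validation reports finite errors and honest exclusions", {
  m <- variogram_model("exponential", c0 = 1, c1 = 4, a = 2)
  rec3 <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 0, 0),
                     se = c(3, 5, 4))
  cv <- loo_cross_validate(m, rec3)
  expect_equal(cv$n, 3)
  expect_true(all(is.finite(cv$sspe)))
  expect_true(cv$ci95[1] <= cv$median_sspe && cv$median_sspe <= cv$ci95[2])
  # duplicate locations with c0 = 0: every fold degenerates - either the
  # left-in duplicate pair makes the system singular, or the target
  # coincides with its duplicate and gets zero variance; all are flagged
  m0 <- variogram_model("exponential", c0 = 0, c1 = 4, a = 2)
  dup <- data.frame(id = as.character(1:4), x = c(0, 0, 1, 2), y = 0,
                    se = c(3, 3, 5, 4))
  expect_warning(cv0 <- loo_cross_validate(m0, dup), "no valid")
  expect_equal(cv0$n_excluded, 4)
  expect_equal(cv0$n, 0)
  expect_true(is.na(cv0$median_sspe))
  # a nugget keeps every fold usable
  m1 <- variogram_model("exponential", c0 = 1, c1 = 4, a = 2)
  cv1 <- loo_cross_validate(m1, dup)
  expect_equal(cv1$n_excluded, 0)
  expect_equal(cv1$n, 4)
})

test_that("overstating the nugget deflates the median SSPE", {
  d <- reference_dataset(55)
  true_m <- variogram_model("exponential", c0 = 40, c1 = 120, a = 5)
  infl_m <- variogram_model("exponential", c0 = 400, c1 = 120, a = 5)
  cv_true <- loo_cross_validate(true_m, d$records)
  cv_infl <- loo_cross_validate(infl_m, d$records)
  expect_lt(cv_infl$median_sspe, 0.6 * cv_true$median_sspe)
  expect_lt(cv_infl$median_sspe, 0.3)
})

test_that("the median order-statistic interval covers the true median", {
  # coverage of the binomial interval for the chi-squared(1) median
  set.seed(131)
  hits <- 0
  for (r in 1:200) {
    x <- rnorm(101)^2
    ci <- median_order_ci(x)
    if (ci[1] <= qchisq(0.5, 1) && qchisq(0.5, 1) <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("model selection minimises distance to 0.455 with documented ties", {
  mk <- function(median, family) {
    structure(list(sspe = rep(median, 9), median_sspe = median,
                   ci95 = c(median - 0.05, median + 0.05), n = 9,
                   n_excluded = 0,
                   model = variogram_model(family, c0 = 1, c1 = 1,
                                           a = if (family == "nugget") NA else 1)),
              class = "cv_report")
  }
  # medians as in a district cross-validation table: 0.431 vs 0.432; the
  # spherical median is 0.001 closer to the chi-squared(1) median
  sel <- select_model(list(mk(0.431, "exponential"), mk(0.432, "spherical")))
  expect_equal(sel$model$family, "spherical")
  expect_equal(sel$table$distance, abs(c(0.431, 0.432) - qchisq(0.5, 1)))
  sel2 <- select_model(list(mk(0.455, "exponential"), mk(0.439, "spherical")))
  expect_equal(sel2$model$family, "exponential")
  expect_equal(sel2$table$distance[1], abs(0.455 - qchisq(0.5, 1)))
  expect_true(sel2$table$target_in_ci[1])
  # exact tie: exponential preferred over spherical
  tie <- select_model(list(mk(0.5, "spherical"), mk(0.5, "exponential")))
  expect_equal(tie$model$family, "exponential")
  one <- select_model(list(mk(0.7, "spherical")))
  expect_equal(one$model$family, "spherical")
  expect_error(select_model(list()), "no candidate")
})
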
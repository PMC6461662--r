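test_that("AUC matches closed cases and exhaustive pairwise counting", {
  u <- univariate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(u$auc, 1)
  expect_equal(u$best_threshold, 2.5)
  expect_equal(u$sensitivity + u$specificity - 1, 1)

  expect_equal(auc_mann_whitney(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)

  withr::with_seed(19, {
    for (i in 1:8) {
      n <- sample(c(10, 57, 500), 1)
      y <- rbinom(n, 1, 0.45)
      if (length(unique(y)) < 2) next
      v <- round(rnorm(n, y, 1.3), 1) # rounding induces ties
      expect_identical(auc_mann_whitney(v, y), auc_bruteforce(v, y))
    }
  })
})

test_that("AUC is invariant under strictly monotone transforms and direction-aware", {
  withr::with_seed(23, {
    y <- rbinom(80, 1, 0.5)
    v <- rnorm(80, y)
    a <- auc_mann_whitney(v, y)
    expect_equal(auc_mann_whitney(exp(v), y), a)
    expect_equal(auc_mann_whitney(qlogis(plogis(v)), y), a, tolerance = 1e-12)
    # negation flips the direction, univariate_auc reports AUC >= 0.5
    u <- univariate_auc(-v, y, n_boot = 0)
    expect_equal(u$auc, max(a, 1 - a))
    expect_equal(u$direction, "less")
  })
  expect_error(univariate_auc(1:5, rep(1, 5), n_boot = 0), "both classes")
})

test_that("the Youden threshold reproduces its reported operating point", {
  withr::with_seed(29, {
    y <- rbinom(120, 1, 0.5)
    v <- rnorm(120, 0.8 * y)
    u <- univariate_auc(v, y, n_boot = 0)
    expect_equal(mean(v[y == 1] > u$best_threshold), u$sensitivity)
    expect_equal(mean(v[y == 0] <= u$best_threshold), u$specificity)
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    y <- rbinom(60, 1, 0.5)
    v <- round(rnorm(60, y), 1)
    ref <- as.numeric(suppressMessages(pROC::auc(y, v, direction = "<")))
    expect_equal(auc_mann_whitney(v, y), ref, tolerance = 1e-12)
  })
})

test_that("correlation screen computes Fisher-Z tests and flags redundancy", {
  ft <- default_cohort_fixture()$ft
  feats <- c("mean_hu", "q50_hu", "sd_hu", "diameter_ratio")
  sc <- correlation_screen(ft, feats)
  expect_equal(diag(sc$r), rep(1, 4), ignore_attr = TRUE)
  # closed form: z = atanh(r) * sqrt(n - 3)
  r <- sc$r["mean_hu", "q50_hu"]
  z <- atanh(r) * sqrt(nrow(ft) - 3)
  expect_equal(sc$p["mean_hu", "q50_hu"], 2 * pnorm(-abs(z)))
  expect_equal(2 * pnorm(-abs(atanh(0.99) * sqrt(109 - 3))) < 1e-10, TRUE)
  # mean HU and the histogram median are nearly collinear: flagged, and the
  # flagged member is the one with the lower univariate AUC
  expect_gte(abs(r), 0.9)
  flagged <- sc$flags[sc$flags$feature_a %in% c("mean_hu", "q50_hu") &
                        sc$flags$feature_b %in% c("mean_hu", "q50_hu"), ]
  expect_equal(nrow(flagged), 1L)
  aucs <- sc$univariate_auc[c("mean_hu", "q50_hu")]
  expect_equal(flagged$drop_candidate, names(aucs)[which.min(aucs)])

  # zero-variance features are excluded, not fatal
  ft$flat <- 1
  sc2 <- correlation_screen(ft, c(feats, "flat"))
  expect_equal(sc2$zero_variance, "flat")
})

test_that("the redundancy flag has nominal type-I rate on independent features", {
  hits <- withr::with_seed(37, {
    mean(replicate(1000, {
      x <- rnorm(109); y <- rnorm(109)
      r <- cor(x, y)
      2 * pnorm(-abs(atanh(r) * sqrt(106))) < 0.05
    }))
  })
  expect_equal(hits, 0.05, tolerance = 0.02 / 0.05)
})

test_that("logistic fitting recovers parameters and is invariant to duplication", {
  dat <- withr::with_seed(41, {
    x <- rnorm(5000)
    data.frame(x = x,
               class_label = rbinom(5000, 1, plogis(1 + 2 * x)))
  })
  fit <- fit_logistic(dat, "x")
  # undo the internal standardization to compare with the generative scale
  slope <- coef(fit$fit)[["x"]] / fit$scale[["x"]]
  intercept <- coef(fit$fit)[["(Intercept)"]] - slope * fit$center[["x"]]
  expect_equal(slope, 2, tolerance = 0.1)
  expect_equal(intercept, 1, tolerance = 0.1)

  # duplication leaves the maximum-likelihood fit unchanged (compare on the
  # original scale; the internal standardization uses the sample sd, whose
  # n-1 denominator differs between the two datasets)
  fit2 <- fit_logistic(rbind(dat, dat), "x")
  expect_equal(coef(fit2$fit)[["x"]] / fit2$scale[["x"]],
               coef(fit$fit)[["x"]] / fit$scale[["x"]], tolerance = 1e-6)

  # a label-independent predictor has a slope within 2 SE of zero
  null_dat <- withr::with_seed(43, data.frame(
    x = rnorm(2000), class_label = rbinom(2000, 1, 0.5)))
  nf <- fit_logistic(null_dat, "x")
  expect_lt(abs(coef(nf$fit)[["x"]]),
            2 * summary(nf$fit)$coefficients["x", "Std. Error"])

  # perfect separation is surfaced, not silent
  sep <- data.frame(x = c(1:5, 11:15), class_label = rep(c(0, 1), each = 5))
  expect_warning(fit_logistic(sep, "x"), "separation")
  expect_error(fit_logistic(sep, "zz"), "missing predictor")
})

test_that("repeated stratified CV behaves at the null, at separation, and at a binormal design", {
  null_dat <- withr::with_seed(47, data.frame(
    x = rnorm(200), class_label = rep(c(0, 1), 100)))
  cvn <- repeated_kfold_cv(null_dat, "x", k = 10, repeats = 20, seed = 5)
  expect_equal(unname(cvn$auc["mean"]), 0.5, tolerance = 0.05 / 0.5)
  expect_false(anyNA(cvn$oof)) # every nodule predicted once per repeat

  sep <- data.frame(x = c(rnorm(50), rnorm(50) + 20),
                    class_label = rep(c(0, 1), each = 50))
  cvs <- repeated_kfold_cv(sep, "x", k = 5, repeats = 5, seed = 5)
  expect_equal(unname(cvs$auc["mean"]), 1)
  expect_equal(unname(cvs$accuracy["mean"]), 1)

  # two-Gaussian feature with designed AUC Phi(delta/sqrt(2)) = 0.80
  delta <- sqrt(2) * qnorm(0.8)
  bn <- withr::with_seed(53, data.frame(
    x = rnorm(500) + delta * rep(c(0, 1), each = 250),
    class_label = rep(c(0, 1), each = 250)))
  cvb <- repeated_kfold_cv(bn, "x", k = 10, repeats = 10, seed = 7)
  expect_equal(unname(cvb$auc["mean"]), 0.8, tolerance = 0.03 / 0.8)

  expect_error(repeated_kfold_cv(null_dat[1:8, ], "x", k = 10, repeats = 2),
               "at least k")
  # reproducibility under the same master seed
  cvn2 <- repeated_kfold_cv(null_dat, "x", k = 10, repeats = 20, seed = 5)
  expect_identical(cvn$per_repeat, cvn2$per_repeat)
})

test_that("calibration error is small when well-specified and grows when distorted", {
  dat <- withr::with_seed(59, {
    x <- rnorm(2000)
    data.frame(x = x, class_label = rbinom(2000, 1, plogis(0.3 + 1.5 * x)))
  })
  cal <- calibration_error(dat, "x", n_bootstrap = 60, seed = 2)
  expect_lt(cal$mean_absolute_calibration_error, 0.03)
  expect_true(all(cal$curve$corrected >= 0 & cal$curve$corrected <= 1))

  # deliberately miscalibrated outcome process: y ~ Bernoulli(p^2)
  mis <- withr::with_seed(61, {
    x <- rnorm(2000)
    data.frame(x = x, class_label = rbinom(2000, 1, plogis(0.3 + 1.5 * x)^2))
  })
  calm <- calibration_error(mis, "x", n_bootstrap = 60, seed = 2)
  expect_gt(calm$mean_absolute_calibration_error,
            cal$mean_absolute_calibration_error)
  expect_error(calibration_error(dat, "x", n_bootstrap = 10), "unstable")
})

test_that("the model evaluation report is complete and deterministic", {
  ft <- default_cohort_fixture()$ft_fpc
  ev <- evaluate_models(ft, seed = 11, repeats = 4, n_boot = 50,
                        n_bootstrap_cal = 25)
  expect_equal(nrow(ev$table4), 3L)
  specs <- model_specs()
  for (nm in names(specs))
    expect_equal(ev$table4$predictors[ev$table4$model == nm],
                 paste(specs[[nm]], collapse = " + "))
  expect_equal(nrow(ev$table3), 16L)
  expect_false(anyNA(ev$table3$auc))

  ev2 <- evaluate_models(ft, seed = 11, repeats = 4, n_boot = 50,
                         n_bootstrap_cal = 25)
  expect_identical(ev$table3, ev2$table3)
  expect_identical(ev$table4, ev2$table4)

  expect_error(evaluate_models(default_cohort_fixture()$ft, seed = 1),
               "FPCA stage")
})

test_that("attenuation summaries outrank diameter features in univariate screening", {
  ft <- default_cohort_fixture()$ft_fpc
  hu_feats <- c("mean_hu", "sd_hu", "q875_hu", "iqr_hu")
  diam_feats <- c("min_diameter_mm", "diameter_ratio")
  auc_of <- function(f) {
    a <- auc_mann_whitney(ft[[f]], ft$class_label)
    max(a, 1 - a)
  }
  expect_gt(mean(sapply(hu_feats, auc_of)), mean(sapply(diam_feats, auc_of)))
})
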
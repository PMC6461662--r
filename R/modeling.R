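# Univariate screening, correlation screening, and repeated cross-validated
# logistic models for the binary invasiveness classification (T1 vs T2,
# positive class = T2 / invasive).

as01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) as.integer(labels == "T2")
  else as.integer(labels)
}

#' Mann-Whitney ROC AUC
#'
#' Rank-statistic AUC with ties counted 1/2; equals exhaustive pairwise
#' counting over all positive/negative pairs.
#'
#' @param values feature values
#' @param labels binary labels (0/1 or "T1"/"T2"; positive = 1/"T2")
#' @return AUC for the "greater" direction (higher value predicts positive)
#' @export
auc_mann_whitney <- function(values, labels) {
  y <- as01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Univariate ROC analysis of one feature
#'
#' AUC by the Mann-Whitney statistic, with direction chosen so AUC >= 0.5;
#' the optimal operating threshold maximizes the Youden index
#' J = sensitivity + specificity - 1 over midpoints between adjacent
#' distinct values (smallest threshold on ties); the AUC confidence interval
#' is a stratified percentile bootstrap.
#'
#' @param values feature values
#' @param labels binary labels (positive = "T2"/1)
#' @param n_boot bootstrap resamples for the CI (default 2000)
#' @param conf confidence level
#' @param seed optional seed for the bootstrap
#' @return list: `auc`, `ci_low`, `ci_high`, `direction` ("greater" if high
#'   values predict the positive class), `best_threshold`, `sensitivity`,
#'   `specificity`
#' @export
univariate_auc <- function(values, labels, n_boot = 2000L, conf = 0.95,
                           seed = NULL) {
  y <- as01(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(values) == length(y), length(y) >= 4)
  a <- auc_mann_whitney(values, y)
  direction <- if (a >= 0.5) "greater" else "less"
  v <- if (direction == "greater") values else -values
  a <- max(a, 1 - a)
  # Youden scan over midpoints between adjacent distinct sorted values
  u <- sort(unique(v))
  thr <- if (length(u) > 1) (utils::head(u, -1) + utils::tail(u, -1)) / 2 else u
  J <- vapply(thr, function(t) {
    sens <- mean(v[y == 1] > t)
    spec <- mean(v[y == 0] <= t)
    sens + spec - 1
  }, numeric(1))
  best <- thr[which.max(J)] # which.max takes the first (smallest threshold)
  sens <- mean(v[y == 1] > best)
  spec <- mean(v[y == 0] <= best)
  boot_auc <- numeric(0)
  if (n_boot > 0) {
    run <- function() {
      i1 <- which(y == 1); i0 <- which(y == 0)
      vapply(seq_len(n_boot), function(b) {
        ii <- c(sample(i1, length(i1), TRUE), sample(i0, length(i0), TRUE))
        ab <- auc_mann_whitney(values[ii], y[ii])
        max(ab, 1 - ab)
      }, numeric(1))
    }
    boot_auc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  }
  alpha <- (1 - conf) / 2
  ci <- if (length(boot_auc)) unname(stats::quantile(boot_auc, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  list(auc = a, ci_low = ci[1], ci_high = ci[2], direction = direction,
       best_threshold = if (direction == "greater") best else -best,
       sensitivity = sens, specificity = spec)
}

#' Pairwise correlation screen with Fisher-Z tests
#'
#' Pearson correlations for all feature pairs, two-sided p-values from the
#' Fisher Z transform, and redundancy flags for highly correlated pairs
#' (|r| >= `r_flag`) annotated with the member whose univariate AUC is
#' lower (the screening rule discards that one).
#'
#' @param feature_table data.frame with the feature columns and a
#'   `class_label` column
#' @param features character vector of feature column names
#' @param r_flag absolute correlation threshold (default 0.9)
#' @return list: `r` (correlation matrix), `p` (Fisher-Z p matrix), `flags`
#'   (data.frame of flagged pairs with the lower-AUC member), `zero_variance`
#'   (names of constant columns, excluded rather than crashed on)
#' @export
correlation_screen <- function(feature_table, features = NULL, r_flag = 0.9) {
  if (is.null(features))
    features <- setdiff(names(feature_table),
                        c("nodule_id", "class_label", "pathology_subtype"))
  X <- as.matrix(feature_table[features])
  if (nrow(X) < 3) stop("need at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  zero_var <- features[sds == 0]
  ok <- features[sds > 0]
  r <- stats::cor(X[, ok, drop = FALSE])
  n <- nrow(X)
  z <- atanh(clamp(r, -1 + 1e-15, 1 - 1e-15)) * sqrt(n - 3)
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 0
  aucs <- vapply(ok, function(f)
    max(auc_mann_whitney(feature_table[[f]], feature_table$class_label),
        1 - auc_mann_whitney(feature_table[[f]], feature_table$class_label)),
    numeric(1))
  flags <- data.frame(feature_a = character(0), feature_b = character(0),
                      r = numeric(0), drop_candidate = character(0))
  for (i in seq_along(ok)) for (j in seq_len(i - 1)) {
    if (abs(r[i, j]) >= r_flag) {
      drop <- if (aucs[i] <= aucs[j]) ok[i] else ok[j]
      flags <- rbind(flags, data.frame(feature_a = ok[j], feature_b = ok[i],
                                       r = r[i, j], drop_candidate = drop))
    }
  }
  list(r = r, p = p, flags = flags, zero_variance = zero_var,
       univariate_auc = aucs)
}

#' Predictor sets of the three final logistic models
#'
#' Model 1: Q.875 + IQR + volume + diameter ratio; model 2: FPC1 + volume +
#' diameter ratio; model 3: FPC1 + FPC2 + volume.
#' @return named list of character vectors of feature-table column names
#' @export
model_specs <- function() {
  list(model1 = c("q875_hu", "iqr_hu", "log10_volume", "diameter_ratio"),
       model2 = c("fpc1", "log10_volume", "diameter_ratio"),
       model3 = c("fpc1", "fpc2", "log10_volume"))
}

#' Fit a multiple logistic regression on standardized predictors
#'
#' Maximum-likelihood logistic fit (via `stats::glm`) after centering and
#' scaling each predictor; the scaling is stored so new data are transformed
#' with the training statistics. Perfect separation is surfaced as a warning
#' with a finite iteration cap, not silent divergence.
#'
#' @param feature_table data.frame with predictors and `class_label`
#' @param predictors character vector of predictor columns
#' @param max_iter IRLS iteration cap
#' @return an `ssn_logistic`: glm fit plus scaling, with a
#'   [predict_proba()] method
#' @export
fit_logistic <- function(feature_table, predictors, max_iter = 50L) {
  miss <- setdiff(predictors, names(feature_table))
  if (length(miss))
    stop("missing predictor columns: ", paste(miss, collapse = ", "),
         if (any(grepl("^fpc", miss))) " (run the FPCA stage first)" else "")
  X <- feature_table[predictors]
  if (anyNA(X)) stop("missing values in predictors")
  center <- vapply(X, mean, numeric(1))
  scale_ <- vapply(X, stats::sd, numeric(1))
  scale_[scale_ == 0] <- 1
  Xs <- as.data.frame(scale(X, center, scale_))
  Xs$.y <- as01(feature_table$class_label)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = Xs, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("possible perfect separation; coefficients capped at ",
                max_iter, " IRLS iterations", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, predictors = predictors,
                 center = center, scale = scale_),
            class = "ssn_logistic")
}

#' Predicted probabilities of the positive (invasive) class
#' @param model an `ssn_logistic`
#' @param newdata data.frame containing the model's predictors
#' @return probabilities in (0, 1)
#' @export
predict_proba <- function(model, newdata) {
  Xs <- as.data.frame(scale(newdata[model$predictors], model$center,
                            model$scale))
  clamp(stats::predict(model$fit, Xs, type = "response"), 1e-12, 1 - 1e-12)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of a logistic model
#'
#' Folds are stratified by class and redrawn each repeat from a per-repeat
#' stream derived from the master seed. All preprocessing (predictor
#' standardization) is learned inside the training folds. AUC is computed on
#' the pooled out-of-fold probabilities of each repeat; accuracy,
#' sensitivity and specificity use a fixed probability threshold of 0.5.
#' Point estimates are means over repeats; intervals are the 2.5/97.5
#' percentiles of the repeat-level metrics.
#'
#' @param feature_table data.frame with predictors and `class_label`
#' @param predictors character vector of predictor columns
#' @param k folds (default 10)
#' @param repeats repeats (default 100)
#' @param seed master seed
#' @return an `ssn_cv`: `auc`, `accuracy`, `sensitivity`, `specificity`
#'   (each `c(mean, lo, hi)`), `per_repeat` data.frame, `oof` n x repeats
#'   matrix of out-of-fold probabilities, `k`, `repeats`, `seed`
#' @export
repeated_kfold_cv <- function(feature_table, predictors, k = 10L,
                              repeats = 100L, seed = 1L) {
  y <- as01(feature_table$class_label)
  if (min(table(y)) < k) stop("each class needs at least k members")
  n <- length(y)
  oof <- matrix(NA_real_, n, repeats)
  met <- matrix(NA_real_, repeats, 4,
                dimnames = list(NULL, c("auc", "accuracy", "sensitivity",
                                        "specificity")))
  for (r in seq_len(repeats)) {
    withr::with_seed(derive_seed(seed, paste0("cv-repeat-", r)), {
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        test <- fold == f
        m <- suppressWarnings(fit_logistic(feature_table[!test, , drop = FALSE],
                                           predictors))
        oof[test, r] <- predict_proba(m, feature_table[test, , drop = FALSE])
      }
    })
    p <- oof[, r]
    cls <- as.integer(p > 0.5)
    met[r, ] <- c(auc_mann_whitney(p, y),
                  mean(cls == y),
                  mean(cls[y == 1] == 1),
                  mean(cls[y == 0] == 0))
  }
  summarize <- function(x) c(mean = mean(x),
                             lo = unname(stats::quantile(x, 0.025)),
                             hi = unname(stats::quantile(x, 0.975)))
  structure(list(auc = summarize(met[, "auc"]),
                 accuracy = summarize(met[, "accuracy"]),
                 sensitivity = summarize(met[, "sensitivity"]),
                 specificity = summarize(met[, "specificity"]),
                 per_repeat = as.data.frame(met), oof = oof,
                 k = k, repeats = repeats, seed = seed),
            class = "ssn_cv")
}

lowess_calibration <- function(p, y, at) {
  sm <- stats::lowess(p, y, f = 2 / 3, iter = 0)
  clamp(stats::approx(sm$x, sm$y, xout = at, rule = 2, ties = "ordered")$y, 0, 1)
}

#' Bootstrap optimism-corrected calibration of a logistic model
#'
#' Harrell-style resampling validation of the calibration curve: the
#' apparent curve is a nonparametric smoother (lowess) of the observed
#' outcome against the predicted probability; its optimism is estimated by
#' refitting the model on bootstrap resamples and contrasting the bootstrap
#' curve with its performance on the original sample. The mean absolute
#' calibration error averages |corrected curve - predicted| over the
#' sample's predicted probabilities.
#'
#' @param feature_table data.frame with predictors and `class_label`
#' @param predictors character vector of predictor columns
#' @param n_bootstrap bootstrap refits (default 200, minimum 20)
#' @param seed seed for resampling
#' @return an `ssn_calibration`: `mean_absolute_calibration_error`,
#'   `curve` (data.frame predicted / apparent / corrected), `n_bootstrap`
#' @export
calibration_error <- function(feature_table, predictors, n_bootstrap = 200L,
                              seed = 1L) {
  if (n_bootstrap < 20) stop("n_bootstrap < 20 gives unstable estimates")
  y <- as01(feature_table$class_label)
  full <- suppressWarnings(fit_logistic(feature_table, predictors))
  p_hat <- predict_proba(full, feature_table)
  ord <- order(p_hat)
  at <- p_hat[ord]
  apparent <- lowess_calibration(p_hat, y, at)
  optimism <- matrix(0, n_bootstrap, length(at))
  withr::with_seed(derive_seed(seed, "calibration-boot"), {
    n <- length(y)
    for (b in seq_len(n_bootstrap)) {
      ii <- sample.int(n, n, replace = TRUE)
      mb <- suppressWarnings(fit_logistic(feature_table[ii, , drop = FALSE],
                                          predictors))
      pb <- predict_proba(mb, feature_table[ii, , drop = FALSE])
      cal_boot <- lowess_calibration(pb, y[ii], at)
      p_orig <- predict_proba(mb, feature_table)
      cal_test <- lowess_calibration(p_orig, y, at)
      optimism[b, ] <- cal_boot - cal_test
    }
  })
  corrected <- clamp(apparent - colMeans(optimism), 0, 1)
  mace <- mean(abs(corrected - at))
  structure(list(mean_absolute_calibration_error = mace,
                 curve = data.frame(predicted = at, apparent = apparent,
                                    corrected = corrected),
                 n_bootstrap = n_bootstrap),
            class = "ssn_calibration")
}

# The univariate screening panel: every a-priori and functional predictor.
screening_features <- function(feature_table) {
  intersect(c("fpc1", "sd_hu", "q875_hu", "iqr_hu", "q75_hu",
              "consolidation_ratio", "mean_hu", "q50_hu", "kurtosis_hu",
              "max_diameter_mm", "skewness_hu", "log10_volume",
              "mean_diameter_mm", "diameter_ratio", "min_diameter_mm",
              "fpc2"),
            names(feature_table))
}

#' Full model evaluation report
#'
#' Produces the univariate screening table (AUC with bootstrap CI, Youden
#' threshold, sensitivity/specificity for every predictor, ranked by AUC),
#' the correlation screen, and repeated-CV plus calibration results for the
#' three final logistic models. Deterministic given the seed.
#'
#' @param feature_table feature table with FPC scores joined
#' @param seed master seed for bootstrap/CV streams
#' @param repeats CV repeats (default 100)
#' @param k CV folds (default 10)
#' @param n_boot bootstrap resamples for univariate CIs
#' @param n_bootstrap_cal bootstrap refits for calibration
#' @return list: `table3` (univariate screening data.frame), `correlogram`,
#'   `table4` (one row per model x metric), `cv` (per-model `ssn_cv`),
#'   `calibration` (per-model `ssn_calibration`)
#' @export
evaluate_models <- function(feature_table, seed = 1L, repeats = 100L,
                            k = 10L, n_boot = 2000L, n_bootstrap_cal = 200L) {
  feats <- screening_features(feature_table)
  if (!all(c("fpc1", "fpc2") %in% names(feature_table)))
    stop("feature table lacks fpc1/fpc2 columns: run the FPCA stage first")
  rows <- lapply(feats, function(f) {
    u <- univariate_auc(feature_table[[f]], feature_table$class_label,
                        n_boot = n_boot,
                        seed = derive_seed(seed, paste0("uniboot-", f)))
    data.frame(parameter = f, auc = u$auc, ci_low = u$ci_low,
               ci_high = u$ci_high, sensitivity = u$sensitivity,
               specificity = u$specificity, direction = u$direction,
               best_threshold = u$best_threshold)
  })
  table3 <- do.call(rbind, rows)
  table3 <- table3[order(-table3$auc), ]
  rownames(table3) <- NULL
  screen <- correlation_screen(feature_table, feats)
  specs <- model_specs()
  cv <- lapply(specs, function(p)
    repeated_kfold_cv(feature_table, p, k = k, repeats = repeats,
                      seed = seed))
  cal <- lapply(specs, function(p)
    calibration_error(feature_table, p, n_bootstrap = n_bootstrap_cal,
                      seed = seed))
  table4 <- do.call(rbind, lapply(names(specs), function(nm) {
    x <- cv[[nm]]
    data.frame(model = nm, predictors = paste(specs[[nm]], collapse = " + "),
               auc = x$auc["mean"], auc_lo = x$auc["lo"], auc_hi = x$auc["hi"],
               accuracy = x$accuracy["mean"], accuracy_lo = x$accuracy["lo"],
               accuracy_hi = x$accuracy["hi"],
               sensitivity = x$sensitivity["mean"],
               specificity = x$specificity["mean"],
               calibration_error = cal[[nm]]$mean_absolute_calibration_error)
  }))
  rownames(table4) <- NULL
  list(table3 = table3, correlogram = screen, table4 = table4,
       cv = cv, calibration = cal)
}
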
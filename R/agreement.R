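# Inter-reader reproducibility of the classification pipeline: chance-
# corrected agreement of predicted classes (Cohen's kappa) and absolute-
# agreement ICC of predicted probabilities between two reader-variant
# cohorts.

#' Cohen's kappa for two binary ratings
#'
#' kappa = (p_o - p_e) / (1 - p_e) from the 2x2 agreement table, with a
#' percentile bootstrap CI over paired (subject-level) resampling. When both
#' raters are constant and identical, agreement is perfect and kappa is
#' defined as 1; constant but discordant raters are flagged as undefined.
#'
#' @param labels_a,labels_b equal-length binary label vectors
#' @param n_bootstrap paired bootstrap resamples (default 2000; 0 skips CI)
#' @param conf confidence level
#' @param seed optional bootstrap seed
#' @return list: `kappa`, `ci_low`, `ci_high`, `p_observed`, `p_expected`,
#'   `n_pairs`, `undefined` flag
#' @export
cohens_kappa <- function(labels_a, labels_b, n_bootstrap = 2000L,
                         conf = 0.95, seed = NULL) {
  stopifnot(length(labels_a) == length(labels_b))
  a <- as01(labels_a); b <- as01(labels_b)
  point <- kappa_stat(a, b)
  boot <- numeric(0)
  if (n_bootstrap > 0 && !isTRUE(attr(point, "undefined"))) {
    run <- function() {
      n <- length(a)
      vapply(seq_len(n_bootstrap), function(i) {
        ii <- sample.int(n, n, replace = TRUE)
        as.numeric(kappa_stat(a[ii], b[ii]))
      }, numeric(1))
    }
    boot <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    boot <- boot[is.finite(boot)]
  }
  alpha <- (1 - conf) / 2
  ci <- if (length(boot)) unname(stats::quantile(boot, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  list(kappa = as.numeric(point), ci_low = ci[1], ci_high = ci[2],
       p_observed = attr(point, "p_o"), p_expected = attr(point, "p_e"),
       n_pairs = length(a), undefined = isTRUE(attr(point, "undefined")))
}

kappa_stat <- function(a, b) {
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  if (p_e >= 1 - 1e-15) {
    # both raters constant: kappa 1 if they agree, undefined otherwise
    k <- if (p_o == 1) 1 else NaN
    return(structure(k, p_o = p_o, p_e = p_e, undefined = !is.finite(k)))
  }
  structure((p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, undefined = FALSE)
}

#' Intraclass correlation ICC(2,1) for two raters
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' mean-squares decomposition, with a percentile bootstrap CI over
#' subject-level resampling.
#'
#' @param probs_a,probs_b equal-length numeric vectors (one value per
#'   subject and rater), e.g. predicted probabilities in \[0, 1\]
#' @param n_bootstrap bootstrap resamples (default 2000; 0 skips CI)
#' @param conf confidence level
#' @param seed optional bootstrap seed
#' @return list: `icc`, `ci_low`, `ci_high`, `n_pairs`, `undefined` flag
#'   (set when the between-subject variance is zero)
#' @export
icc <- function(probs_a, probs_b, n_bootstrap = 2000L, conf = 0.95,
                seed = NULL) {
  stopifnot(length(probs_a) == length(probs_b))
  point <- icc21_stat(probs_a, probs_b)
  boot <- numeric(0)
  if (n_bootstrap > 0 && is.finite(point)) {
    run <- function() {
      n <- length(probs_a)
      vapply(seq_len(n_bootstrap), function(i) {
        ii <- sample.int(n, n, replace = TRUE)
        icc21_stat(probs_a[ii], probs_b[ii])
      }, numeric(1))
    }
    boot <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    boot <- boot[is.finite(boot)]
  }
  alpha <- (1 - conf) / 2
  ci <- if (length(boot)) unname(stats::quantile(boot, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  list(icc = point, ci_low = ci[1], ci_high = ci[2],
       n_pairs = length(probs_a), undefined = !is.finite(point))
}

icc21_stat <- function(a, b) {
  n <- length(a)
  k <- 2
  X <- cbind(a, b)
  row_means <- rowMeans(X)
  col_means <- colMeans(X)
  grand <- mean(X)
  MSR <- k * sum((row_means - grand)^2) / (n - 1)
  MSC <- n * sum((col_means - grand)^2) / (k - 1)
  SSE <- sum((X - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (MSR <= 1e-15 || denom <= 1e-15) return(NaN)
  (MSR - MSE) / denom
}

#' Inter-reader agreement of model predictions
#'
#' Fits the same logistic model independently on two reader-variant cohorts
#' of the same nodules and quantifies agreement of the resulting predicted
#' classes (kappa, at probability threshold 0.5) and predicted
#' probabilities (ICC).
#'
#' @param table_a,table_b feature tables of the two reader variants, same
#'   nodules in the same order
#' @param predictors predictor columns (default: the quantile-feature model,
#'   model 1)
#' @param n_bootstrap bootstrap resamples for both CIs
#' @param seed bootstrap seed
#' @return an `ssn_agreement`: `kappa`, `icc` (each with CI), `n_pairs`,
#'   `discordant` (nodule ids classified differently by the two readers)
#' @export
reader_agreement <- function(table_a, table_b,
                             predictors = model_specs()$model1,
                             n_bootstrap = 2000L, seed = 1L) {
  stopifnot(nrow(table_a) == nrow(table_b),
            all(table_a$nodule_id == table_b$nodule_id))
  fit_a <- suppressWarnings(fit_logistic(table_a, predictors))
  fit_b <- suppressWarnings(fit_logistic(table_b, predictors))
  p_a <- predict_proba(fit_a, table_a)
  p_b <- predict_proba(fit_b, table_b)
  cls_a <- as.integer(p_a > 0.5)
  cls_b <- as.integer(p_b > 0.5)
  kap <- cohens_kappa(cls_a, cls_b, n_bootstrap,
                      seed = derive_seed(seed, "kappa-boot"))
  ic <- icc(p_a, p_b, n_bootstrap, seed = derive_seed(seed, "icc-boot"))
  structure(list(kappa = kap, icc = ic, n_pairs = nrow(table_a),
                 discordant = table_a$nodule_id[cls_a != cls_b],
                 predictors = predictors),
            class = "ssn_agreement")
}

#' Write an agreement result as JSON
#' @param agreement an `ssn_agreement`
#' @param path output file
#' @export
write_agreement_json <- function(agreement, path) {
  jsonlite::write_json(unclass(agreement), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
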
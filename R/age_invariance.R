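#' Per-feature linear regression on age
#'
#' Ordinary least squares of each feature's value on chronological age
#' (with intercept), with the two-sided t-test p-value for the slope.
#' Computed in closed form across all features at once. A zero-variance
#' feature gets slope 0 and p = 1 (with a message), a stated convention
#' rather than NA.
#'
#' @param M a [population_matrix] (or plain features x subjects matrix).
#' @param ages numeric vector of ages (years), one per subject; must vary.
#' @return an object of class `age_regression_report`: data frame
#'   `table` with feature (0-based), slope (correlation units per year),
#'   p; plus `n_features` and `n_subjects`.
#' @export
per_feature_age_regression <- function(M, ages) {
  X <- if (inherits(M, "population_matrix")) M$values else as.matrix(M)
  n <- ncol(X)
  if (length(ages) != n) stopf("one age per subject required")
  if (n < 3) stopf("need >= 3 subjects")
  if (sd(ages) == 0) stopf("ages must vary")
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  ym <- rowMeans(X)
  slope <- as.numeric((X %*% xc) / sxx)
  # residual SS via total SS minus regression SS, feature-wise
  tss <- rowSums((X - ym)^2)
  rss <- pmax(tss - slope^2 * sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- ifelse(se > 0, slope / se, Inf * sign(slope))
  p <- 2 * pt(-abs(tval), df = n - 2)
  constant <- tss == 0
  if (any(constant)) {
    message(sprintf("%d constant feature(s): slope set to 0, p to 1",
                    sum(constant)))
    slope[constant] <- 0
    p[constant] <- 1
  }
  # saturated fit (rss == 0, non-constant): slope exact, p -> 0
  p[!constant & rss == 0] <- 0
  structure(
    list(table = data.frame(feature = seq_len(nrow(X)) - 1L,
                            slope = slope, p = p),
         n_features = nrow(X), n_subjects = n),
    class = "age_regression_report"
  )
}

#' @export
print.age_regression_report <- function(x, ...) {
  cat(sprintf("<age_regression_report> %d features, %d subjects; min p = %.3g\n",
              x$n_features, x$n_subjects, min(x$table$p)))
  invisible(x)
}

#' False-discovery-rate significance flags
#'
#' Benjamini-Hochberg step-up (default) or Benjamini-Yekutieli at level
#' `alpha`: a p-value is flagged iff its adjusted value is <= alpha. Flags
#' are monotone in p by construction of the step-up rule.
#'
#' @param p_values numeric vector in [0, 1].
#' @param alpha FDR level (default 0.001).
#' @param method "BH" (default) or "BY".
#' @return logical vector of significance flags.
#' @export
fdr_adjust <- function(p_values, alpha = 0.001, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = method) <= alpha
}

#' Summarize age association of a feature set after FDR correction
#'
#' Convenience wrapper: regression of the restricted features on age, BH
#' flags at `alpha`, and the non-significant fraction — the package's
#' age-invariance statistic for a candidate stable signature.
#'
#' @param M a [population_matrix].
#' @param ages ages in years.
#' @param features [feature_set] to restrict to (NULL = all features).
#' @param alpha FDR level (default 0.001).
#' @param method FDR procedure, see [fdr_adjust].
#' @return list: `report` (the regression report), `significant` (flags),
#'   `n_features`, `n_nonsignificant`, `frac_nonsignificant`.
#' @export
age_invariance_summary <- function(M, ages, features = NULL, alpha = 0.001,
                                   method = "BH") {
  vals <- if (is.null(features)) M else restrict_rows(M, features)
  rep_ <- per_feature_age_regression(vals, ages)
  flags <- fdr_adjust(rep_$table$p, alpha = alpha, method = method)
  list(report = rep_, significant = flags,
       n_features = length(flags),
       n_nonsignificant = sum(!flags),
       frac_nonsignificant = mean(!flags))
}

fit_linear_age_model <- function(X_train, y_train, ridge_lambda) {
  p <- ncol(X_train)
  xm <- colMeans(X_train); ym <- mean(y_train)
  Xc <- sweep(X_train, 2, xm)
  yc <- y_train - ym
  if (p >= nrow(X_train)) {
    # ridge fallback: OLS is singular once features reach the training size
    beta <- solve(crossprod(Xc) + ridge_lambda * diag(p), crossprod(Xc, yc))
  } else {
    fit <- .lm.fit(cbind(1, Xc), yc)
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
  }
  list(beta = as.numeric(beta), xm = xm, ym = ym)
}

predict_linear_age_model <- function(model, X) {
  as.numeric(sweep(X, 2, model$xm) %*% model$beta + model$ym)
}

#' Cross-validated age prediction error on a feature set
#'
#' Shuffles subjects into `folds` near-equal folds under `seed`; per fold,
#' fits a linear model of age on the restricted features over the training
#' folds and scores mean absolute error (MAE, years) on the held-out fold.
#' When the feature count reaches the training size, a small fixed ridge
#' penalty replaces OLS (which would be singular).
#'
#' @param M a [population_matrix].
#' @param ages ages in years, one per subject.
#' @param features a [feature_set] (or 0-based index vector), >= 1 feature.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param ridge_lambda ridge penalty used only in the fallback (default 1).
#' @return an object of class `cv_mae_report`: `fold_mae` (years),
#'   `mean`, `sd`, `folds`, `provenance`, `seed`.
#' @export
cv_age_prediction <- function(M, ages, features, folds = 10, seed = 1L,
                              ridge_lambda = 1) {
  X_all <- t(restrict_rows(M, features))   # subjects x features
  n <- nrow(X_all)
  if (length(ages) != n) stopf("one age per subject required")
  if (folds > n) stopf("more folds (%d) than subjects (%d)", folds, n)
  if (folds < 2) stopf("need >= 2 folds")
  assignment <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  fold_mae <- vapply(seq_len(folds), function(f) {
    train <- assignment != f
    if (sum(train) < 2) stopf("fold %d leaves fewer than 2 training subjects", f)
    model <- fit_linear_age_model(X_all[train, , drop = FALSE], ages[train],
                                  ridge_lambda)
    pred <- predict_linear_age_model(model, X_all[!train, , drop = FALSE])
    mean(abs(pred - ages[!train]))
  }, numeric(1))
  structure(
    list(fold_mae = fold_mae, mean = mean(fold_mae), sd = sd(fold_mae),
         folds = folds, provenance = feature_provenance(features),
         seed = seed),
    class = "cv_mae_report"
  )
}

#' @export
print.cv_mae_report <- function(x, ...) {
  cat(sprintf("<cv_mae_report> %d-fold MAE %.2f +/- %.2f years (%s features)\n",
              x$folds, x$mean, x$sd, x$provenance))
  invisible(x)
}

#' MAE distribution over random feature sets
#'
#' Draws `n_sets` independent uniform random feature sets of size k and
#' evaluates each by [cv_age_prediction]; the contrast of this
#' distribution with the stable-set MAE is the package's age-invariance
#' validation (stable features should predict age worse than random sets,
#' which pick up age-dependent edges).
#'
#' @param M a [population_matrix].
#' @param ages ages in years.
#' @param k random set size (typically the stable-set size).
#' @param n_sets number of random sets.
#' @param folds CV folds (default 10).
#' @param seed master seed; per-set seeds are derived from it.
#' @param ridge_lambda passed to [cv_age_prediction].
#' @return list: `set_mae` (per-set mean MAEs), `mean`, `sd`, `seeds`.
#' @export
random_set_mae_distribution <- function(M, ages, k, n_sets, folds = 10,
                                        seed = 1L, ridge_lambda = 1) {
  if (n_sets < 1) stopf("need n_sets >= 1")
  set_seeds <- with_seed(seed, sample.int(2147483646L, n_sets))
  set_mae <- vapply(seq_len(n_sets), function(i) {
    fs <- sample_random_features(M$m, k, set_seeds[i])
    cv_age_prediction(M, ages, fs, folds = folds, seed = set_seeds[i],
                      ridge_lambda = ridge_lambda)$mean
  }, numeric(1))
  list(set_mae = set_mae, mean = mean(set_mae), sd = sd(set_mae),
       seeds = set_seeds)
}
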
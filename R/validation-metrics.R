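#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; used both as R-squared
#' on the training set and as the external R-squared on a test set.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param yhat Predicted values.
#' @return A real number <= 1.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("observed values are constant", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' External validation coefficients Q2F1, Q2F2, Q2F3
#'
#' Three external-prediction determination coefficients that differ in the
#' reference mean and in size normalization:
#' \deqn{Q^2_{F1} = 1 - \sum_{te}(y-\hat y)^2 / \sum_{te}(y-\bar y_{tr})^2}
#' \deqn{Q^2_{F2} = 1 - \sum_{te}(y-\hat y)^2 / \sum_{te}(y-\bar y_{te})^2}
#' \deqn{Q^2_{F3} = 1 - [\sum_{te}(y-\hat y)^2/n_{te}] /
#'                      [\sum_{tr}(y-\bar y_{tr})^2/n_{tr}]}
#' F3 is invariant to duplicating test compounds; F1/F2 are not.
#'
#' @param y_test Observed test responses.
#' @param yhat_test Predicted test responses.
#' @param ybar_train Mean of the training responses (F1).
#' @param y_train Full training response vector (F3).
#' @return A real number <= 1.
#' @export
q2_f1 <- function(y_test, yhat_test, ybar_train) {
  stopifnot(length(y_test) == length(yhat_test))
  den <- sum((y_test - ybar_train)^2)
  if (den == 0) stop("zero reference variance for Q2F1", call. = FALSE)
  1 - sum((y_test - yhat_test)^2) / den
}

#' @rdname q2_f1
#' @export
q2_f2 <- function(y_test, yhat_test) {
  stopifnot(length(y_test) == length(yhat_test))
  den <- sum((y_test - mean(y_test))^2)
  if (den == 0) stop("test responses are constant (Q2F2 undefined)", call. = FALSE)
  1 - sum((y_test - yhat_test)^2) / den
}

#' @rdname q2_f1
#' @export
q2_f3 <- function(y_test, yhat_test, y_train) {
  stopifnot(length(y_test) == length(yhat_test))
  den <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (den == 0) stop("training responses are constant (Q2F3 undefined)",
                     call. = FALSE)
  1 - (sum((y_test - yhat_test)^2) / length(y_test)) / den
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between observed and predicted values, penalizing
#' both imprecision and location/scale shift:
#' \deqn{CCC = 2 \sum(y-\bar y)(\hat y-\bar{\hat y}) /
#'   [\sum(y-\bar y)^2 + \sum(\hat y-\bar{\hat y})^2 + n(\bar y-\bar{\hat y})^2]}
#' Equals 1 only for perfect concordance and satisfies |CCC| <= |r|.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A real number in \[-1, 1\].
#' @export
ccc <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  n <- length(y)
  my <- mean(y); mp <- mean(yhat)
  num <- 2 * sum((y - my) * (yhat - mp))
  den <- sum((y - my)^2) + sum((yhat - mp)^2) + n * (my - mp)^2
  if (sum((y - my)^2) == 0 && sum((yhat - mp)^2) == 0) {
    stop("both vectors constant (CCC undefined)", call. = FALSE)
  }
  num / den
}

#' Leave-10\%-out cross-validated Q2
#'
#' Repeated stratified 10-fold cross-validation on the training set: each
#' repetition deals the compounds into 10 folds within response tertiles,
#' refits the supplied recipe with each fold held out, and pools the
#' predicted residuals into `1 - PRESS / sum((y - mean(y))^2)`, averaged
#' over repetitions. Deterministic given `seed`.
#'
#' @param response Named numeric training response (length >= 10).
#' @param recipe Function `(train_ids, predict_ids) -> named predictions`
#'   that refits the modeling pipeline on `train_ids` and predicts the
#'   held-out compounds.
#' @param n_folds Folds per repetition; default 10 (leave-10\%-out).
#' @param n_repeats Repetitions; default 10.
#' @param n_bins Stratification bins; default 3.
#' @param seed Integer seed.
#' @return The cross-validated Q2 (a real number <= 1).
#' @export
q2_l10o <- function(response, recipe, n_folds = 10, n_repeats = 10,
                    n_bins = 3, seed = 1) {
  stopifnot(is.function(recipe))
  n <- length(response)
  if (n < n_folds) stop("need at least `n_folds` compounds", call. = FALSE)
  edges <- response_bin_edges(response, n_bins)
  bins <- bin_response(response, edges)
  ss_tot <- sum((response - mean(response))^2)
  if (ss_tot == 0) stop("training responses are constant", call. = FALSE)
  q2 <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- integer(n)
    with_seed(seed + r - 1L, {
      for (b in seq_len(n_bins)) {
        idx <- which(bins == b)
        if (length(idx) == 0L) next
        # deal shuffled members round-robin so fold sizes differ by <= 1
        fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
      }
    })
    press <- 0
    for (f in seq_len(n_folds)) {
      out <- names(response)[fold == f]
      if (length(out) == 0L) next
      pred <- recipe(setdiff(names(response), out), out)
      press <- press + sum((response[out] - pred[out])^2)
    }
    q2[r] <- 1 - press / ss_tot
  }
  mean(q2)
}

#' Assemble a validation report
#'
#' Bundles the internal and external statistics of one fitted model into a
#' single object: training/test determination coefficients, the external
#' Q2F1/Q2F2/Q2F3 and concordance, test MSE/RMSE, per-split RSVA metrics
#' and their percentile aggregate.
#'
#' @param y_train,yhat_train Observed and fitted training responses.
#' @param y_test,yhat_test Observed and predicted test responses (may be
#'   `NULL` when no external set exists).
#' @param q2_l10o Leave-10\%-out Q2 (or `NA`).
#' @param per_split Optional per-split metric data frame.
#' @param percentile Aggregation percentile; default 60.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(y_train, yhat_train, y_test = NULL,
                              yhat_test = NULL, q2_l10o = NA_real_,
                              per_split = NULL, percentile = 60) {
  rep <- list(
    r2_train = r_squared(y_train, yhat_train),
    q2_l10o = q2_l10o,
    mse_train = mean((y_train - yhat_train)^2)
  )
  if (!is.null(y_test)) {
    rep$r2_test <- r_squared(y_test, yhat_test)
    rep$q2_f1 <- q2_f1(y_test, yhat_test, mean(y_train))
    rep$q2_f2 <- q2_f2(y_test, yhat_test)
    rep$q2_f3 <- q2_f3(y_test, yhat_test, y_train)
    rep$ccc_test <- ccc(y_test, yhat_test)
    rep$mse <- mean((y_test - yhat_test)^2)
    rep$rmse <- sqrt(rep$mse)
  }
  rep$per_split <- per_split
  rep$aggregated <- if (!is.null(per_split)) {
    aggregate_metrics(per_split, percentile)
  } else NULL
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  nums <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1L, TRUE)]
  cat("<validation_report>\n")
  print(round(unlist(nums), 4))
  invisible(x)
}

#' Write a validation report to CSV (long format: metric, value)
#' @param report A [validation_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  nums <- report[vapply(report, function(v) is.numeric(v) && length(v) == 1L, TRUE)]
  write.csv(data.frame(metric = names(nums), value = unlist(nums),
                       row.names = NULL), path, row.names = FALSE)
  invisible(path)
}
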
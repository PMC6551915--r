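#' Leverage (hat-matrix diagonal) against a training design
#'
#' `h_i = x_i' (X'X)^{-1} x_i` where X is the training design (the model's
#' selected features plus an intercept column). Leverage measures distance
#' from the centroid of the modeled space; training leverages sum to the
#' number of design columns.
#'
#' @param train Numeric matrix of training feature values (no intercept
#'   column; one is added internally).
#' @param query Optional matrix of query rows in the same feature space;
#'   default the training matrix itself.
#' @param intercept Add an intercept column; default `TRUE`.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage <- function(train, query = NULL, intercept = TRUE) {
  train <- as.matrix(train)
  Xt <- if (intercept) cbind(`(Intercept)` = 1, train) else train
  qr_t <- qr(Xt)
  if (qr_t$rank < ncol(Xt)) {
    stop("training design is rank deficient (", qr_t$rank, " < ", ncol(Xt), ")",
         call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qr_t))
  Q <- if (is.null(query)) train else as.matrix(query)
  Xq <- if (intercept) cbind(1, Q) else Q
  rowSums((Xq %*% XtXinv) * Xq)
}

#' Warning leverage (critical hat value)
#'
#' `h* = 3 (k + 1) / n` for a model with `k` features fitted on `n`
#' training compounds; leverages above `h*` mark structurally influential
#' (high-leverage) compounds.
#'
#' @param n_features Number of model features `k`.
#' @param n_train Number of training compounds `n`.
#' @return The warning leverage.
#' @export
critical_hat <- function(n_features, n_train) {
  stopifnot(n_train > 0)
  3 * (n_features + 1) / n_train
}

#' Williams-plot classification
#'
#' Flags response outliers (|standardized residual| strictly above
#' `sigma_limit`) and structurally influential compounds (leverage strictly
#' above `h_star`). A compound exactly on either boundary is not flagged.
#'
#' @param std_residuals Residuals standardized by the training residual
#'   scale (see [compute_ad_report()]).
#' @param leverages Leverages from [leverage()].
#' @param h_star Warning leverage from [critical_hat()].
#' @param sigma_limit Residual limit; default 3.0.
#' @return Data frame with `leverage`, `std_residual`, `response_outlier`,
#'   `high_leverage`, and `in_domain` (neither flag set) — also the plot
#'   data for a Williams plot.
#' @export
williams <- function(std_residuals, leverages, h_star, sigma_limit = 3.0) {
  stopifnot(length(std_residuals) == length(leverages))
  data.frame(
    leverage = leverages,
    std_residual = std_residuals,
    response_outlier = abs(std_residuals) > sigma_limit,
    high_leverage = leverages > h_star,
    in_domain = abs(std_residuals) <= sigma_limit & leverages <= h_star
  )
}

#' Standardization applicability domain
#'
#' Each feature is z-scored by the training mean and standard deviation;
#' a compound is outside the domain when any feature exceeds `z_limit`
#' standard deviations in absolute value (strictly), following the
#' three-sigma rule for approximately normal features.
#'
#' @param train Training feature matrix.
#' @param query Query feature matrix (same columns).
#' @param z_limit Limit in SD units; default 3.0.
#' @return Data frame with `max_abs_z` and `in_domain` per query row.
#' @export
standardization_ad <- function(train, query, z_limit = 3.0) {
  train <- as.matrix(train); query <- as.matrix(query)
  mu <- colMeans(train)
  sdev <- apply(train, 2L, stats::sd)
  if (any(sdev == 0)) {
    stop("zero-SD training feature(s): ",
         paste(colnames(train)[sdev == 0], collapse = ", "), call. = FALSE)
  }
  z <- abs(sweep(sweep(query, 2L, mu, "-"), 2L, sdev, "/"))
  max_abs_z <- apply(z, 1L, max)
  data.frame(max_abs_z = max_abs_z, in_domain = max_abs_z <= z_limit)
}

#' Distance-to-centroid applicability domain
#'
#' The threshold is the largest distance between any training compound and
#' the training centroid; a query is outside when its distance to that
#' centroid strictly exceeds the threshold. Every training compound is
#' inside by construction.
#'
#' @param train Training feature matrix.
#' @param query Query feature matrix.
#' @param metric `"euclidean"` or `"cityblock"` (L1).
#' @return List with `threshold` and a data frame (`distance`,
#'   `in_domain`) per query row.
#' @export
distance_ad <- function(train, query, metric = c("euclidean", "cityblock")) {
  metric <- match.arg(metric)
  train <- as.matrix(train); query <- as.matrix(query)
  center <- colMeans(train)
  dist_to_center <- function(M) {
    D <- sweep(M, 2L, center, "-")
    if (metric == "euclidean") sqrt(rowSums(D^2)) else rowSums(abs(D))
  }
  threshold <- max(dist_to_center(train))
  d <- dist_to_center(query)
  list(threshold = threshold,
       table = data.frame(distance = d, in_domain = d <= threshold))
}

#' k-nearest-neighbour applicability domain
#'
#' Each training compound is scored by the mean Euclidean distance to its
#' `k` nearest training neighbours (self excluded); the threshold is the
#' largest of these scores. A query is outside when its mean distance to
#' its `k` nearest training compounds strictly exceeds the threshold.
#'
#' @param train Training feature matrix with more than `k` rows.
#' @param query Query feature matrix.
#' @param k Number of neighbours; default 3.
#' @return List with `threshold` and a data frame (`knn_distance`,
#'   `in_domain`) per query row.
#' @export
knn_ad <- function(train, query, k = 3) {
  train <- as.matrix(train); query <- as.matrix(query)
  n <- nrow(train)
  if (n <= k) stop("need more than k = ", k, " training compounds", call. = FALSE)
  cross_dist <- function(A, B) {
    # Euclidean distances between rows of A and rows of B
    aa <- rowSums(A^2); bb <- rowSums(B^2)
    d2 <- outer(aa, bb, "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  }
  dtr <- cross_dist(train, train)
  train_score <- vapply(seq_len(n), function(i) {
    mean(sort(dtr[i, -i], partial = k)[seq_len(k)])
  }, numeric(1))
  threshold <- max(train_score)
  dq <- cross_dist(query, train)
  score <- apply(dq, 1L, function(d) mean(sort(d, partial = k)[seq_len(k)]))
  list(threshold = threshold,
       table = data.frame(knn_distance = score, in_domain = score <= threshold))
}

#' Consensus applicability-domain verdict
#'
#' Averages the binary in-domain indicators of the supplied methods per
#' compound; a compound is in the consensus domain when its score is at
#' least 0.5. By convention the training-set consensus uses the leverage
#' and standardization methods, while the test-set consensus uses all five
#' approaches (leverage, standardization, Euclidean, city-block, kNN).
#'
#' @param method_flags Logical matrix or data frame, one column per method,
#'   one row per compound.
#' @return List with `score` (mean indicator per compound), `in_domain`
#'   (score >= 0.5), and `coverage` (percentage of compounds in domain).
#' @export
consensus_ad <- function(method_flags) {
  m <- as.matrix(as.data.frame(method_flags))
  if (ncol(m) == 0L || nrow(m) == 0L) stop("no method flags given", call. = FALSE)
  if (anyNA(m)) stop("missing method flag(s)", call. = FALSE)
  score <- rowMeans(m)
  in_domain <- score >= 0.5
  list(score = score, in_domain = in_domain, coverage = 100 * mean(in_domain))
}

#' Insubria-graph classification
#'
#' For compounds without experimental response values, classifies each
#' prediction as interpolated (leverage <= h*) or extrapolated (leverage
#' strictly above h*), and separately flags predictions falling outside the
#' model's response range (the range of its training predictions).
#'
#' @param leverages Leverages against the model's training design.
#' @param predictions Model predictions for the same compounds.
#' @param h_star Warning leverage.
#' @param prediction_range Length-2 numeric `c(min, max)` of training
#'   predictions, or `NULL` to skip response-range flagging.
#' @return Data frame with `leverage`, `prediction`, `extrapolated`, and
#'   `out_of_range` (`NA` when no range is available) — the Insubria plot
#'   data.
#' @export
insubria <- function(leverages, predictions, h_star, prediction_range = NULL) {
  stopifnot(length(leverages) == length(predictions))
  out_of_range <- if (is.null(prediction_range)) {
    rep(NA, length(predictions))
  } else {
    predictions < prediction_range[1L] | predictions > prediction_range[2L]
  }
  data.frame(leverage = leverages, prediction = predictions,
             extrapolated = leverages > h_star, out_of_range = out_of_range)
}

#' Full applicability-domain report for a fitted model
#'
#' Evaluates all five AD methods in the model's own feature space (the
#' selected features after power transformation), plus the consensus
#' verdict and coverages. Training consensus averages the leverage and
#' standardization indicators; test consensus averages all five methods.
#'
#' @param model A `qsmart_model` with at least one coefficient.
#' @param dataset A [fuse()]d dataset containing training and test rows.
#' @param train_ids,test_ids Compound IDs of the two roles.
#' @param z_limit Residual and standardization limit in sigma units;
#'   default 3.
#' @param k Neighbours for the kNN method; default 3.
#' @return An object of class `ad_report`: `per_compound` table,
#'   `thresholds`, and `coverage` (`AD_Train`, `AD_Test` percentages).
#' @export
compute_ad_report <- function(model, dataset, train_ids, test_ids,
                              z_limit = 3.0, k = 3) {
  stopifnot(inherits(model, "qsmart_model"), inherits(dataset, "fused_dataset"))
  feats <- names(model$coefficients)
  if (length(feats) == 0L) stop("model has no features (empty model)", call. = FALSE)
  X <- design_matrix(dataset)
  missing <- setdiff(feats, colnames(X))
  if (length(missing)) stop("dataset lacks model feature(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  Z <- sweep(abs(X[, feats, drop = FALSE]), 2L, model_exponents(model), "^")
  Zt <- Z[train_ids, , drop = FALSE]
  Zq <- Z[test_ids, , drop = FALSE]
  y <- dataset$response
  pred <- predict(model, dataset)

  h_star <- critical_hat(length(feats), length(train_ids))
  h_tr <- leverage(Zt)
  h_te <- leverage(Zt, Zq)
  res_tr <- y[train_ids] - pred[train_ids]
  res_te <- y[test_ids] - pred[test_ids]
  s <- sqrt(mean(res_tr^2))
  if (s == 0) s <- 1  # perfect training fit: residual scale degenerate
  w_tr <- williams(res_tr / s, h_tr, h_star, z_limit)
  w_te <- williams(res_te / s, h_te, h_star, z_limit)

  std_tr <- standardization_ad(Zt, Zt, z_limit)
  std_te <- standardization_ad(Zt, Zq, z_limit)
  eu_tr <- distance_ad(Zt, Zt, "euclidean"); eu_te <- distance_ad(Zt, Zq, "euclidean")
  cb_tr <- distance_ad(Zt, Zt, "cityblock"); cb_te <- distance_ad(Zt, Zq, "cityblock")
  kn_tr <- knn_ad(Zt, Zt, k); kn_te <- knn_ad(Zt, Zq, k)

  cons_tr <- consensus_ad(cbind(leverage = w_tr$in_domain,
                                standardization = std_tr$in_domain))
  cons_te <- consensus_ad(cbind(leverage = w_te$in_domain,
                                standardization = std_te$in_domain,
                                euclidean = eu_te$table$in_domain,
                                cityblock = cb_te$table$in_domain,
                                knn = kn_te$table$in_domain))

  per_compound <- rbind(
    data.frame(compound_id = train_ids, role = "train",
               h = h_tr, std_residual = res_tr / s, max_abs_z = std_tr$max_abs_z,
               dist_euclid = eu_tr$table$distance, dist_city = cb_tr$table$distance,
               dist_knn = kn_tr$table$knn_distance,
               in_leverage = w_tr$in_domain, in_std = std_tr$in_domain,
               in_euclid = eu_tr$table$in_domain, in_city = cb_tr$table$in_domain,
               in_knn = kn_tr$table$in_domain,
               consensus_score = cons_tr$score, in_consensus = cons_tr$in_domain,
               stringsAsFactors = FALSE),
    data.frame(compound_id = test_ids, role = "test",
               h = h_te, std_residual = res_te / s, max_abs_z = std_te$max_abs_z,
               dist_euclid = eu_te$table$distance, dist_city = cb_te$table$distance,
               dist_knn = kn_te$table$knn_distance,
               in_leverage = w_te$in_domain, in_std = std_te$in_domain,
               in_euclid = eu_te$table$in_domain, in_city = cb_te$table$in_domain,
               in_knn = kn_te$table$in_domain,
               consensus_score = cons_te$score, in_consensus = cons_te$in_domain,
               stringsAsFactors = FALSE)
  )
  rownames(per_compound) <- NULL
  structure(list(
    per_compound = per_compound,
    thresholds = list(h_star = h_star, z_limit = z_limit,
                      dist_euclid = eu_tr$threshold, dist_city = cb_tr$threshold,
                      dist_knn = kn_tr$threshold),
    coverage = list(AD_Train = cons_tr$coverage, AD_Test = cons_te$coverage),
    prediction_range = range(pred[train_ids])
  ), class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> h* = %.4f; AD_Train = %.1f%%, AD_Test = %.1f%%\n",
              x$thresholds$h_star, x$coverage$AD_Train, x$coverage$AD_Test))
  invisible(x)
}

#' Write an AD report's per-compound table to CSV
#' @param report An [compute_ad_report()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ad_report <- function(report, path) {
  write.csv(report$per_compound, path, row.names = FALSE)
  invisible(path)
}
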
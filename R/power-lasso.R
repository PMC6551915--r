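#' Power-transformation parameters
#'
#' The block-wise exponent pair applied entry-wise to the absolute values of
#' the design matrix: `alpha` for the molecular-descriptor block, `gamma`
#' shared by all gene (log fold-change) blocks. Both must be strictly
#' positive; `|0|^e = 0` for any positive exponent, so zeros are preserved.
#'
#' @param alpha Exponent for MD columns (> 0).
#' @param gamma Exponent for gene columns (> 0).
#' @return An object of class `power_params`.
#' @export
power_params <- function(alpha = 1, gamma = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 ||
      !is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`alpha` and `gamma` must be single strictly positive numbers",
         call. = FALSE)
  }
  structure(list(alpha = alpha, gamma = gamma), class = "power_params")
}

#' Build the power-transformed design matrix X(alpha, gamma)
#'
#' Applies `|x|^alpha` to every MD column and `|x|^gamma` to every gene
#' column of a fused dataset.
#'
#' @param dataset A [fuse()]d dataset.
#' @param params A [power_params()] pair.
#' @return Numeric matrix, compounds x features, same dimnames as
#'   [design_matrix()].
#' @export
power_transform <- function(dataset, params) {
  stopifnot(inherits(dataset, "fused_dataset"), inherits(params, "power_params"))
  X <- abs(design_matrix(dataset))
  kinds <- column_kinds(dataset)
  md <- kinds == "MD"
  if (any(md)) X[, md] <- X[, md, drop = FALSE]^params$alpha
  if (any(!md)) X[, !md] <- X[, !md, drop = FALSE]^params$gamma
  X
}

# Column standardization used inside the solver: mean 0, sum of squares n
# (population scaling). Degenerate (zero-variance) columns are flagged and
# pinned at coefficient zero rather than dropped, so column indexing is
# stable.
standardize_columns <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  scale <- sqrt(colSums(Xc^2) / n)
  ok <- scale > 1e-12
  Xs <- Xc
  Xs[, ok] <- sweep(Xc[, ok, drop = FALSE], 2L, scale[ok], "/")
  Xs[, !ok] <- 0
  list(X = Xs, center = center, scale = scale, ok = ok, n = n)
}

#' Penalty path for the lasso
#'
#' Computes a decreasing sequence of `n_lambdas` penalty values, log-spaced
#' from `lambda_max` down to `lambda_max * 1e-3`, where
#' `lambda_max = max_j |x_j' (y - mean(y))| / n` over the standardized
#' columns of `X`. At `lambda_max` the penalized fit is exactly the
#' all-zero coefficient vector (the KKT entry condition), so the path spans
#' the full range from the null model to a nearly unpenalized fit.
#'
#' @param X Transformed design matrix (rows aligned with `y`).
#' @param y Response vector.
#' @param n_lambdas Path length; default 100.
#' @return Decreasing numeric vector of length `n_lambdas`.
#' @export
lambda_path <- function(X, y, n_lambdas = 100) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  st <- standardize_columns(X)
  yc <- y - mean(y)
  lam_max <- max(abs(crossprod(st$X, yc)) / st$n)
  if (!is.finite(lam_max) || lam_max <= 0) {
    stop("degenerate design: no column correlates with the response",
         call. = FALSE)
  }
  # guard the exact KKT boundary against summation-order rounding so the
  # first path point yields the all-zero fit
  lam_max <- lam_max * (1 + 1e-10)
  exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = n_lambdas))
}

# Low-level path solver on a fixed design. Returns raw-scale coefficients
# (p x nlambda) and intercepts; `lambdas` must be non-increasing for warm
# starts to make sense. With on_fail = "flag", non-converged path points
# are reported in `converged` instead of raising.
lasso_path_fit <- function(X, y, lambdas, tol = 1e-7, max_sweeps = 1e5,
                           on_fail = c("error", "flag"),
                           df_max = ncol(X) + 1L) {
  on_fail <- match.arg(on_fail)
  st <- standardize_columns(X)
  yc <- y - mean(y)
  res <- .cd_lasso_path(st$X, yc, as.numeric(lambdas), as.integer(st$ok),
                        tol, as.integer(max_sweeps), as.integer(df_max))
  if (!all(res$converged) && on_fail == "error") {
    bad <- which(!res$converged)
    stop(sprintf(paste0("lasso solver failed to converge for %d lambda value(s) ",
                        "(first: lambda = %.6g after %d sweeps, tol = %g)"),
                 length(bad), lambdas[bad[1L]], res$sweeps[bad[1L]], tol),
         call. = FALSE)
  }
  beta_raw <- res$beta
  beta_raw[st$ok, ] <- beta_raw[st$ok, , drop = FALSE] / st$scale[st$ok]
  intercepts <- mean(y) - as.numeric(crossprod(beta_raw, st$center))
  rownames(beta_raw) <- colnames(X)
  list(beta = beta_raw, intercept = intercepts, sweeps = res$sweeps,
       converged = res$converged)
}

#' Fit the lasso-type estimator at a fixed penalty
#'
#' Minimizes `(1/(2n)) * ||y - b0 - X beta||^2 + lambda * ||beta||_1` by
#' cyclic coordinate descent with an unpenalized intercept. Columns are
#' mean-centered and unit-scaled inside the solver; coefficients are
#' reported back on the scale of `X` (the transformed but unstandardized
#' design). The per-observation `1/(2n)` factor makes `lambda` comparable
#' across sample sizes and consistent with [lambda_path()]: the estimator is
#' the same L1-penalized least-squares minimizer, with the penalty weight
#' expressed per observation.
#'
#' @param X Transformed design matrix with column names.
#' @param y Response vector, length `nrow(X)`.
#' @param lambda Penalty weight, >= 0.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (standardized scale); default 1e-7.
#' @param max_sweeps Sweep budget before a non-convergence error; default 1e5.
#' @return An object of class `lasso_fit`: `intercept`, `beta` (full
#'   named vector), `coefficients` (nonzero entries only), `lambda`,
#'   `fitted`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-7, max_sweeps = 1e5) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  fit <- lasso_path_fit(X, y, lambda, tol = tol, max_sweeps = max_sweeps)
  beta <- fit$beta[, 1L]
  structure(list(intercept = fit$intercept[1L], beta = beta,
                 coefficients = beta[beta != 0], lambda = lambda,
                 fitted = as.numeric(X %*% beta) + fit$intercept[1L]),
            class = "lasso_fit")
}

#' Select the penalty by mean validation error over repeated splits
#'
#' For each split plan, the full path is fitted on the split's training rows
#' and evaluated as mean squared error on its holdout rows; the penalty
#' minimizing the across-split mean MSE wins. Ties go to the larger penalty
#' (the more parsimonious model).
#'
#' @param X Transformed design matrix whose row names are compound IDs.
#' @param y Named response aligned with `X`.
#' @param path Decreasing penalty sequence from [lambda_path()].
#' @param splits List of [stratified_split()] plans over the rows of `X`.
#' @return List with `lambda` (the selected value), `index` (its position
#'   in `path`), and `mse` (the per-penalty mean validation MSE).
#' @details A penalty is only considered selectable when the solver
#'   converges for it on every split; penalties that stall on some split
#'   carry infinite MSE and cannot win. Screening fits use a reduced sweep
#'   budget (`max_sweeps`) and stop the path early once a fit saturates
#'   (more nonzero coefficients than training rows, i.e. an interpolating
#'   fit): such penalties sit deep in the overfitting tail, where slow
#'   coordinate-descent oscillation between almost-collinear transformed
#'   columns is common and the validation MSE can only deteriorate. An
#'   error is raised only when no penalty is computable on all splits.
#' @param max_sweeps Sweep budget per penalty for the screening fits;
#'   default 2000.
#' @export
select_lambda <- function(X, y, path, splits, max_sweeps = 2000) {
  stopifnot(is.matrix(X), length(splits) >= 1L)
  ids <- rownames(X)
  if (is.null(ids)) stop("X must carry compound IDs as rownames", call. = FALSE)
  mse <- matrix(NA_real_, length(splits), length(path))
  usable <- rep(TRUE, length(path))
  for (s in seq_along(splits)) {
    plan <- splits[[s]]
    tr <- match(plan$train_ids, ids)
    ho <- match(plan$holdout_ids, ids)
    if (anyNA(tr) || anyNA(ho)) stop("split plan IDs not found in X", call. = FALSE)
    fit <- lasso_path_fit(X[tr, , drop = FALSE], y[tr], path,
                          max_sweeps = max_sweeps, on_fail = "flag",
                          df_max = length(tr) - 1L)
    pred <- X[ho, , drop = FALSE] %*% fit$beta +
      matrix(fit$intercept, length(ho), length(path), byrow = TRUE)
    mse[s, ] <- colMeans((pred - y[ho])^2)
    usable <- usable & fit$converged
  }
  if (!any(usable)) {
    stop("lasso solver failed to converge at every penalty on some split",
         call. = FALSE)
  }
  mean_mse <- colMeans(mse)
  mean_mse[!usable] <- Inf
  idx <- which.min(mean_mse)  # path is decreasing: first minimum = largest lambda
  list(lambda = path[idx], index = idx, mse = mean_mse)
}

#' Fit a QSMARt model on a fused dataset
#'
#' Transforms the dataset with [power_transform()], fits the lasso at the
#' given penalty, and packages the nonzero coefficients together with their
#' block kinds and transformation exponents so the model is self-contained
#' for prediction on raw (untransformed, signed) feature values.
#'
#' @param dataset A [fuse()]d dataset.
#' @param params A [power_params()] pair.
#' @param lambda Penalty weight.
#' @param ids Optional subset of compound IDs to train on (default: all).
#' @param name Optional model name.
#' @return An object of class `qsmart_model`.
#' @export
fit_qsmart <- function(dataset, params, lambda, ids = NULL, name = NULL) {
  stopifnot(inherits(dataset, "fused_dataset"))
  if (!is.null(ids)) dataset <- subset_compounds(dataset, ids)
  X <- power_transform(dataset, params)
  y <- dataset$response
  fit <- fit_lasso(X, y, lambda)
  kinds <- stats::setNames(column_kinds(dataset), dataset$feature_index$feature)
  qsmart_model(intercept = fit$intercept, coefficients = fit$coefficients,
               alpha = params$alpha, gamma = params$gamma,
               feature_kinds = kinds[names(fit$coefficients)],
               lambda = lambda, training_ids = compound_ids(dataset),
               fitted = stats::setNames(fit$fitted, compound_ids(dataset)),
               name = name)
}

#' Construct a sparse linear QSMARt model
#'
#' The portable model object: an intercept plus named nonzero coefficients
#' on power-transformed features, with the exponent pair recorded per block
#' kind. Prediction applies `intercept + sum_j beta_j * |x_j|^e_j` where
#' `e_j` is `alpha` for MD features and `gamma` for gene features.
#'
#' @param intercept Model intercept.
#' @param coefficients Named numeric vector of nonzero coefficients.
#' @param alpha,gamma Transformation exponents (> 0).
#' @param feature_kinds Named character vector (`"MD"`/`"GENE"`) aligned
#'   with `coefficients`.
#' @param lambda Penalty at which the model was fitted (NA if external).
#' @param training_ids Compound IDs of the training set (may be empty).
#' @param fitted Optional named fitted values on the training set.
#' @param name Optional model name.
#' @return An object of class `qsmart_model`.
#' @export
qsmart_model <- function(intercept, coefficients, alpha, gamma, feature_kinds,
                         lambda = NA_real_, training_ids = character(),
                         fitted = NULL, name = NULL) {
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("`coefficients` must be named", call. = FALSE)
  }
  feature_kinds <- feature_kinds[names(coefficients)]
  if (length(coefficients) && (anyNA(feature_kinds) ||
                               !all(feature_kinds %in% c("MD", "GENE")))) {
    stop("`feature_kinds` must map every coefficient to 'MD' or 'GENE'",
         call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 alpha = alpha, gamma = gamma,
                 feature_kinds = feature_kinds, lambda = lambda,
                 training_ids = training_ids, fitted = fitted, name = name),
            class = "qsmart_model")
}

#' @export
print.qsmart_model <- function(x, ...) {
  cat(sprintf("<qsmart_model>%s %d term(s), alpha = %g, gamma = %g, lambda = %s\n",
              if (!is.null(x$name)) paste0(" ", x$name, ":") else "",
              length(x$coefficients), x$alpha, x$gamma,
              if (is.na(x$lambda)) "NA" else format(x$lambda)))
  if (length(x$coefficients)) {
    print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  } else {
    cat(sprintf("  intercept-only model: %g\n", x$intercept))
  }
  invisible(x)
}

# exponent applied to each named model feature
model_exponents <- function(model) {
  ifelse(model$feature_kinds == "MD", model$alpha, model$gamma)
}

#' Predict from a QSMARt model
#'
#' @param object A `qsmart_model`.
#' @param newdata A [fuse()]d dataset, or a matrix/data.frame of raw
#'   (signed, untransformed) feature values with named columns covering
#'   every feature of the model. Gene features are absolute log
#'   fold-changes after the model's internal `|x|` transform, so signed
#'   logFC input is handled correctly.
#' @param ... Unused.
#' @return Numeric vector of predictions, named by row when row names exist.
#' @export
predict.qsmart_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fused_dataset")) newdata <- design_matrix(newdata)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  stopifnot(is.matrix(newdata))
  need <- names(object$coefficients)
  if (length(need) == 0L) {
    return(stats::setNames(rep(object$intercept, nrow(newdata)), rownames(newdata)))
  }
  missing <- setdiff(need, colnames(newdata))
  if (length(missing)) {
    stop("missing model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- abs(newdata[, need, drop = FALSE])
  Z <- sweep(Z, 2L, model_exponents(object), "^")
  stats::setNames(as.numeric(Z %*% object$coefficients) + object$intercept,
                  rownames(newdata))
}

#' Serialize a QSMARt model to JSON
#'
#' Numbers are written at full precision so that a write/read round trip is
#' bit-identical.
#'
#' @param model A `qsmart_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qsmart_model <- function(model, path) {
  stopifnot(inherits(model, "qsmart_model"))
  obj <- list(
    name = model$name,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    alpha = model$alpha, gamma = model$gamma,
    feature_kinds = as.list(model$feature_kinds),
    lambda = model$lambda,
    training_ids = as.list(model$training_ids),
    package_version = as.character(utils::packageVersion("qsmartr"))
  )
  # 17 significant digits: enough for an exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a QSMARt model from JSON
#' @param path Path to a file written by [write_qsmart_model()].
#' @return A `qsmart_model`.
#' @export
read_qsmart_model <- function(path) {
  obj <- jsonlite::read_json(path)
  qsmart_model(
    intercept = as.numeric(obj$intercept),
    coefficients = unlist(lapply(obj$coefficients, as.numeric)),
    alpha = as.numeric(obj$alpha), gamma = as.numeric(obj$gamma),
    feature_kinds = unlist(lapply(obj$feature_kinds, as.character)),
    lambda = if (is.null(obj$lambda)) NA_real_ else as.numeric(obj$lambda),
    training_ids = as.character(unlist(obj$training_ids)),
    name = if (is.null(obj$name)) NULL else as.character(obj$name)
  )
}
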
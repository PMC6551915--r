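#' Default exponent grid
#'
#' Nine values per exponent, giving the 81-cell (alpha, gamma) grid of the
#' standard workflow.
#' @return Numeric vector of nine exponents.
#' @export
default_grid <- function() c(0.1, 0.25, 0.50, 0.75, 1, 1.25, 1.50, 1.75, 2)

#' Eligibility criteria for candidate models
#'
#' Thresholds applied to a candidate's validation and applicability-domain
#' report. All listed internal/external statistics must reach their
#' threshold and the consensus test-set coverage must equal `ad_test`. The
#' concordance threshold is reported but non-blocking by default (strict
#' mode makes it blocking), reflecting that a model can be acceptable on
#' all determination coefficients while falling short on concordance.
#'
#' @param r2_train,r2_test,q2_l10o,q2_f1,q2_f2,q2_f3 Metric thresholds;
#'   default 0.6 each.
#' @param ccc Concordance threshold; default 0.85.
#' @param ccc_blocking Should the concordance threshold block eligibility?
#'   Default `FALSE`.
#' @param ad_test Required consensus test coverage in percent; default 100.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(r2_train = 0.6, r2_test = 0.6, q2_l10o = 0.6,
                                 q2_f1 = 0.6, q2_f2 = 0.6, q2_f3 = 0.6,
                                 ccc = 0.85, ccc_blocking = FALSE,
                                 ad_test = 100) {
  structure(list(r2_train = r2_train, r2_test = r2_test, q2_l10o = q2_l10o,
                 q2_f1 = q2_f1, q2_f2 = q2_f2, q2_f3 = q2_f3,
                 ccc = ccc, ccc_blocking = ccc_blocking, ad_test = ad_test),
            class = "eligibility_criteria")
}

# metric value or NA from a candidate's validation report
cand_metric <- function(cand, name) {
  v <- cand$validation[[name]]
  if (is.null(v)) NA_real_ else v
}

#' Grid search over the transformation exponents
#'
#' Runs the full modeling procedure for every (alpha, gamma) pair: build
#' the transformed design on the outer training set, compute the penalty
#' path, select the penalty by RSVA (mean validation MSE over repeated
#' stratified 90/10 splits), refit on the whole training set, and validate
#' on the held-back test set. A cell whose selected fit has no nonzero
#' coefficients is retained as an empty, ineligible candidate.
#'
#' @param dataset A [fuse()]d dataset.
#' @param alpha_grid,gamma_grid Exponent grids; default [default_grid()]
#'   each (81 cells). Grid index runs alpha-major: cell `t` corresponds to
#'   `alpha_grid[ceiling(t / length(gamma_grid))]` and
#'   `gamma_grid[(t - 1) %% length(gamma_grid) + 1]`.
#' @param outer_split Optional [stratified_split()] plan defining the outer
#'   train/test partition; by default an 80/20 stratified split seeded with
#'   `seed`.
#' @param n_splits Inner RSVA repetitions; default 100.
#' @param train_frac Inner training fraction; default 0.9.
#' @param n_bins Stratification bins; default 3.
#' @param n_lambdas Penalty-path length; default 100.
#' @param percentile RSVA aggregation percentile; default 60.
#' @param select_sweeps Sweep budget per penalty for the screening fits of
#'   [select_lambda()]; default 300.
#' @param validation `"full"` evaluates per-split aggregates, the
#'   leave-10\%-out Q2 and the applicability domain for every non-empty
#'   cell; `"basic"` computes training/test statistics only (used for large
#'   screening runs).
#' @param seed Integer seed; drives the outer split (`seed`) and the inner
#'   split ensemble (`seed + 1`, `+2`, ...).
#' @return An object of class `qsmart_grid`: list of candidates plus the
#'   outer split and settings.
#' @export
grid_search <- function(dataset, alpha_grid = default_grid(),
                        gamma_grid = default_grid(), outer_split = NULL,
                        n_splits = 100, train_frac = 0.9, n_bins = 3,
                        n_lambdas = 100, percentile = 60, select_sweeps = 300,
                        validation = c("full", "basic"), seed = 1) {
  stopifnot(inherits(dataset, "fused_dataset"),
            length(alpha_grid) >= 1L, length(gamma_grid) >= 1L)
  validation <- match.arg(validation)
  if (is.null(outer_split)) {
    outer_split <- stratified_split(dataset$response, train_frac = 0.8,
                                    n_bins = n_bins, seed = seed)
  }
  train_ids <- outer_split$train_ids
  test_ids <- outer_split$holdout_ids
  y <- dataset$response
  splits <- make_rsva_splits(y[train_ids], n_splits = n_splits,
                             train_frac = train_frac, n_bins = n_bins,
                             base_seed = seed + 1L)
  kinds <- stats::setNames(column_kinds(dataset), dataset$feature_index$feature)

  cells <- expand.grid(gamma = gamma_grid, alpha = alpha_grid,
                       KEEP.OUT.ATTRS = FALSE)[, c("alpha", "gamma")]
  candidates <- vector("list", nrow(cells))
  for (t in seq_len(nrow(cells))) {
    params <- power_params(cells$alpha[t], cells$gamma[t])
    candidates[[t]] <- evaluate_cell(dataset, params, train_ids, test_ids,
                                     splits, n_lambdas, percentile,
                                     validation, kinds, grid_index = t,
                                     seed = seed, select_sweeps = select_sweeps)
  }
  structure(list(candidates = candidates, outer_split = outer_split,
                 alpha_grid = alpha_grid, gamma_grid = gamma_grid,
                 settings = list(n_splits = n_splits, train_frac = train_frac,
                                 n_bins = n_bins, n_lambdas = n_lambdas,
                                 percentile = percentile,
                                 validation = validation, seed = seed)),
            class = "qsmart_grid")
}

# One grid cell: path, penalty selection, refit, validation, AD.
evaluate_cell <- function(dataset, params, train_ids, test_ids, splits,
                          n_lambdas, percentile, validation, kinds,
                          grid_index, seed, select_sweeps = 300) {
  y <- dataset$response
  X <- power_transform(dataset, params)
  Xtr <- X[train_ids, , drop = FALSE]

  empty_candidate <- function(lambda = NA_real_) {
    list(grid_index = grid_index, alpha = params$alpha, gamma = params$gamma,
         lambda = lambda,
         model = qsmart_model(intercept = mean(y[train_ids]),
                              coefficients = stats::setNames(numeric(0), character(0)),
                              alpha = params$alpha, gamma = params$gamma,
                              feature_kinds = character(0), lambda = lambda,
                              training_ids = train_ids),
         validation = NULL, ad = NULL, eligible = FALSE, n_features = 0L)
  }

  path <- tryCatch(lambda_path(Xtr, y[train_ids], n_lambdas),
                   error = function(e) NULL)
  if (is.null(path)) return(empty_candidate())
  sel <- tryCatch(select_lambda(Xtr, y[train_ids], path, splits,
                                max_sweeps = select_sweeps),
                  error = function(e) NULL)
  if (is.null(sel)) return(empty_candidate())
  fit <- fit_lasso(Xtr, y[train_ids], sel$lambda)
  if (length(fit$coefficients) == 0L) return(empty_candidate(sel$lambda))

  model <- qsmart_model(intercept = fit$intercept,
                        coefficients = fit$coefficients,
                        alpha = params$alpha, gamma = params$gamma,
                        feature_kinds = kinds[names(fit$coefficients)],
                        lambda = sel$lambda, training_ids = train_ids,
                        fitted = stats::setNames(fit$fitted, train_ids))
  pred_te <- as.numeric(X[test_ids, , drop = FALSE] %*% fit$beta) + fit$intercept

  per_split <- NULL
  l10o <- NA_real_
  ad <- NULL
  if (validation == "full") {
    per_split <- as.data.frame(t(vapply(splits, function(plan) {
      f <- lasso_path_fit(X[plan$train_ids, , drop = FALSE],
                          y[plan$train_ids], sel$lambda)
      p <- as.numeric(X[plan$holdout_ids, , drop = FALSE] %*% f$beta[, 1L]) +
        f$intercept[1L]
      yo <- y[plan$holdout_ids]
      c(q2 = tryCatch(q2_f2(yo, p), error = function(e) NA_real_),
        q2_f1 = q2_f1(yo, p, mean(y[plan$train_ids])),
        q2_f3 = q2_f3(yo, p, y[plan$train_ids]),
        ccc = tryCatch(ccc(yo, p), error = function(e) NA_real_),
        mse = mean((yo - p)^2))
    }, numeric(5))))
    recipe <- function(tr, out) {
      f <- lasso_path_fit(X[tr, , drop = FALSE], y[tr], sel$lambda)
      stats::setNames(as.numeric(X[out, , drop = FALSE] %*% f$beta[, 1L]) +
                        f$intercept[1L], out)
    }
    l10o <- q2_l10o(y[train_ids], recipe, seed = seed + 2L)
    ad <- tryCatch(compute_ad_report(model, dataset, train_ids, test_ids),
                   error = function(e) NULL)
  }

  val <- validation_report(y_train = y[train_ids], yhat_train = fit$fitted,
                           y_test = y[test_ids], yhat_test = pred_te,
                           q2_l10o = l10o, per_split = per_split,
                           percentile = percentile)
  list(grid_index = grid_index, alpha = params$alpha, gamma = params$gamma,
       lambda = sel$lambda, model = model, validation = val, ad = ad,
       eligible = NA, n_features = length(model$coefficients))
}

#' @export
print.qsmart_grid <- function(x, ...) {
  cat(sprintf("<qsmart_grid> %d candidate(s) (%d x %d grid), %d train / %d test\n",
              length(x$candidates), length(x$alpha_grid), length(x$gamma_grid),
              length(x$outer_split$train_ids), length(x$outer_split$holdout_ids)))
  invisible(x)
}

#' Flatten grid-search candidates into a table
#'
#' @param grid A [grid_search()] result (or a bare list of candidates).
#' @return Data frame with one row per grid cell: exponents, penalty,
#'   feature count, validation statistics, AD coverages and eligibility.
#' @export
candidates_table <- function(grid) {
  cands <- if (inherits(grid, "qsmart_grid")) grid$candidates else grid
  do.call(rbind, lapply(cands, function(cand) {
    data.frame(
      grid_index = cand$grid_index, alpha = cand$alpha, gamma = cand$gamma,
      lambda = cand$lambda, n_features = cand$n_features,
      r2_train = cand_metric(cand, "r2_train"),
      q2_l10o = cand_metric(cand, "q2_l10o"),
      r2_test = cand_metric(cand, "r2_test"),
      q2_f1 = cand_metric(cand, "q2_f1"),
      q2_f2 = cand_metric(cand, "q2_f2"),
      q2_f3 = cand_metric(cand, "q2_f3"),
      ccc_test = cand_metric(cand, "ccc_test"),
      mse = cand_metric(cand, "mse"),
      ad_train = if (is.null(cand$ad)) NA_real_ else cand$ad$coverage$AD_Train,
      ad_test = if (is.null(cand$ad)) NA_real_ else cand$ad$coverage$AD_Test,
      eligible = isTRUE(cand$eligible),
      stringsAsFactors = FALSE
    )
  }))
}

#' Apply eligibility criteria to grid candidates
#'
#' A candidate is eligible when every blocking metric threshold is met and
#' its consensus test-set AD coverage equals the required percentage. Empty
#' candidates and candidates without AD reports are ineligible.
#'
#' @param grid A [grid_search()] result or list of candidates.
#' @param criteria An [eligibility_criteria()] object.
#' @return The same structure with each candidate's `eligible` flag set.
#' @export
apply_eligibility <- function(grid, criteria = eligibility_criteria()) {
  cands <- if (inherits(grid, "qsmart_grid")) grid$candidates else grid
  cands <- lapply(cands, function(cand) {
    if (is.null(cand$validation) || cand$n_features == 0L) {
      cand$eligible <- FALSE
      return(cand)
    }
    checks <- c(
      cand_metric(cand, "r2_train") >= criteria$r2_train,
      cand_metric(cand, "r2_test") >= criteria$r2_test,
      cand_metric(cand, "q2_l10o") >= criteria$q2_l10o,
      cand_metric(cand, "q2_f1") >= criteria$q2_f1,
      cand_metric(cand, "q2_f2") >= criteria$q2_f2,
      cand_metric(cand, "q2_f3") >= criteria$q2_f3,
      if (criteria$ccc_blocking) cand_metric(cand, "ccc_test") >= criteria$ccc else TRUE,
      !is.null(cand$ad) && cand$ad$coverage$AD_Test >= criteria$ad_test
    )
    cand$eligible <- all(checks, na.rm = FALSE) && !anyNA(checks)
    cand
  })
  if (inherits(grid, "qsmart_grid")) {
    grid$candidates <- cands
    grid
  } else {
    cands
  }
}

#' Select the final model among eligible candidates
#'
#' Ranks eligible candidates by prediction error E (test-set MSE,
#' ascending), breaking ties by fewest features, then widest training AD
#' coverage, then smallest grid index. The ranking is returned in full so
#' the choice is auditable; the result does not depend on input order.
#'
#' @param grid A [grid_search()] result (after [apply_eligibility()]) or a
#'   list of candidates.
#' @return List with `final` (the winning candidate) and `ranking` (data
#'   frame of eligible candidates in rank order).
#' @export
select_final <- function(grid) {
  cands <- if (inherits(grid, "qsmart_grid")) grid$candidates else grid
  eligible <- Filter(function(cand) isTRUE(cand$eligible), cands)
  if (length(eligible) == 0L) stop("no eligible model", call. = FALSE)
  tab <- candidates_table(eligible)
  ord <- order(tab$mse, tab$n_features, -tab$ad_train, tab$grid_index)
  ranking <- tab[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(final = eligible[[ord[1L]]], ranking = ranking)
}

#' Run the grid search on a single view (MD-only or MOA-only)
#'
#' Applies the identical procedure to one block family: nine cells over the
#' relevant exponent (the other exponent is inert because no column of the
#' other kind is present).
#'
#' @param dataset A [fuse()]d dataset containing the requested view.
#' @param view `"MD"` (descriptor block) or `"MOA"` (all gene blocks).
#' @param grid Exponent grid for the view; default [default_grid()].
#' @param ... Passed to [grid_search()].
#' @return A `qsmart_grid` with `length(grid)` candidates.
#' @export
compare_single_view <- function(dataset, view = c("MD", "MOA"),
                                grid = default_grid(), ...) {
  view <- match.arg(view)
  sub <- subset_view(dataset, view)
  if (view == "MD") {
    grid_search(sub, alpha_grid = grid, gamma_grid = 1, ...)
  } else {
    grid_search(sub, alpha_grid = 1, gamma_grid = grid, ...)
  }
}
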
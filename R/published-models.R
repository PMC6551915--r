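#' Bundled published HSA-binding models
#'
#' Three published logK_HSA models ship with the package as JSON files and
#' load as ready-to-use [qsmart_model()] objects:
#'
#' * `"QSMART_FINAL"` — the integrated six-term model: three molecular
#'   descriptors (Mor23i, N-072, ALOGP) at exponent 1.25 and three gene
#'   log fold-change features (MCF7_ENSG00000112115, PC3_ENSG00000197646,
#'   PC3_ENSG00000276644) at exponent 1.75.
#' * `"MD_ONLY"` — the nine-descriptor model at exponent 0.11.
#' * `"MOA_ONLY"` — the nine-gene model at exponent 0.16.
#'
#' Gene features enter as absolute log fold-changes: the model applies
#' `|x|^exponent` itself, so signed logFC input is correct. No training
#' data ships with the models, so their prediction range is absent unless
#' the user supplies a training design (see [screen_external()]).
#'
#' @param name One of `"QSMART_FINAL"`, `"MD_ONLY"`, `"MOA_ONLY"`.
#' @return A `qsmart_model`.
#' @examples
#' m <- published_model("QSMART_FINAL")
#' # all-zero features return the intercept
#' predict(m, matrix(0, 1, 6, dimnames = list("cpd", names(m$coefficients))))
#' @export
published_model <- function(name = c("QSMART_FINAL", "MD_ONLY", "MOA_ONLY")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models",
                      paste0(tolower(name), ".json"), package = "qsmartr")
  if (!nzchar(path)) stop("bundled model file not found for ", name, call. = FALSE)
  read_qsmart_model(path)
}

#' Predict with a bundled published model
#'
#' @inheritParams published_model
#' @param feature_table Matrix or data frame of raw feature values whose
#'   column names cover every feature of the chosen model.
#' @return Named numeric vector of predicted logK_HSA values.
#' @export
predict_published <- function(name, feature_table) {
  predict(published_model(name), feature_table)
}

#' Screen external compounds through the Insubria graph
#'
#' Classifies compounds lacking experimental responses: leverages are
#' computed against a user-supplied training design in the model's feature
#' space, predictions against the model, and each compound is labelled
#' interpolated/extrapolated (leverage vs the warning leverage) and in/out
#' of the model's response range when one is available.
#'
#' @inheritParams predict_published
#' @param train_design Matrix of raw training feature values (columns =
#'   model features) standing in for the model's training set; transformed
#'   internally like any model input.
#' @param h_star Warning leverage; by default
#'   `critical_hat(k, nrow(train_design))` for a k-feature model.
#' @param prediction_range Optional `c(min, max)` response range; by
#'   default the range of the model's predictions on `train_design`.
#' @return An [insubria()] data frame, one row per compound of
#'   `feature_table`.
#' @export
screen_external <- function(name, feature_table, train_design, h_star = NULL,
                            prediction_range = NULL) {
  model <- published_model(name)
  feats <- names(model$coefficients)
  feature_table <- as.matrix(as.data.frame(feature_table))
  train_design <- as.matrix(as.data.frame(train_design))
  missing <- setdiff(feats, colnames(train_design))
  if (length(missing)) stop("train_design lacks model feature(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  expo <- model_exponents(model)
  Zt <- sweep(abs(train_design[, feats, drop = FALSE]), 2L, expo, "^")
  if (is.null(h_star)) h_star <- critical_hat(length(feats), nrow(train_design))
  if (is.null(prediction_range)) {
    prediction_range <- range(predict(model, train_design))
  }
  if (nrow(feature_table) == 0L) {
    return(insubria(numeric(0), numeric(0), h_star, prediction_range))
  }
  miss_q <- setdiff(feats, colnames(feature_table))
  if (length(miss_q)) stop("feature_table lacks model feature(s): ",
                           paste(miss_q, collapse = ", "), call. = FALSE)
  Zq <- sweep(abs(feature_table[, feats, drop = FALSE]), 2L, expo, "^")
  h <- leverage(Zt, Zq)
  pred <- predict(model, feature_table)
  out <- insubria(h, pred, h_star, prediction_range)
  rownames(out) <- rownames(feature_table)
  out
}
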
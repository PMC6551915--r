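#' Configuration for an end-to-end modeling run
#'
#' Collects file paths, grids, split settings and thresholds. Defaults
#' match the standard workflow: an 80/20 stratified outer split, 100 inner
#' 90/10 RSVA splits over three response bins, a 100-value penalty path,
#' 60th-percentile aggregation, k = 3 neighbours, and the 9 x 9 exponent
#' grid.
#'
#' @param md_path Path to the descriptor CSV/TSV.
#' @param gene_paths Named character vector of gene logFC tables, names
#'   being cell-line labels (may be empty).
#' @param response_path Two-column CSV (compound_id, response).
#' @param out_dir Output directory.
#' @param alpha_grid,gamma_grid Exponent grids; default [default_grid()].
#' @param n_splits,inner_train_frac,outer_train_frac,n_bins,n_lambdas,percentile,k_nn
#'   Workflow settings (defaults 100, 0.9, 0.8, 3, 100, 60, 3).
#' @param filter_frac,filter_r Constant / correlation filter thresholds
#'   (defaults 0.80 and 0.95).
#' @param filter_genes Also apply both filters to gene blocks; default
#'   `FALSE` (descriptor-only filtering).
#' @param criteria An [eligibility_criteria()] object.
#' @param validation `"full"` or `"basic"` (see [grid_search()]).
#' @param seed Integer seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(md_path = NULL, gene_paths = character(),
                       response_path = NULL, out_dir = "qsmartr-run",
                       alpha_grid = default_grid(), gamma_grid = default_grid(),
                       n_splits = 100, inner_train_frac = 0.9,
                       outer_train_frac = 0.8, n_bins = 3, n_lambdas = 100,
                       percentile = 60, k_nn = 3, filter_frac = 0.80,
                       filter_r = 0.95, filter_genes = FALSE,
                       criteria = eligibility_criteria(),
                       validation = "full", seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

load_run_inputs <- function(config) {
  if (is.null(config$md_path) && length(config$gene_paths) == 0L) {
    stop("[input] no feature tables configured", call. = FALSE)
  }
  if (is.null(config$response_path) || !file.exists(config$response_path)) {
    stop("[input] response file missing: ",
         if (is.null(config$response_path)) "<not set>" else config$response_path,
         call. = FALSE)
  }
  resp_df <- read.table(config$response_path, header = TRUE, sep = ",",
                        stringsAsFactors = FALSE)
  response <- stats::setNames(as.numeric(resp_df[[2L]]),
                              as.character(resp_df[[1L]]))
  md <- NULL
  if (!is.null(config$md_path)) {
    md <- load_block(config$md_path, "MD", "descriptors")
    md <- filter_constant(md, config$filter_frac)
    md <- filter_correlated(md, config$filter_r)
  }
  genes <- lapply(seq_along(config$gene_paths), function(i) {
    lab <- names(config$gene_paths)[i]
    if (is.null(lab) || !nzchar(lab)) {
      lab <- sub("\\.[^.]*$", "", basename(config$gene_paths[i]))
    }
    g <- load_block(config$gene_paths[i], "GENE", lab)
    if (isTRUE(config$filter_genes)) {
      g <- filter_constant(g, config$filter_frac)
      g <- filter_correlated(g, config$filter_r)
    }
    g
  })
  list(md = md, genes = genes,
       dataset = fuse(md, genes, response))
}

#' Run the full modeling workflow
#'
#' Filter, fuse, outer split, grid search, eligibility, final-model
#' selection; writes the candidates table, the final model JSON, validation
#' and AD reports, the split plans and an effective-config manifest into
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the grid, the selection result (or
#'   `NULL` when no candidate is eligible) and the output paths.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)
  dataset <- inputs$dataset
  outer <- stratified_split(dataset$response, config$outer_train_frac,
                            n_bins = config$n_bins, seed = config$seed)
  grid <- grid_search(dataset, alpha_grid = config$alpha_grid,
                      gamma_grid = config$gamma_grid, outer_split = outer,
                      n_splits = config$n_splits,
                      train_frac = config$inner_train_frac,
                      n_bins = config$n_bins, n_lambdas = config$n_lambdas,
                      percentile = config$percentile,
                      validation = config$validation, seed = config$seed)
  grid <- apply_eligibility(grid, config$criteria)
  selection <- tryCatch(select_final(grid), error = function(e) NULL)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(candidates = file.path(config$out_dir, "candidates.csv"),
                manifest = file.path(config$out_dir, "manifest.json"),
                splits = file.path(config$out_dir, "splits.csv"))
  write.csv(candidates_table(grid), paths$candidates, row.names = FALSE)
  write_split_plans(list(outer), paths$splits)
  if (!is.null(selection)) {
    paths$final_model <- file.path(config$out_dir, "final_model.json")
    paths$validation <- file.path(config$out_dir, "validation.csv")
    write_qsmart_model(selection$final$model, paths$final_model)
    write_validation_report(selection$final$validation, paths$validation)
    if (!is.null(selection$final$ad)) {
      paths$ad <- file.path(config$out_dir, "ad.csv")
      write_ad_report(selection$final$ad, paths$ad)
    }
  }
  manifest <- config
  manifest$criteria <- unclass(config$criteria)
  manifest <- lapply(unclass(manifest), function(v) if (is.null(v)) NA else v)
  manifest$selected_grid_index <-
    if (is.null(selection)) NA else selection$final$grid_index
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(grid = grid, selection = selection, paths = paths))
}

#' Predict from a serialized model over a feature table
#'
#' Reads a model JSON and a raw feature table, writes a predictions CSV,
#' and — when a training-design table is supplied — appends
#' Insubria-graph labels (extrapolated, out_of_range).
#'
#' @param model_path Path to a [write_qsmart_model()] JSON.
#' @param features_path Delimited table (header + compound-ID column) of
#'   raw feature values.
#' @param out_path Output CSV path.
#' @param train_design_path Optional table of raw training feature values
#'   used for leverage and the prediction range.
#' @return The predictions data frame, invisibly.
#' @export
run_predict <- function(model_path, features_path, out_path,
                        train_design_path = NULL) {
  model <- read_qsmart_model(model_path)
  header <- readLines(features_path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- read.table(features_path, header = TRUE, sep = sep,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  X <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(X) <- ids
  out <- data.frame(compound_id = ids,
                    prediction = if (nrow(X)) unname(predict(model, X)) else numeric(0),
                    stringsAsFactors = FALSE)
  if (!is.null(train_design_path)) {
    tr <- read.table(train_design_path, header = TRUE, sep = sep,
                     check.names = FALSE, stringsAsFactors = FALSE)
    Xtr <- as.matrix(tr[, -1L, drop = FALSE])
    feats <- names(model$coefficients)
    expo <- model_exponents(model)
    Zt <- sweep(abs(Xtr[, feats, drop = FALSE]), 2L, expo, "^")
    Zq <- sweep(abs(X[, feats, drop = FALSE]), 2L, expo, "^")
    h_star <- critical_hat(length(feats), nrow(Xtr))
    rng <- range(predict(model, Xtr))
    ins <- insubria(if (nrow(Zq)) leverage(Zt, Zq) else numeric(0),
                    out$prediction, h_star, rng)
    out <- cbind(out, ins[, c("leverage", "extrapolated", "out_of_range")])
  }
  write.csv(out, out_path, row.names = FALSE)
  invisible(out)
}
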
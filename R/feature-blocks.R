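#' Construct a feature block
#'
#' A feature block is one compounds-by-features numeric matrix: either a
#' molecular-descriptor (MD) table or a per-gene log fold-change table for
#' one cell line (a "GENE" block). Blocks are the unit on which filtering
#' operates before fusion into a single modeling matrix.
#'
#' @param values Numeric matrix with compound identifiers as row names and
#'   feature names as column names. All entries must be finite.
#' @param block_kind Either `"MD"` or `"GENE"`.
#' @param source_label Free-text label for provenance, e.g. a cell-line name
#'   such as `"MCF7"`. Used to prefix gene feature names at fusion time.
#' @return An object of class `feature_block`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("c1", "c2", "c3"), c("f1", "f2")))
#' feature_block(m, "MD", "descriptors")
#' @export
feature_block <- function(values, block_kind = c("MD", "GENE"),
                          source_label = "") {
  block_kind <- match.arg(block_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  ids <- rownames(values)
  feats <- colnames(values)
  if (is.null(ids) || is.null(feats)) {
    stop("`values` must have compound IDs as rownames and feature names as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate compound IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(feats)) {
    stop("duplicate feature names: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at compound '%s', feature '%s'",
                 ids[bad[1L]], feats[bad[2L]]), call. = FALSE)
  }
  structure(list(compound_ids = ids, feature_names = feats, values = values,
                 block_kind = block_kind, source_label = source_label),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %s%s: %d compounds x %d features\n",
              x$block_kind,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a feature block from a delimited text file
#'
#' Expects a header row of feature names and a first column of compound
#' identifiers; the body must be numeric. The delimiter is auto-detected
#' (tab if the header line contains a tab, otherwise comma) and can be
#' overridden.
#'
#' @param path Path to a CSV/TSV file.
#' @inheritParams feature_block
#' @param sep Field delimiter; `NULL` (default) auto-detects.
#' @return A [feature_block()].
#' @export
load_block <- function(path, block_kind = c("MD", "GENE"), source_label = "",
                       sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
  if (ncol(raw) < 2L) stop("expected a compound-ID column plus >=1 feature column",
                           call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(as.numeric(vals), nrow = nrow(body),
                 dimnames = list(ids, colnames(body)))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  }
  feature_block(vals, block_kind = block_kind, source_label = source_label)
}

removal_log <- function(block) {
  log <- attr(block, "removal_log")
  if (is.null(log)) {
    log <- data.frame(feature = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  log
}

append_removals <- function(block, removed, reason, prior) {
  log <- rbind(prior, data.frame(feature = removed,
                                 reason = rep_len(reason, length(removed)),
                                 stringsAsFactors = FALSE))
  attr(block, "removal_log") <- log
  block
}

#' Remove near-constant features
#'
#' Drops every feature whose single most frequent value occurs in strictly
#' more than `frac` of the compounds (exact-value modal frequency, not
#' variance). Survivor order is preserved, and a removal log is attached as
#' the `"removal_log"` attribute (a two-column data frame: feature, reason).
#'
#' @param block A [feature_block()].
#' @param frac Modal-frequency threshold in (0, 1); default 0.80, removal
#'   only when the modal share is strictly greater.
#' @return The filtered `feature_block`.
#' @export
filter_constant <- function(block, frac = 0.80) {
  stopifnot(inherits(block, "feature_block"))
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1) {
    stop("`frac` must be a single proportion in (0, 1)", call. = FALSE)
  }
  n <- nrow(block$values)
  modal_share <- apply(block$values, 2L, function(x) max(tabulate(match(x, unique(x)))) / n)
  drop <- modal_share > frac
  kept <- feature_block(block$values[, !drop, drop = FALSE],
                        block_kind = block$block_kind,
                        source_label = block$source_label)
  append_removals(kept, block$feature_names[drop],
                  sprintf("modal frequency > %.2f", frac), removal_log(block))
}

#' Remove highly intercorrelated features
#'
#' For every feature pair with absolute Pearson correlation strictly above
#' `r`, one member is removed. The rule is deterministic: features are
#' scanned in column order and the LATER member of an offending pair is
#' dropped, so survivors pairwise satisfy |r| <= threshold and the result is
#' order-stable. Constant features must be removed first (their correlation
#' is undefined).
#'
#' @param block A [feature_block()] with at least two features.
#' @param r Absolute-correlation threshold; default 0.95, removal only when
#'   strictly exceeded.
#' @return The filtered `feature_block` with updated removal log.
#' @export
filter_correlated <- function(block, r = 0.95) {
  stopifnot(inherits(block, "feature_block"))
  p <- ncol(block$values)
  if (p < 2L) stop("need at least two features", call. = FALSE)
  sds <- apply(block$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) present (undefined correlation): ",
         paste(block$feature_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm <- abs(stats::cor(block$values))
  keep <- rep(TRUE, p)
  for (j in seq_len(p - 1L)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(p) > j & cm[j, ] > r)
    keep[later] <- FALSE
  }
  kept <- feature_block(block$values[, keep, drop = FALSE],
                        block_kind = block$block_kind,
                        source_label = block$source_label)
  append_removals(kept, block$feature_names[!keep],
                  sprintf("|pairwise correlation| > %.2f", r), removal_log(block))
}

#' Fuse descriptor and gene blocks with the response into one dataset
#'
#' Restricts all blocks and the response to the compounds present in every
#' input, reorders rows to a single canonical order (sorted IDs), prefixes
#' gene feature names with their block's `source_label`, and records a
#' global feature index. The result is the modeling matrix X with aligned
#' response y.
#'
#' @param md_block A `feature_block` of kind `"MD"`.
#' @param gene_blocks List of `feature_block`s of kind `"GENE"` (may be
#'   empty for a descriptor-only dataset).
#' @param response Named numeric vector of the modeled endpoint (e.g.
#'   logK_HSA), names being compound IDs.
#' @return An object of class `fused_dataset` with elements `blocks`,
#'   `response`, and `feature_index`.
#' @export
fuse <- function(md_block, gene_blocks = list(), response) {
  if (inherits(gene_blocks, "feature_block")) gene_blocks <- list(gene_blocks)
  blocks <- c(if (!is.null(md_block)) list(md_block) else list(), gene_blocks)
  if (length(blocks) == 0L) stop("at least one block required", call. = FALSE)
  for (b in blocks) stopifnot(inherits(b, "feature_block"))
  if (is.null(names(response)) || !is.numeric(response)) {
    stop("`response` must be a named numeric vector", call. = FALSE)
  }
  ids <- Reduce(intersect, c(lapply(blocks, `[[`, "compound_ids"),
                             list(names(response))))
  if (length(ids) == 0L) {
    stop("no compounds shared by all blocks and the response", call. = FALSE)
  }
  ids <- sort(ids)
  blocks <- lapply(blocks, function(b) {
    vals <- b$values[ids, , drop = FALSE]
    nm <- colnames(vals)
    if (b$block_kind == "GENE" && nzchar(b$source_label)) {
      nm <- ifelse(startsWith(nm, paste0(b$source_label, "_")), nm,
                   paste0(b$source_label, "_", nm))
      colnames(vals) <- nm
    }
    feature_block(vals, block_kind = b$block_kind, source_label = b$source_label)
  })
  feats <- unlist(lapply(blocks, `[[`, "feature_names"), use.names = FALSE)
  if (anyDuplicated(feats)) {
    stop("global feature names not unique after prefixing: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "), call. = FALSE)
  }
  feature_index <- data.frame(
    feature = feats,
    block = rep(seq_along(blocks), vapply(blocks, function(b) ncol(b$values), 0L)),
    block_kind = rep(vapply(blocks, `[[`, "", "block_kind"),
                     vapply(blocks, function(b) ncol(b$values), 0L)),
    column = unlist(lapply(blocks, function(b) seq_len(ncol(b$values)))),
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, response = response[ids],
                 feature_index = feature_index),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(sprintf("<fused_dataset> %d compounds, %d features in %d block(s)\n",
              length(x$response), nrow(x$feature_index), length(x$blocks)))
  for (b in x$blocks) print(b)
  invisible(x)
}

#' Compound identifiers of a fused dataset
#' @param dataset A [fuse()]d dataset.
#' @return Character vector in canonical row order.
#' @export
compound_ids <- function(dataset) {
  stopifnot(inherits(dataset, "fused_dataset"))
  names(dataset$response)
}

#' Raw (untransformed) design matrix of a fused dataset
#'
#' Column-binds all blocks in block order; columns carry the global
#' (prefixed) feature names.
#'
#' @param dataset A [fuse()]d dataset.
#' @return Numeric matrix, compounds x features.
#' @export
design_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "fused_dataset"))
  do.call(cbind, lapply(dataset$blocks, `[[`, "values"))
}

# per-column block kind ("MD"/"GENE"), aligned with design_matrix columns
column_kinds <- function(dataset) {
  dataset$feature_index$block_kind
}

#' Restrict a fused dataset to a subset of compounds
#' @param dataset A [fuse()]d dataset.
#' @param ids Compound identifiers to keep (canonical order is preserved).
#' @return A `fused_dataset`.
#' @export
subset_compounds <- function(dataset, ids) {
  stopifnot(inherits(dataset, "fused_dataset"))
  keep <- compound_ids(dataset)[compound_ids(dataset) %in% ids]
  if (length(keep) == 0L) stop("no matching compounds", call. = FALSE)
  blocks <- lapply(dataset$blocks, function(b) {
    feature_block(b$values[keep, , drop = FALSE], b$block_kind, b$source_label)
  })
  structure(list(blocks = blocks, response = dataset$response[keep],
                 feature_index = dataset$feature_index),
            class = "fused_dataset")
}

#' Restrict a fused dataset to one view (MD or GENE blocks)
#' @param dataset A [fuse()]d dataset.
#' @param view `"MD"` or `"MOA"` (all gene blocks).
#' @return A `fused_dataset` containing only the requested blocks.
#' @export
subset_view <- function(dataset, view = c("MD", "MOA")) {
  view <- match.arg(view)
  kind <- if (view == "MD") "MD" else "GENE"
  keep <- vapply(dataset$blocks, function(b) b$block_kind == kind, TRUE)
  if (!any(keep)) stop("view '", view, "' not present in dataset", call. = FALSE)
  blocks <- dataset$blocks[keep]
  feature_index <- dataset$feature_index[dataset$feature_index$block_kind == kind, ,
                                         drop = FALSE]
  feature_index$block <- match(feature_index$block, which(keep))
  rownames(feature_index) <- NULL
  structure(list(blocks = blocks, response = dataset$response,
                 feature_index = feature_index),
            class = "fused_dataset")
}

#' Write a block's removal log to CSV
#' @param block A filtered [feature_block()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(block, path) {
  write.csv(removal_log(block), path, row.names = FALSE)
  invisible(path)
}
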
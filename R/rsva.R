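#' Stratified response-binned train/holdout split
#'
#' The splitting primitive of the random split validation algorithm (RSVA).
#' The response is cut into `n_bins` equal-frequency bins (quantile edges);
#' within each bin the compounds are shuffled by a seeded RNG and the train
#' side receives `ceiling(bin_size * train_frac)` members (capped at
#' `bin_size - 1` so every bin of size at least two contributes to both
#' sides), the remainder going to the holdout side. The plan is deterministic given the seed, and
#' bin edges depend only on the response vector, so all plans built from
#' the same response share edges.
#'
#' @param response Named numeric vector (compound IDs as names).
#' @param train_frac Proportion assigned to the training side, in (0, 1).
#' @param n_bins Number of response bins; default 3.
#' @param seed Integer seed.
#' @return An object of class `split_plan` with `train_ids`, `holdout_ids`,
#'   `seed`, and `bin_edges`.
#' @export
stratified_split <- function(response, train_frac, n_bins = 3, seed = 1) {
  if (is.null(names(response)) || !is.numeric(response)) {
    stop("`response` must be a named numeric vector", call. = FALSE)
  }
  n <- length(response)
  if (n < 2L) stop("need at least two compounds to split", call. = FALSE)
  if (n < n_bins) stop("fewer compounds than bins", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  edges <- response_bin_edges(response, n_bins)
  bins <- bin_response(response, edges)
  train_ids <- character()
  with_seed(seed, {
    for (b in seq_len(n_bins)) {
      members <- names(response)[bins == b]
      if (length(members) == 0L) next
      members <- sample(members)
      n_tr <- ceiling(length(members) * train_frac)
      # every bin of size >= 2 contributes to both sides
      if (length(members) >= 2L) n_tr <- min(n_tr, length(members) - 1L)
      train_ids <- c(train_ids, members[seq_len(n_tr)])
    }
  })
  holdout_ids <- setdiff(names(response), train_ids)
  structure(list(train_ids = sort(train_ids), holdout_ids = sort(holdout_ids),
                 seed = as.integer(seed), bin_edges = edges),
            class = "split_plan")
}

# Equal-frequency (quantile) bin edges; interior quantiles only.
response_bin_edges <- function(response, n_bins) {
  probs <- seq(0, 1, length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
  unname(stats::quantile(response, probs = probs, type = 7))
}

bin_response <- function(response, edges) {
  findInterval(response, vec = edges, left.open = TRUE) + 1L
}

#' Build the repeated RSVA split plans
#'
#' Generates `n_splits` stratified plans over the training set, with seeds
#' `base_seed + i - 1` for the i-th plan, so the whole ensemble is
#' reproducible from one integer.
#'
#' @param response Named numeric response of the (outer) training set.
#' @param n_splits Number of plans; default 100.
#' @param train_frac Inner training fraction; default 0.9.
#' @param n_bins Response bins; default 3.
#' @param base_seed Integer seed of the first plan.
#' @return List of [stratified_split()] plans.
#' @export
make_rsva_splits <- function(response, n_splits = 100, train_frac = 0.9,
                             n_bins = 3, base_seed = 1) {
  lapply(seq_len(n_splits), function(i) {
    stratified_split(response, train_frac = train_frac, n_bins = n_bins,
                     seed = base_seed + i - 1L)
  })
}

#' Aggregate per-split metrics at a percentile
#'
#' The RSVA summary: for each metric, the given percentile of its values
#' across splits, using the linear-interpolation convention between order
#' statistics (R's quantile type 7), which makes the aggregate
#' bit-reproducible.
#'
#' @param per_split Data frame or matrix with one row per split and one
#'   column per metric.
#' @param percentile Percentile in \[0, 100\]; default 60.
#' @return Named numeric vector of aggregated metrics.
#' @export
aggregate_metrics <- function(per_split, percentile = 60) {
  per_split <- as.data.frame(per_split)
  if (nrow(per_split) < 1L) stop("need at least one split row", call. = FALSE)
  vapply(per_split, function(v) {
    unname(stats::quantile(v, probs = percentile / 100, type = 7, na.rm = TRUE))
  }, numeric(1))
}

#' Export split plans as a long CSV
#' @param splits List of [stratified_split()] plans.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_plans <- function(splits, path) {
  rows <- do.call(rbind, lapply(seq_along(splits), function(i) {
    p <- splits[[i]]
    data.frame(compound_id = c(p$train_ids, p$holdout_ids),
               split_index = i,
               role = rep(c("train", "holdout"),
                          c(length(p$train_ids), length(p$holdout_ids))),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
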
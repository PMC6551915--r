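#' Specification for a synthetic fused dataset
#'
#' Describes a toy-scale analogue of a fused descriptor + transcriptomics
#' modeling problem: an MD block with heterogeneous column marginals
#' (mixed scales, signs and sparsity, plus a few near-constant columns and
#' exact duplicate pairs to exercise the filters), one gene log fold-change
#' block per cell line with zero-centered small-dispersion columns, and a
#' response generated from a planted sparse linear signal in
#' power-transformed space with additive Gaussian noise.
#'
#' Each active feature's coefficient is scaled so that its contribution to
#' the response has standard deviation `beta_scale` times a Uniform(0.5,
#' 1.5) draw, making the planted signal comparable across columns of very
#' different scales.
#'
#' @param n_compounds Number of compounds; default 100.
#' @param p_md MD-block width; default 50.
#' @param p_gene Gene-block width per cell line; default 50.
#' @param n_cell_lines Number of gene blocks; default 2.
#' @param k_active_md Planted active MD features; default 3.
#' @param k_active_gene Planted active gene features per cell line;
#'   default 1 (so the default total support size is 5).
#' @param true_alpha,true_gamma Exponents of the planted transform;
#'   defaults 1.25 and 1.75.
#' @param beta_scale Per-feature signal scale (response-SD units);
#'   default 1.
#' @param noise_sd Additive noise SD; default 0.1.
#' @param intercept True intercept; default 0.5.
#' @param n_near_constant Near-constant bait columns in the MD block;
#'   default 2.
#' @param n_duplicate_pairs Exact-duplicate bait pairs in the MD block;
#'   default 1.
#' @param seed Integer seed; one RNG stream drives the whole draw.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 100, p_md = 50, p_gene = 50,
                           n_cell_lines = 2, k_active_md = 3,
                           k_active_gene = 1, true_alpha = 1.25,
                           true_gamma = 1.75, beta_scale = 1, noise_sd = 0.1,
                           intercept = 0.5, n_near_constant = 2,
                           n_duplicate_pairs = 1, seed = 1) {
  stopifnot(noise_sd >= 0, beta_scale > 0, true_alpha > 0, true_gamma > 0,
            k_active_md + n_near_constant + 2 * n_duplicate_pairs <= p_md,
            k_active_gene <= p_gene, n_cell_lines >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

cell_line_labels <- function(n) {
  base <- c("MCF7", "PC3")
  if (n <= 2L) base[seq_len(n)] else c(base, paste0("CL", seq_len(n - 2L) + 2L))
}

# MD columns: cycle through uniform (signed, mixed scale), log-normal
# (positive, heavy-tailed) and Poisson count-like (sparse) marginals.
draw_md_columns <- function(n, p) {
  vapply(seq_len(p), function(j) {
    switch((j - 1L) %% 3L + 1L,
           runif(n, -1, 1) * 10^runif(1, -1, 1.5),
           rlnorm(n, meanlog = runif(1, -1, 2), sdlog = 0.6),
           rpois(n, lambda = sample(c(0.3, 1, 4), 1)))
  }, numeric(n))
}

#' Generate a synthetic fused dataset with a planted sparse signal
#'
#' Draws the blocks described by a [synthetic_spec()], plants a sparse
#' coefficient vector on power-transformed columns, and returns the fused
#' dataset together with a truth record (support, coefficients, exponents,
#' and the identities of the filter-bait columns, which are never part of
#' the support).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [fuse()]d dataset) and `truth`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sim <- with_seed(spec$seed, draw_synthetic(spec, null_response = FALSE))
  sim
}

#' Generate a null dataset (response independent of the features)
#'
#' Identical feature draw to [generate()], but the response is pure
#' standard-normal noise, unrelated to any column — the negative control
#' for calibration studies.
#'
#' @param spec A [synthetic_spec()].
#' @return A [fuse()]d dataset.
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, draw_synthetic(spec, null_response = TRUE))$dataset
}

draw_synthetic <- function(spec, null_response) {
  n <- spec$n_compounds
  ids <- sprintf("cpd%04d", seq_len(n))

  md <- draw_md_columns(n, spec$p_md)
  colnames(md) <- sprintf("MD%03d", seq_len(spec$p_md))
  rownames(md) <- ids

  # bait columns at the tail of the MD block: near-constant columns whose
  # modal share is 0.9, and exact duplicates of inactive columns
  p <- spec$p_md
  bait_const <- bait_dup <- character(0)
  if (spec$n_near_constant > 0) {
    idx <- p - seq_len(spec$n_near_constant) + 1L
    for (j in idx) {
      x <- rep(round(runif(1, 1, 5)), n)
      n_dev <- max(1L, floor(0.1 * n))
      x[sample(n, n_dev)] <- x[1L] + runif(n_dev)
      md[, j] <- x
    }
    bait_const <- colnames(md)[idx]
  }
  if (spec$n_duplicate_pairs > 0) {
    for (d in seq_len(spec$n_duplicate_pairs)) {
      j2 <- p - spec$n_near_constant - (2L * d - 1L)
      j1 <- j2 - 1L
      md[, j2] <- md[, j1]
    }
    pairs <- vapply(seq_len(spec$n_duplicate_pairs), function(d) {
      j2 <- p - spec$n_near_constant - (2L * d - 1L)
      c(colnames(md)[j2 - 1L], colnames(md)[j2])
    }, character(2))
    bait_dup <- as.character(pairs)
  }
  md_block <- feature_block(md, "MD", "descriptors")

  labels <- cell_line_labels(spec$n_cell_lines)
  gene_blocks <- lapply(labels, function(lab) {
    g <- matrix(rnorm(n * spec$p_gene, 0, 0.5), n, spec$p_gene,
                dimnames = list(ids, sprintf("ENSG%08d", seq_len(spec$p_gene))))
    feature_block(g, "GENE", lab)
  })

  # planted support: head MD columns (never the bait tail) and the head
  # gene columns of each cell line
  support_md <- colnames(md)[seq_len(spec$k_active_md)]
  support_gene <- unlist(lapply(labels, function(lab) {
    paste0(lab, "_", sprintf("ENSG%08d", seq_len(spec$k_active_gene)))
  }))
  support <- c(support_md, support_gene)

  # assemble the response before fusing so the truth is on raw blocks
  response <- stats::setNames(rep(spec$intercept, n), ids)
  dataset0 <- fuse(md_block, gene_blocks,
                   stats::setNames(rnorm(n), ids))  # placeholder response
  Xab <- power_transform(dataset0, power_params(spec$true_alpha, spec$true_gamma))
  beta <- stats::setNames(numeric(length(support)), support)
  for (f in support) {
    z <- Xab[, f]
    s <- stats::sd(z)
    if (s == 0) s <- 1
    beta[f] <- sample(c(-1, 1), 1) * spec$beta_scale * runif(1, 0.5, 1.5) / s
  }
  y <- if (null_response) {
    stats::setNames(rnorm(n), ids)
  } else {
    response + as.numeric(Xab[, support, drop = FALSE] %*% beta) +
      rnorm(n, 0, spec$noise_sd)
  }
  dataset <- fuse(md_block, gene_blocks, stats::setNames(y, ids))
  list(dataset = dataset,
       truth = list(support = support, beta = beta,
                    intercept = spec$intercept, alpha = spec$true_alpha,
                    gamma = spec$true_gamma,
                    bait = list(near_constant = bait_const,
                                duplicates = bait_dup)))
}

#' Write synthetic inputs as the delimited files the pipeline reads
#'
#' Emits one CSV per block (descriptor block plus one per cell line), a
#' two-column response CSV, and a truth JSON, mirroring the on-disk input
#' contract of [load_block()] and [run_fit()].
#'
#' @param sim A [generate()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (b in sim$dataset$blocks) {
    fname <- if (b$block_kind == "MD") "md.csv" else paste0(b$source_label, ".csv")
    path <- file.path(dir, fname)
    vals <- b$values
    if (b$block_kind == "GENE") {
      # strip the fusion prefix so files round-trip through fuse()
      colnames(vals) <- sub(paste0("^", b$source_label, "_"), "", colnames(vals))
    }
    df <- data.frame(compound_id = rownames(vals), vals, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    paths[[fname]] <- path
  }
  resp <- data.frame(compound_id = names(sim$dataset$response),
                     response = as.numeric(sim$dataset$response))
  write.csv(resp, file.path(dir, "response.csv"), row.names = FALSE)
  paths[["response.csv"]] <- file.path(dir, "response.csv")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["truth.json"]] <- file.path(dir, "truth.json")
  invisible(paths)
}
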
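# Shared in-code fixtures: everything is generated, nothing read from disk.

mk_block <- function(values, kind = "MD", label = "descriptors",
                     ids = NULL, feats = NULL) {
  if (is.null(ids)) ids <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(feats)) feats <- sprintf("f%d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, feats)
  feature_block(values, kind, label)
}

# small fused dataset with a known linear signal on transformed columns
mk_fused <- function(n = 30, p_md = 6, p_gene = 4, seed = 1, noise = 0.05,
                     alpha = 1, gamma = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("c%02d", seq_len(n))
    md <- matrix(rnorm(n * p_md, sd = 2), n,
                 dimnames = list(ids, sprintf("MD%02d", seq_len(p_md))))
    g1 <- matrix(rnorm(n * p_gene, sd = 0.5), n,
                 dimnames = list(ids, sprintf("G%02d", seq_len(p_gene))))
    y <- 0.3 + 1.5 * abs(md[, 1])^alpha - 2 * abs(g1[, 1])^gamma +
      rnorm(n, sd = noise)
    fuse(feature_block(md, "MD", "descriptors"),
         list(feature_block(g1, "GENE", "MCF7")),
         stats::setNames(y, ids))
  })
}

# write a small delimited feature table; returns the path
write_table_fixture <- function(df, sep = ",", ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
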
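# Block loading, filtering and fusion.

test_that("load_block reads a delimited table with IDs and enforces numerics", {
  df <- data.frame(compound_id = c("a", "b", "c"),
                   f1 = c(1, 2, 3), f2 = c(0.5, -1, 2))
  b <- load_block(write_table_fixture(df), "MD", "descriptors")
  expect_s3_class(b, "feature_block")
  expect_equal(dim(b$values), c(3L, 2L))
  expect_equal(b$values["b", "f2"], -1)

  # tab-delimited autodetection
  bt <- load_block(write_table_fixture(df, sep = "\t", ext = "tsv"), "MD")
  expect_equal(bt$values, b$values)

  dup <- df; dup$compound_id[2] <- "a"
  expect_error(load_block(write_table_fixture(dup), "MD"), "duplicate compound")

  bad <- df; bad$f2 <- c("0.5", "NA", "2")
  expect_error(load_block(write_table_fixture(bad), "MD"), "row 'b', column 'f2'")
})

test_that("filter_constant removes by strict modal-frequency rule", {
  vals <- cbind(const = rep(7, 5),           # 5/5 modal > 0.8 -> removed
                border = c(1, 1, 1, 1, 2),   # 4/5 = 0.80 exactly -> kept
                distinct = 1:5)              # all distinct -> kept
  b <- filter_constant(mk_block(vals, feats = colnames(vals)), frac = 0.8)
  expect_equal(b$feature_names, c("border", "distinct"))
  log <- attr(b, "removal_log")
  expect_equal(log$feature, "const")

  expect_error(filter_constant(mk_block(vals), frac = 1.2), "proportion")
})

test_that("filter_correlated drops the later member of each offending pair", {
  withr::local_seed(11)
  x <- rnorm(200)
  z1 <- rnorm(200); z2 <- rnorm(200)
  stopifnot(abs(cor(z1, z2)) < 0.95)  # validates the fixture itself
  vals <- cbind(a = x, b = -x, u = z1, v = z2, a2 = x)
  b <- filter_correlated(mk_block(vals, feats = colnames(vals)), r = 0.95)
  # a survives; b (sign flip, |r| = 1) and a2 (duplicate) are later -> dropped
  expect_equal(b$feature_names, c("a", "u", "v"))
  # survivors pairwise below the threshold
  cm <- abs(cor(b$values))
  expect_true(all(cm[upper.tri(cm)] <= 0.95))

  const <- cbind(c = rep(1, 10), d = rnorm(10))
  expect_error(filter_correlated(mk_block(const, feats = colnames(const))),
               "constant")
})

test_that("constant-then-correlation filtering is idempotent", {
  for (seed in 1:3) {
    sim <- generate(synthetic_spec(n_compounds = 40, p_md = 20, seed = seed))
    md <- sim$dataset$blocks[[1]]
    f1 <- filter_correlated(filter_constant(md))
    f2 <- filter_correlated(filter_constant(f1))
    expect_equal(f2$feature_names, f1$feature_names)
  }
})

test_that("fuse intersects compounds, prefixes genes, and indexes features", {
  md <- mk_block(matrix(1:9, 3), ids = c("c1", "c2", "c3"))
  g <- mk_block(matrix(rnorm(8), 4), kind = "GENE", label = "MCF7",
                ids = c("c2", "c3", "c4", "c5"), feats = c("ENSG1", "ENSG2"))
  resp <- stats::setNames(1:4, c("c1", "c2", "c3", "c4"))
  d <- fuse(md, list(g), resp)
  expect_equal(compound_ids(d), c("c2", "c3"))
  expect_equal(d$feature_index$feature,
               c("f1", "f2", "f3", "MCF7_ENSG1", "MCF7_ENSG2"))
  expect_equal(unname(d$response), c(2, 3))

  # width additivity: 5 + 10 + 10 = 25
  md5 <- mk_block(matrix(rnorm(15), 3), ids = c("c1", "c2", "c3"))
  g10a <- mk_block(matrix(rnorm(30), 3), "GENE", "MCF7", ids = c("c1", "c2", "c3"))
  g10b <- mk_block(matrix(rnorm(30), 3), "GENE", "PC3", ids = c("c1", "c2", "c3"))
  d25 <- fuse(md5, list(g10a, g10b), stats::setNames(1:3, c("c1", "c2", "c3")))
  expect_equal(nrow(d25$feature_index), 25L)
  expect_equal(ncol(design_matrix(d25)), 25L)

  # feature name -> column lookup is a bijection onto surviving columns
  X <- design_matrix(d25)
  expect_equal(colnames(X), d25$feature_index$feature)
  expect_false(anyDuplicated(d25$feature_index$feature) > 0)

  expect_error(fuse(md, list(), stats::setNames(1, "zz")), "no compounds shared")
})

test_that("subset_view isolates one block family", {
  d <- mk_fused(n = 12)
  md_only <- subset_view(d, "MD")
  moa_only <- subset_view(d, "MOA")
  expect_true(all(md_only$feature_index$block_kind == "MD"))
  expect_true(all(moa_only$feature_index$block_kind == "GENE"))
  expect_equal(ncol(design_matrix(md_only)) + ncol(design_matrix(moa_only)),
               ncol(design_matrix(d)))
})
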
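# Grid search, eligibility, final-model choice, single-view comparison.

fake_candidate <- function(grid_index, mse = 0.1, n_features = 5,
                           ad_train = 100, ad_test = 100, r2 = 0.9,
                           ccc = 0.9, eligible = NA) {
  list(grid_index = grid_index, alpha = 1, gamma = 1, lambda = 0.1,
       model = NULL, n_features = n_features, eligible = eligible,
       validation = list(r2_train = r2, q2_l10o = r2, r2_test = r2,
                         q2_f1 = r2, q2_f2 = r2, q2_f3 = r2,
                         ccc_test = ccc, mse = mse),
       ad = list(coverage = list(AD_Train = ad_train, AD_Test = ad_test)))
}

test_that("grid_search emits one candidate per cell", {
  d <- mk_fused(n = 24, p_md = 4, p_gene = 3, seed = 4)
  g <- grid_search(d, alpha_grid = c(0.5, 1), gamma_grid = c(1, 2),
                   n_splits = 3, validation = "basic", seed = 1)
  expect_length(g$candidates, 4)
  tab <- candidates_table(g)
  expect_equal(tab$grid_index, 1:4)
  expect_equal(tab$alpha, c(0.5, 0.5, 1, 1))  # alpha-major ordering
  expect_equal(tab$gamma, c(1, 2, 1, 2))
  # outer 80/20 split on 24 compounds
  expect_length(g$outer_split$train_ids, sum(ceiling(table(
    qsmartr:::bin_response(d$response, g$outer_split$bin_edges)) * 0.8)))
})

test_that("apply_eligibility enforces thresholds and full test coverage", {
  cands <- list(
    fake_candidate(1),                      # passes everything
    fake_candidate(2, r2 = 0.5),            # fails the 0.6 thresholds
    fake_candidate(3, ad_test = 90),        # fails AD_Test = 100
    fake_candidate(4, ccc = 0.5)            # low CCC: non-blocking by default
  )
  out <- apply_eligibility(cands)
  expect_equal(vapply(out, `[[`, TRUE, "eligible"), c(TRUE, FALSE, FALSE, TRUE))
  strict <- apply_eligibility(cands, eligibility_criteria(ccc_blocking = TRUE))
  expect_false(strict[[4]]$eligible)
  # empty models are never eligible
  empty <- fake_candidate(5); empty$n_features <- 0L; empty$validation <- NULL
  expect_false(apply_eligibility(list(empty))[[1]]$eligible)
})

test_that("select_final ranks by error, parsimony, AD_Train, grid index", {
  cands <- apply_eligibility(list(
    fake_candidate(1, mse = 0.2, n_features = 6),
    fake_candidate(2, mse = 0.1, n_features = 9, ad_train = 100),
    fake_candidate(3, mse = 0.1, n_features = 6, ad_train = 90),
    fake_candidate(4, mse = 0.1, n_features = 6, ad_train = 100)
  ))
  sel <- select_final(cands)
  # equal error: fewer features beat more; wider AD_Train beats narrower
  expect_equal(sel$final$grid_index, 4)
  expect_equal(sel$ranking$grid_index, c(4, 3, 2, 1))
  # invariant to input order
  sel2 <- select_final(rev(cands))
  expect_equal(sel2$final$grid_index, 4)
  # grid-index tiebreak when everything else is equal
  sel3 <- select_final(apply_eligibility(list(fake_candidate(7),
                                              fake_candidate(2))))
  expect_equal(sel3$final$grid_index, 2)
  expect_error(select_final(list(fake_candidate(1, r2 = 0))), "no eligible")
})

test_that("restricting the grid to the winning cell reproduces the model", {
  sim <- generate(synthetic_spec(n_compounds = 60, p_md = 20, p_gene = 15,
                                 seed = 3))
  g <- grid_search(sim$dataset, alpha_grid = c(1, 1.25), gamma_grid = c(1.5, 1.75),
                   n_splits = 5, validation = "basic", seed = 11)
  tab <- candidates_table(g)
  win <- tab[which.min(tab$mse), ]
  g2 <- grid_search(sim$dataset, alpha_grid = win$alpha, gamma_grid = win$gamma,
                    n_splits = 5, validation = "basic", seed = 11)
  m1 <- g$candidates[[win$grid_index]]$model
  m2 <- g2$candidates[[1]]$model
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$lambda, m2$lambda)
})

test_that("single-view runs cover one block family with 9 cells", {
  sim <- generate(synthetic_spec(n_compounds = 50, p_md = 15, p_gene = 10,
                                 seed = 6))
  md <- compare_single_view(sim$dataset, "MD", n_splits = 3,
                            validation = "basic", seed = 2)
  expect_length(md$candidates, 9)
  feats <- unlist(lapply(md$candidates, function(cand) names(cand$model$coefficients)))
  expect_true(all(grepl("^MD", feats)))

  moa <- compare_single_view(sim$dataset, "MOA", n_splits = 3,
                             validation = "basic", seed = 2)
  expect_length(moa$candidates, 9)
  feats_moa <- unlist(lapply(moa$candidates,
                             function(cand) names(cand$model$coefficients)))
  expect_true(all(grepl("^(MCF7|PC3)_", feats_moa)))
})

test_that("a gene-only view of pure noise yields mostly empty or weak models", {
  d <- generate_null(synthetic_spec(n_compounds = 40, p_md = 10, p_gene = 15,
                                    seed = 21))
  moa <- compare_single_view(d, "MOA", n_splits = 3, validation = "basic",
                             seed = 5)
  tab <- candidates_table(moa)
  # under the null no cell should look externally predictive
  expect_true(all(is.na(tab$q2_f2) | tab$q2_f2 < 0.6))
})

test_that("the integrated model beats single views on cross-block signal", {
  sim <- generate(synthetic_spec(n_compounds = 80, p_md = 20, p_gene = 15,
                                 seed = 9, noise_sd = 0.1))
  grids <- list(
    both = grid_search(sim$dataset, alpha_grid = 1.25, gamma_grid = 1.75,
                       n_splits = 5, validation = "basic", seed = 4),
    md = compare_single_view(sim$dataset, "MD", grid = 1.25, n_splits = 5,
                             validation = "basic", seed = 4),
    moa = compare_single_view(sim$dataset, "MOA", grid = 1.75, n_splits = 5,
                              validation = "basic", seed = 4)
  )
  mses <- vapply(grids, function(g) min(candidates_table(g)$mse, na.rm = TRUE),
                 numeric(1))
  expect_lt(mses["both"], mses["md"])
  expect_lt(mses["both"], mses["moa"])
})
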
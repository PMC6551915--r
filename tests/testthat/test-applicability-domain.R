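# Leverage, warning leverage, Williams, standardization, distance, kNN,
# consensus and Insubria classification.

test_that("leverage matches the closed form on the intercept + x design", {
  x <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "x"))
  h <- leverage(x)
  # h_i = 1/3 + x_i^2 / 2
  expect_equal(h, c(5 / 6, 1 / 3, 5 / 6))
  expect_equal(sum(h), 2)  # trace of the hat matrix = p' = 2
  # a query at the training centroid has h = 1/n
  centroid <- matrix(mean(x), 1, 1, dimnames = list(NULL, "x"))
  expect_equal(leverage(x, centroid), 1 / 3)

  rank_def <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_error(leverage(rank_def), "rank deficient")
})

test_that("critical_hat is 3(k+1)/n", {
  expect_equal(critical_hat(6, 48), 0.4375)
  expect_equal(critical_hat(1, 6), 1.0)
  expect_equal(critical_hat(4, 20), 2 * critical_hat(4, 40))
})

test_that("williams flags use strict boundaries", {
  w <- williams(std_residuals = c(3.1, 3.0, 0), leverages = c(0.1, 0.5, 0.5),
                h_star = 0.5, sigma_limit = 3)
  expect_equal(w$response_outlier, c(TRUE, FALSE, FALSE))
  expect_equal(w$high_leverage, c(FALSE, FALSE, FALSE))  # h = h* not flagged
  expect_equal(w$in_domain, c(FALSE, TRUE, TRUE))
})

test_that("standardization AD uses the three-sigma rule with strict exceedance", {
  withr::local_seed(2)
  train <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  mu <- colMeans(train); sdev <- apply(train, 2, sd)
  inside <- matrix(mu, 1, dimnames = list(NULL, c("a", "b")))
  at3 <- matrix(mu + 3 * sdev, 1, dimnames = list(NULL, c("a", "b")))
  out <- matrix(c(mu[1] + 4 * sdev[1], mu[2]), 1,
                dimnames = list(NULL, c("a", "b")))
  res <- standardization_ad(train, rbind(inside, at3, out))
  expect_equal(res$in_domain, c(TRUE, TRUE, FALSE))

  const <- cbind(a = rep(1, 5), b = rnorm(5))
  expect_error(standardization_ad(const, const), "zero-SD")
})

test_that("distance AD thresholds at the farthest training compound", {
  train <- rbind(c(0, 0), c(0, 2)); colnames(train) <- c("x", "y")
  # centroid (0, 1); both training points at distance 1
  eu <- distance_ad(train, rbind(c(0, 3), c(0, 1)), "euclidean")
  expect_equal(eu$threshold, 1)
  expect_equal(eu$table$distance, c(2, 0))
  expect_equal(eu$table$in_domain, c(FALSE, TRUE))
  cb <- distance_ad(train, matrix(c(1, 1), 1), "cityblock")
  expect_equal(cb$threshold, 1)
  expect_equal(cb$table$in_domain, TRUE)  # L1 distance exactly 1: strict >
  # training compounds are inside by construction
  tr_check <- distance_ad(train, train, "euclidean")
  expect_true(all(tr_check$table$in_domain))
})

test_that("kNN AD on four collinear equispaced points has threshold 2s", {
  train <- matrix(0:3, 4, 1, dimnames = list(NULL, "x"))
  res <- knn_ad(train, train, k = 3)
  # training scores exclude self: end points mean(1, 2, 3) = 2, middle
  # points mean(1, 1, 2) = 4/3 -> threshold 2 (twice the spacing)
  expect_equal(res$threshold, 2)
  # query scores (here: the training points themselves) include the exact
  # self match at distance zero
  expect_equal(res$table$knn_distance, c(1, 2 / 3, 2 / 3, 1))
  expect_true(all(res$table$in_domain))
  far <- matrix(10, 1, 1, dimnames = list(NULL, "x"))
  expect_false(knn_ad(train, far, 3)$table$in_domain)
  dup <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  expect_true(knn_ad(train, dup, 3)$table$in_domain)
  expect_error(knn_ad(train[1:3, , drop = FALSE], train, 3), "more than k")
})

test_that("consensus averages binary votes with an inclusive 0.5 rule", {
  flags <- cbind(a = c(TRUE, TRUE, TRUE, FALSE),
                 b = c(TRUE, TRUE, FALSE, FALSE),
                 c = c(TRUE, TRUE, TRUE, FALSE),
                 d = c(TRUE, FALSE, TRUE, FALSE),
                 e = c(TRUE, FALSE, FALSE, FALSE))
  res <- consensus_ad(flags)
  expect_equal(res$score, c(1, 0.6, 0.6, 0))
  expect_equal(res$in_domain, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$coverage, 75)
  # train-style 1/2 vote is inside (score >= 0.5)
  tr <- consensus_ad(cbind(leverage = TRUE, standardization = FALSE))
  expect_true(tr$in_domain)
  expect_equal(tr$score, 0.5)
  expect_error(consensus_ad(cbind(a = c(TRUE, NA))), "missing")
  # monotonicity: an always-inside method can only raise scores
  res2 <- consensus_ad(cbind(flags, always = TRUE))
  expect_true(all(res2$score >= res$score - 1e-12))
})

test_that("insubria separates leverage and response-range verdicts", {
  out <- insubria(leverages = c(0.2, 0.5, 0.7), predictions = c(1, 5, 2),
                  h_star = 0.5, prediction_range = c(0, 4))
  expect_equal(out$extrapolated, c(FALSE, FALSE, TRUE))  # h = h* interpolated
  expect_equal(out$out_of_range, c(FALSE, TRUE, FALSE))
  # absent range leaves the response flag NA
  expect_true(all(is.na(insubria(0.1, 1, 0.5)$out_of_range)))
})

test_that("full AD report satisfies its structural invariants", {
  d <- mk_fused(n = 40, seed = 9, noise = 0.2)
  split <- stratified_split(d$response, 0.8, seed = 3)
  m <- fit_qsmart(d, power_params(1, 1), 0.02, ids = split$train_ids)
  ad <- compute_ad_report(m, d, split$train_ids, split$holdout_ids)
  tr <- ad$per_compound[ad$per_compound$role == "train", ]
  # training leverages sum to the number of design columns (features + 1)
  expect_equal(sum(tr$h), length(m$coefficients) + 1, tolerance = 1e-8)
  expect_equal(ad$thresholds$h_star,
               3 * mean(tr$h))
  # every training compound inside the distance-based domains
  expect_true(all(tr$in_euclid & tr$in_city & tr$in_knn))
  expect_true(all(ad$per_compound$consensus_score >= 0 &
                    ad$per_compound$consensus_score <= 1))
  expect_true(ad$coverage$AD_Train >= 0 && ad$coverage$AD_Train <= 100)
  expect_true(ad$coverage$AD_Test >= 0 && ad$coverage$AD_Test <= 100)
})
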
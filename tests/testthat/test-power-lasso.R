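# Power transform, penalty path, coordinate-descent lasso, prediction.

test_that("power_transform applies block-wise |x|^exponent", {
  d <- mk_fused(n = 10)
  X <- design_matrix(d)
  Z <- power_transform(d, power_params(2, 0.5))
  md_cols <- d$feature_index$block_kind == "MD"
  expect_equal(Z[, md_cols], abs(X[, md_cols])^2)
  expect_equal(Z[, !md_cols], abs(X[, !md_cols])^0.5)
  # alpha = gamma = 1 is exactly |X|
  expect_identical(power_transform(d, power_params(1, 1)), abs(X))
  # zero maps to zero for small positive exponents
  d$blocks[[1]]$values[1, 1] <- 0
  expect_equal(power_transform(d, power_params(0.1, 1))[1, 1], 0)
  expect_error(power_params(0, 1), "strictly positive")
  expect_error(power_params(1, -2), "strictly positive")
})

test_that("lambda_path spans lambda_max down three decades and zeroes the fit", {
  withr::local_seed(4)
  X <- matrix(rnorm(40), 10); colnames(X) <- paste0("f", 1:4)
  y <- rnorm(10)
  p <- lambda_path(X, y, 100)
  expect_length(p, 100)
  expect_true(all(diff(p) < 0))
  expect_equal(p[100], p[1] * 1e-3, tolerance = 1e-12)
  # KKT entry condition: the first path point gives the all-zero fit
  f <- fit_lasso(X, y, p[1])
  expect_length(f$coefficients, 0)
  expect_equal(f$intercept, mean(y))
  # just below lambda_max at least one coefficient enters
  f2 <- fit_lasso(X, y, p[1] * 0.99)
  expect_gt(length(f2$coefficients), 0)

  # single standardized feature equal to y, n = 4
  y4 <- c(-1, 0, 1, 2)
  X4 <- matrix(y4, dimnames = list(NULL, "s"))
  p4 <- lambda_path(X4, y4, 10)
  expect_length(fit_lasso(X4, y4, p4[1])$coefficients, 0)

  expect_error(lambda_path(X, rep(1, 10)), "zero variance")
})

test_that("lambda = 0 reproduces ordinary least squares", {
  withr::local_seed(7)
  n <- 10
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(n, sd = 0.3)
  f <- fit_lasso(X, y, 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(c(f$intercept, f$beta)), ols, tolerance = 1e-6)
})

test_that("every fit satisfies the KKT subgradient conditions", {
  # |x_j' r| <= n * lambda for zero coefficients; = n * lambda with matching
  # sign for nonzero ones (standardized columns; s = n is the objective's
  # lambda scaling)
  for (seed in 1:5) {
    withr::local_seed(seed)
    n <- 40; p <- 12
    X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("f", seq_len(p))
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.5)
    lam <- lambda_path(X, y, 50)[25]
    f <- fit_lasso(X, y, lam)
    st <- qsmartr:::standardize_columns(X)
    beta_std <- f$beta * st$scale
    r <- (y - mean(y)) - st$X %*% beta_std
    g <- as.numeric(crossprod(st$X, r)) / n
    tol <- 1e-5
    expect_true(all(abs(g[beta_std == 0]) <= lam + tol))
    nz <- beta_std != 0
    expect_equal(unname(g[nz]), lam * unname(sign(beta_std[nz])),
                 tolerance = 1e-4)
  }
})

test_that("solution matches glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  withr::local_seed(12)
  X <- matrix(rnorm(300), 100); colnames(X) <- paste0("f", 1:3)
  y <- 0.5 + X[, 1] + rnorm(100, sd = 0.3)
  for (lam in lambda_path(X, y, 10)[c(3, 6, 9)]) {
    fg <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE, thresh = 1e-14)
    fo <- fit_lasso(X, y, lam)
    expect_equal(c(fo$intercept, unname(fo$beta)),
                 c(fg$a0, as.numeric(fg$beta)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("objective at the solution beats the null and OLS references", {
  withr::local_seed(3)
  n <- 30
  X <- matrix(rnorm(n * 3), n); colnames(X) <- paste0("f", 1:3)
  y <- X[, 1] + rnorm(n, sd = 0.2)
  obj <- function(b0, b, lam) {
    mean((y - b0 - X %*% b)^2) / 2 + lam * sum(abs(b))
  }
  lam <- 0.05
  f <- fit_lasso(X, y, lam)
  expect_lte(obj(f$intercept, f$beta, lam), obj(mean(y), rep(0, 3), lam))
  ols <- coef(lm(y ~ X))
  expect_lte(obj(f$intercept, f$beta, lam), obj(ols[1], ols[-1], lam))
})

test_that("active-set size grows (weakly) as the penalty decreases", {
  withr::local_seed(9)
  X <- matrix(rnorm(50 * 8), 50); colnames(X) <- paste0("f", 1:8)
  y <- X[, 1] - X[, 2] + rnorm(50, sd = 0.3)
  path <- lambda_path(X, y, 40)
  fp <- qsmartr:::lasso_path_fit(X, y, path)
  nnz <- colSums(fp$beta != 0)
  # minor local violations are tolerated; the trend must be monotone
  expect_equal(nnz[1], 0)
  expect_lte(sum(pmax(-diff(nnz), 0)), 1)
  expect_gte(nnz[40], nnz[1])
})

test_that("select_lambda minimizes validation MSE and breaks ties upward", {
  withr::local_seed(21)
  n <- 60
  ids <- sprintf("c%02d", 1:n)
  X <- matrix(rnorm(n * 5), n, dimnames = list(ids, paste0("f", 1:5)))
  y <- stats::setNames(2 * X[, 1] - X[, 3] + rnorm(n, sd = 1e-4), ids)
  path <- lambda_path(X, y, 30)
  splits <- make_rsva_splits(y, 5, 0.9, base_seed = 2)
  sel <- select_lambda(X, y, path, splits)
  # near-noiseless truth: the optimum sits in the small-penalty tail
  expect_gte(sel$index, 25)
  # explicit tie goes to the larger penalty (earlier index)
  mse <- c(5, 3, 3, 4)
  expect_equal(which.min(mse), 2L)
})

test_that("prediction applies the stored exponents and flags missing features", {
  m <- qsmart_model(intercept = 1, coefficients = c(f = 2),
                    alpha = 1, gamma = 1, feature_kinds = c(f = "MD"))
  X <- matrix(-3, 1, 1, dimnames = list("q", "f"))
  expect_equal(unname(predict(m, X)), 1 + 2 * 3)  # |−3|^1 * 2
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "f"))
  expect_equal(unname(predict(m, zero)), c(1, 1))
  bad <- matrix(1, 1, 1, dimnames = list("q", "other"))
  expect_error(predict(m, bad), "missing model feature.*f")

  # round-trip: training predictions reproduce stored fitted values
  d <- mk_fused(n = 25, seed = 5)
  fm <- fit_qsmart(d, power_params(1.5, 0.75), 0.01)
  expect_equal(predict(fm, d), fm$fitted, tolerance = 1e-12)
})

test_that("model JSON serialization round-trips bit-identically", {
  d <- mk_fused(n = 20, seed = 8)
  m <- fit_qsmart(d, power_params(1.25, 1.75), 0.05, name = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  write_qsmart_model(m, path)
  m2 <- read_qsmart_model(path)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$alpha, m$alpha)
  expect_identical(m2$gamma, m$gamma)
  expect_identical(m2$lambda, m$lambda)
  expect_identical(m2$training_ids, m$training_ids)
})
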
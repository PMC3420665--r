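test_that("ridge(0), PCR(rank) and PLS(rank) all reproduce OLS fitted values", {
  for (seed in 1:4) {
    pr <- rand_problem(40, 6, seed)
    ols <- ols_fitted(pr$X, pr$y)
    for (cfg in list(list(method = "RR", lambda = 0),
                     list(method = "PCR", k = 6),
                     list(method = "PLS", k = 6))) {
      fit <- do.call(rvfit, c(list(x = pr$X, y = pr$y), cfg))
      expect_equal(unname(fitted(fit)), ols, tolerance = 1e-8)
    }
  }
})

test_that("single-column designs reduce to simple linear regression", {
  pr <- rand_problem(30, 1, 7)
  ols <- ols_fitted(pr$X, pr$y)
  expect_equal(unname(fitted(rvfit(pr$X, pr$y, "PCR", k = 1))), ols,
               tolerance = 1e-10)
  expect_equal(unname(fitted(rvfit(pr$X, pr$y, "PLS", k = 1))), ols,
               tolerance = 1e-10)
})

test_that("ridge shrinkage follows the closed form d^2/(d^2 + lambda)", {
  # centered single column [1, -1], y = [2, 0], lambda = 2:
  # d^2 = 2, shrink = 1/2, yhat = ybar + u u'yc / 2 = [1.5, 0.5]
  X <- cbind(c(1, -1))
  fit <- rvfit(X, c(2, 0), "RR", lambda = 2)
  expect_equal(unname(fitted(fit)), c(1.5, 0.5), tolerance = 1e-12)
})

test_that("large ridge penalties collapse the fit toward the mean", {
  pr <- rand_problem(60, 8, 3)
  f0 <- rvfit(pr$X, pr$y, "RR", lambda = 0)
  fbig <- rvfit(pr$X, pr$y, "RR", lambda = 1e12)
  expect_lt(max(abs(fitted(fbig) - mean(pr$y))), 1e-8)
  # OLS maximizes the training correlation over all linear fits
  expect_lte(fbig$fit_statistic, f0$fit_statistic + 1e-12)
})

test_that("PCR one-component fit matches the explicit SVD oracle", {
  # columns [1,-1] and [1,1]; centering zeroes the second column, so the
  # rank-1 fit lies along u1 = [1,-1]/sqrt(2) and reproduces y = [2, 0]
  X <- cbind(c(1, -1), c(1, 1))
  fit <- rvfit(X, c(2, 0), "PCR", k = 1)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  u1 <- sv$u[, 1]
  oracle <- mean(c(2, 0)) + u1 * sum(u1 * c(1, -1))
  expect_equal(unname(fitted(fit)), oracle, tolerance = 1e-12)
  expect_equal(unname(fitted(fit)), c(2, 0), tolerance = 1e-12)
})

test_that("component-count rule matches a brute-force R-squared sweep", {
  pr <- rand_problem(50, 5, 9)
  # y exactly in the span of the first principal component -> k = 1
  Xc <- sweep(pr$X, 2, colMeans(pr$X))
  sv <- svd(Xc)
  y1 <- 2 + 3 * sv$u[, 1]
  expect_equal(choose_k(pr$X, y1, "compk", theta = 0.99), 1L)
  # theta -> 1 recovers the full rank
  expect_equal(choose_k(pr$X, pr$y, "compk", theta = 1 - 1e-12), 5L)
  expect_equal(choose_k(pr$X, pr$y, "one"), 1L)

  # two-equal-signal design: exhaustive sweep over k with lm() as oracle
  set.seed(12)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- X[, 1] + X[, 2] + 0.2 * rnorm(80)
  theta <- 0.8
  r2 <- vapply(1:6, function(k) {
    Z <- sweep(X, 2, colMeans(X)) %*% svd(sweep(X, 2, colMeans(X)))$v[, 1:k]
    summary(stats::lm(y ~ Z))$r.squared
  }, numeric(1))
  oracle_k <- which(r2 >= theta * r2[6])[1]
  expect_equal(choose_k(X, y, "compk", theta = theta, method = "PCR"),
               oracle_k)
})

test_that("the first PLS weight vector is proportional to X'y", {
  set.seed(15)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  Xc <- sweep(X, 2, colMeans(X))
  core <- rvreg:::.pls_core(Xc, y - mean(y), k_max = 3)
  w1 <- core$W[, 1]
  target <- drop(crossprod(Xc, y - mean(y)))
  expect_equal(w1 / sqrt(sum(w1^2)), target / sqrt(sum(target^2)),
               tolerance = 1e-12)
})

test_that("PLS returns a null fit when X'y is exactly zero", {
  # y orthogonal to every centered column
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  y <- c(1, 1, 1, 1)
  fit <- rvfit(X, y, "PLS")
  expect_equal(fit$fit_statistic, 0)
  expect_equal(unname(fitted(fit)), rep(1, 4))
})

test_that("LASSO gives the empty model at lambda >= lambda_max", {
  pr <- rand_problem(50, 8, 20)
  Xc <- sweep(pr$X, 2, colMeans(pr$X))
  yc <- pr$y - mean(pr$y)
  lmax <- max(abs(crossprod(Xc, yc))) / 50
  for (crit in c("AIC", "BIC", "GIC")) {
    f <- rvreg:::.fit_lasso(Xc, yc, criterion = crit)
    # the path starts exactly at lambda_max: that entry must be empty
    path <- rvreg:::.lasso_path(Xc, yc)
    expect_equal(path[1], lmax, tolerance = 1e-10)
    gfit <- glmnet::glmnet(Xc, yc, lambda = lmax * c(1.5, 1),
                           standardize = FALSE, intercept = FALSE)
    expect_true(all(as.matrix(gfit$beta) == 0))
  }
})

test_that("orthonormal designs soft-threshold and match exhaustive IC search", {
  Q <- orthonormal_design(40, 5, 18)
  set.seed(19)
  y <- Q %*% c(2, -1.2, 0.6, 0, 0) + rnorm(40, sd = 0.4)
  yc <- drop(y - mean(y))
  n <- 40
  path <- rvreg:::.lasso_path(Q, yc)
  # closed form: beta_j(lambda) = S(q_j' y, n lambda) (since Q'Q = I)
  b_ols <- drop(crossprod(Q, yc))
  B_oracle <- vapply(path, function(l)
    sign(b_ols) * pmax(0, abs(b_ols) - n * l), numeric(5))
  gfit <- glmnet::glmnet(Q, yc, lambda = path, standardize = FALSE,
                         intercept = FALSE)
  expect_equal(as.matrix(gfit$beta), B_oracle, tolerance = 1e-4,
               ignore_attr = TRUE)
  # IC minimizer agrees with exhaustive evaluation on the oracle path
  for (crit in c("AIC", "BIC")) {
    ic_oracle <- vapply(seq_along(path), function(i) {
      rss <- sum((yc - Q %*% B_oracle[, i])^2)
      information_criterion(rss, n, sum(B_oracle[, i] != 0), crit, p = 5)
    }, numeric(1))
    f <- rvreg:::.fit_lasso(Q, yc, criterion = crit)
    expect_equal(f$hyperparams$lambda, path[which.min(ic_oracle)],
                 tolerance = 1e-8)
  }
})

test_that("BIC-selected LASSO recovers one strong predictor", {
  hits <- 0L
  set.seed(22)
  for (r in 1:200) {
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- 2 * X[, 4] + rnorm(200, sd = 0.5)
    Xc <- sweep(X, 2, colMeans(X))
    f <- rvreg:::.fit_lasso(Xc, y - mean(y), criterion = "BIC")
    hits <- hits + (4L %in% f$selected)
  }
  expect_gt(hits / 200, 0.95)
})

test_that("KKT conditions hold at the IC-selected lambda", {
  for (seed in 1:5) {
    pr <- rand_problem(80, 15, 100 + seed, signal = 1.2)
    Xc <- sweep(pr$X, 2, colMeans(pr$X))
    yc <- pr$y - mean(pr$y)
    f <- rvreg:::.fit_lasso(Xc, yc, criterion = "AIC")
    r <- yc - Xc %*% f$beta
    g <- abs(crossprod(Xc, r)) / 80
    expect_true(all(g <= f$hyperparams$lambda + 1e-8))
  }
})

test_that("SPLS with eta = 0 reproduces plain PLS", {
  pr <- rand_problem(60, 6, 33)
  Xc <- sweep(pr$X, 2, colMeans(pr$X))
  yc <- pr$y - mean(pr$y)
  sp <- rvreg:::.fit_spls(Xc, yc, K_max = 4, eta_grid = 0, criterion = "BIC")
  expect_equal(sort(sp$selected), 1:6)      # all variables active
  pls <- rvreg:::.fit_pls_top(Xc, yc, k = sp$hyperparams$K)
  expect_equal(sp$fitted_c, pls$fitted_c, tolerance = 1e-8)
  expect_equal(sp$beta, pls$beta, tolerance = 1e-8)
})

test_that("SPLS thresholding keeps only dominant loadings as eta -> 1", {
  # 5 variables; variable 2 dominates X'y by construction
  set.seed(35)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- 3 * X[, 2] + rnorm(100, sd = 0.3)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  w <- abs(drop(crossprod(Xc, yc)))
  expect_equal(which.max(w), 2L)
  sets <- rvreg:::.spls_active_sets(Xc, yc, K_max = 1, eta = 0.9)
  expect_equal(sets[[1]], 2L)               # brute-force: only the max survives
  fit <- rvfit(X, y, "SPLS", eta_grid = 0.9, K_max = 1)
  expect_equal(unname(fit$selected), 2L)
})

test_that("information criteria match their plug-in values", {
  expect_equal(information_criterion(100, 100, 3, "AIC"), 6)
  expect_equal(information_criterion(100, 100, 3, "BIC"), 3 * log(100))
  expect_equal(information_criterion(100, 100, 3, "GIC", p = 50),
               3 * log(log(100)) * log(50))
  expect_identical(information_criterion(0, 100, 3, "AIC"), -Inf)
  expect_error(information_criterion(100, 100, 3, "GIC"), "needs p")
})

test_that("post-selection F-test matches the F(2, 7) worked case", {
  expect_equal(as.numeric(post_selection_f_pvalue(matrix(rnorm(20), 10),
                                                  rnorm(10), integer(0))), 1)
  # construct y with R-squared exactly 0.5 on 2 selected columns, n = 10
  set.seed(41)
  X <- matrix(rnorm(20), 10, 2)
  f0 <- stats::lm(X[, 1] + X[, 2] ~ X)
  u <- fitted(f0) - mean(fitted(f0))
  u <- u / sqrt(sum(u^2))
  v <- residuals(stats::lm(rnorm(10) ~ X))
  v <- v / sqrt(sum(v^2))
  y <- 3 + u + v
  p <- post_selection_f_pvalue(X, y, 1:2)
  expect_equal(as.numeric(p), stats::pf(3.5, 2, 7, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(as.numeric(p), 0.0885, tolerance = 2e-3)

  # exact fit: machine-minimum p with the degeneracy flag raised
  yexact <- 1 + 2 * X[, 1]
  pe <- post_selection_f_pvalue(X, yexact, 1L)
  expect_equal(as.numeric(pe), .Machine$double.xmin)
  expect_true(attr(pe, "degenerate"))
})

test_that("model-fit accessors are coherent", {
  pr <- rand_problem(50, 6, 55)
  fit <- rvfit(pr$X, pr$y, "RR", lambda = 10)
  expect_equal(unname(predict(fit, pr$X)), unname(fitted(fit)),
               tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), unname(pr$y - fitted(fit)))
  cf <- coef(fit)
  manual <- cf[1] + pr$X %*% cf[-1]
  expect_equal(drop(manual), unname(fitted(fit)), tolerance = 1e-10,
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.rvfit")
  expect_equal(s$n_selected, 6L)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(50L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 9))
})
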
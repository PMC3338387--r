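test_that("lasso_solve matches closed forms and certifies KKT", {
  set.seed(20)
  n <- 100
  # null-model threshold: above lambda_max everything is zero
  X <- matrix(rnorm(n * 10), n)
  y <- rnorm(n)
  std <- vbnetrec:::std_cols(X)
  lmax <- max(abs(crossprod(std$x, y - mean(y)))) / n
  f0 <- lasso_solve(y, X, lmax * 1.01)
  expect_equal(unname(f0$beta[, 1]), rep(0, 10))

  # single standardized predictor: soft threshold in closed form
  x1 <- as.numeric(scale(rnorm(n)))
  x1 <- x1 / sqrt(mean(x1^2))
  f1 <- lasso_solve(y, matrix(x1), 0.15)
  st <- mean(x1 * (y - mean(y)))
  st <- sign(st) * max(0, abs(st) - 0.15)
  expect_equal(f1$beta_std[1, 1], st, tolerance = 1e-8)

  # lambda = 0 on full-rank design: OLS
  Xs <- matrix(rnorm(40 * 5), 40)
  ys <- rnorm(40)
  fo <- lasso_solve(ys, Xs, 0)
  ols <- coef(lm(ys ~ Xs))[-1]
  expect_equal(unname(fo$beta[, 1]), unname(ols), tolerance = 1e-6)

  # KKT certification across random problems and penalty factors
  for (i in 1:10) {
    Xr <- matrix(rnorm(60 * 25), 60)
    yr <- drop(Xr[, 1:2] %*% c(2, -1)) + rnorm(60)
    pf <- ifelse(runif(25) < 0.2, Inf, runif(25, 0.5, 2))
    fr <- lasso_solve(yr, Xr, c(0.5, 0.1, 0.01), penalty_factor = pf)
    expect_lt(max(fr$kkt), 1e-6)
    expect_true(all(fr$beta[!is.finite(pf), ] == 0))
  }
})

test_that("lasso path agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 150; P <- 40
  X <- matrix(rnorm(n * P), n)
  y <- drop(X[, 1:3] %*% c(1.5, -1, 0.5)) + rnorm(n)
  lam <- c(0.6, 0.3, 0.1, 0.05, 0.01)
  mine <- lasso_solve(y, X, lam)
  ref <- glmnet::glmnet(X, y, lambda = lam, thresh = 1e-14)
  expect_equal(unname(as.matrix(mine$beta)),
               unname(as.matrix(ref$beta)), tolerance = 1e-5)
})

test_that("mb_penalty implements the quantile formula", {
  # oracle: direct quantile evaluation
  expect_equal(mb_penalty(0.05, 300, 1000, 1),
               2 / sqrt(300) * qnorm(0.05 / (2 * 1000^2),
                                     lower.tail = FALSE))
  # monotonicity in alpha, linearity in sigma_hat
  expect_gt(mb_penalty(0.025, 300, 1000, 1),
            mb_penalty(0.05, 300, 1000, 1))
  expect_equal(mb_penalty(0.05, 300, 1000, 2),
               2 * mb_penalty(0.05, 300, 1000, 1))
  expect_error(mb_penalty(0, 300, 10, 1), "alpha")
  expect_error(mb_penalty(1.5, 300, 10, 1), "alpha")
})

test_that("MB bound controls null false positives and nests", {
  fps <- numeric(5)
  for (s in 1:5) {
    net <- simulate_network(80, 150, 0, seed = s + 300)
    fps[s] <- nrow(bound_via_mb_penalty(net$Y, 1)$edges)
  }
  expect_lte(mean(fps), 1)
  # larger bound selects a superset per response
  net <- simulate_network(60, 150, 1 / 60, seed = 77)
  e1 <- bound_via_mb_penalty(net$Y, 1)$edges
  e1000 <- bound_via_mb_penalty(net$Y, 1000)$edges
  k <- function(e) (e[, 1] - 1) * 60 + e[, 2]
  expect_true(all(k(e1) %in% k(e1000)))
})

test_that("randomized lasso reduces to plain lasso at unit weights", {
  set.seed(22)
  X <- matrix(rnorm(100 * 15), 100)
  y <- drop(X[, 1] * 2) + rnorm(100)
  plain <- lasso_solve(y, X, 0.2)$active[[1]]
  rl <- lasso_solve(y, X, 0.2, penalty_factor = rep(1, 15))$active[[1]]
  expect_identical(plain, rl)
  # determinism under a fixed seed
  a1 <- randomized_lasso(y, X, 0.2, seed = 5)
  a2 <- randomized_lasso(y, X, 0.2, seed = 5)
  expect_identical(a1, a2)
})

test_that("harsher weights never help a feature enter", {
  # paired comparison: same data, weight of feature 1 forced to 0.2
  # vs 1.0, all other penalties equal
  set.seed(23)
  n_sel <- c(harsh = 0, lax = 0)
  for (i in 1:60) {
    X <- matrix(rnorm(50 * 10), 50)
    y <- drop(X[, 1] * 0.5) + rnorm(50)
    pf_harsh <- rep(1, 10); pf_harsh[1] <- 1 / 0.2
    pf_lax <- rep(1, 10)
    n_sel["harsh"] <- n_sel["harsh"] +
      (1 %in% lasso_solve(y, X, 0.12, penalty_factor = pf_harsh)$active[[1]])
    n_sel["lax"] <- n_sel["lax"] +
      (1 %in% lasso_solve(y, X, 0.12, penalty_factor = pf_lax)$active[[1]])
  }
  expect_lte(n_sel[["harsh"]], n_sel[["lax"]])
})

test_that("stability_selection bounds null selections and reports sane paths", {
  empty <- 0
  for (s in 1:5) {
    set.seed(s + 400)
    y <- rnorm(100)
    X <- matrix(rnorm(100 * 50), 100)
    ss <- stability_selection(y, X, fp_bound = 1, seed = s)
    if (length(ss$selected) == 0) empty <- empty + 1
    expect_true(all(ss$Pi >= 0 & ss$Pi <= 1))
    # q_bar non-increasing in lambda
    expect_true(all(diff(ss$q_bar[order(ss$grid)]) <= 1e-9))
    expect_gt(ss$lambda_star, min(ss$grid))
    expect_lt(ss$lambda_star, max(ss$grid))
  }
  expect_gte(empty, 4)
})

test_that("stability_selection recovers a strong planted signal", {
  set.seed(24)
  X <- matrix(rnorm(200 * 30), 200)
  y <- drop(X[, c(2, 9)] %*% c(2, -2)) + rnorm(200)
  ss <- stability_selection(y, X, fp_bound = 1, seed = 10)
  expect_true(all(c(2, 9) %in% ss$selected))
  expect_lte(length(ss$selected), 4)
})

test_that("stability_network matches the single-problem engine semantics", {
  # null network: no edges at bound 1
  net0 <- simulate_network(40, 120, 0, seed = 91)
  st0 <- stability_network(net0$Y, fp_bound = 1, seed = 92)
  expect_equal(nrow(st0$edges), 0)
  expect_true(all(st0$lambda_star > min(default_lambda_grid())))
  # symmetric score matrix
  expect_equal(st0$score, t(st0$score))
})

test_that("cv_lasso over-selects strong models; adaptive shrinks the set", {
  set.seed(25)
  X <- matrix(rnorm(150 * 40), 150)
  y <- drop(X[, c(1, 5, 9)] %*% c(2, 2, -2)) + rnorm(150)
  cv <- cv_lasso(y, X, seed = 3)
  expect_true(all(c(1, 5, 9) %in% cv$active))
  expect_gte(length(cv$active), 3)  # typically a superset
  ad <- cv_adaptive_lasso(y, X, seed = 3)
  expect_true(all(ad$active %in% cv$active))
  expect_true(all(c(1, 5, 9) %in% ad$active))
  # deterministic given the seed
  cv2 <- cv_lasso(y, X, seed = 3)
  expect_identical(cv$active, cv2$active)
  expect_equal(cv$lambda_star, cv2$lambda_star)
  # all-zero path on pure noise with tiny n is allowed to be empty
  ad0 <- cv_adaptive_lasso(rnorm(30), matrix(rnorm(30 * 5), 30),
                           seed = 4)
  expect_true(is.list(ad0))
})
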
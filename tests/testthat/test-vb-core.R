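test_that("truncation_bound follows min(1, sqrt(n)/(m+p-1))", {
  expect_equal(truncation_bound(300, 1000), sqrt(300) / 999)
  expect_equal(truncation_bound(300, 1000), 0.017334, tolerance = 5e-4)
  expect_equal(truncation_bound(4, 3), 1)             # capped at 1
  expect_equal(truncation_bound(100, 1, 1e6), 1e-5)
  expect_error(truncation_bound(0, 10), "n")
  expect_error(truncation_bound(10, 1, 0), "m \\+ p - 1")
})

test_that("regression_problem centers and flags degenerate columns", {
  set.seed(4)
  W <- cbind(rnorm(30), rep(2, 30), rnorm(30))
  expect_warning(pr <- regression_problem(rnorm(30) + 5, W),
                 "zero-variance")
  expect_equal(pr$active, c(TRUE, FALSE, TRUE))
  expect_equal(colMeans(pr$W), rep(0, 3), tolerance = 1e-12)
  expect_equal(mean(pr$y), 0, tolerance = 1e-12)
  expect_error(regression_problem(c(1, NA, 3), matrix(1:9, 3)),
               "missing")
})

test_that("init_state is seed-deterministic and valid", {
  prob <- regression_problem(rnorm(50), matrix(rnorm(50 * 20), 50))
  s1 <- init_state(prob, 11)
  s2 <- init_state(prob, 11)
  s3 <- init_state(prob, 12)
  expect_identical(s1$p, s2$p)
  expect_false(identical(s1$p, s3$p))
  expect_true(all(s1$p >= 0 & s1$p <= 1))
  expect_true(all(s1$s2 > 0))
  expect_true(is.finite(lower_bound(s1, prob)))
})

test_that("orthogonal-residual feature update collapses to prior odds", {
  # response built entirely from covariate space: every projection is 0
  set.seed(5)
  n <- 60
  W <- scale(matrix(rnorm(n * 4), n), scale = FALSE)
  y <- rnorm(n)
  y <- y - mean(y)
  y <- y - W %*% solve(crossprod(W), crossprod(W, y))  # orthogonalize
  prob <- regression_problem(y, W)
  st <- init_state(prob, 1)
  st$mu <- rep(0, 4)  # expected fit zero so r = y exactly
  st$r <- prob$y
  st <- update_features(st, prob)
  expect_equal(st$mu, rep(0, 4), tolerance = 1e-10)
  expected_logit <- (st$elog_pi - st$elog1m_pi) +
    0.5 * (st$elog_b + log(st$s2))
  expect_equal(log(st$p / (1 - st$p)), expected_logit, tolerance = 1e-8)
})

test_that("a single strong predictor is found with certainty", {
  set.seed(6)
  x <- rnorm(300)
  y <- 5 * x + rnorm(300)
  fit <- fit_vb(regression_problem(y, matrix(x)), seed = 2)
  expect_true(fit$converged)
  expect_gt(fit$p[1], 1 - 1e-6)
  expect_equal(fit$mu[1], 5, tolerance = 0.1)
})

test_that("duplicate columns split inclusion mass but keep the fit", {
  set.seed(7)
  x <- rnorm(300)
  y <- 3 * x + rnorm(300)
  # duplicated predictor plus noise columns
  W <- cbind(x, x, matrix(rnorm(300 * 8), 300))
  fit2 <- fit_vb(regression_problem(y, W), seed = 3)
  single <- fit_vb(regression_problem(y, matrix(x)), seed = 3)
  expect_gt(fit2$p[1] + fit2$p[2], 0.9)
  tot2 <- fit2$p[1] * fit2$mu[1] + fit2$p[2] * fit2$mu[2]
  tot1 <- single$p[1] * single$mu[1]
  expect_equal(tot2, tot1, tolerance = 0.1)
})

test_that("update_hyperparameters accumulates the sufficient statistics", {
  set.seed(8)
  prob <- regression_problem(rnorm(40), matrix(rnorm(40 * 6), 40))
  st <- init_state(prob, 1)
  st <- update_features(st, prob)
  st <- update_hyperparameters(st, prob)
  expect_equal(st$a_pi, 1 + sum(st$p))
  expect_equal(st$b_pi, 1 + prob$P - sum(st$p))
  expect_equal(st$a_e, 2 + prob$n / 2)
  expect_equal(st$a_b, 2 + sum(st$p) / 2)
  expect_lte(st$pi_mean, prob$bound)
  # empty model: slab factor returns to its prior
  st$p <- rep(0, prob$P); st$mu <- rep(0, prob$P)
  st$r <- prob$y
  st <- update_hyperparameters(st, prob)
  expect_equal(st$a_pi, 1)
  expect_equal(st$b_pi, 1 + prob$P)
  expect_equal(st$a_b, 2)
  expect_equal(st$b_b, 0.5)
})

test_that("update_unpenalized solves exact least squares on covariates", {
  set.seed(9)
  n <- 80
  Tm <- matrix(rnorm(n * 2), n)
  y <- 3 * Tm[, 1] - 2 * Tm[, 2]
  prob <- regression_problem(y, matrix(rnorm(n * 5), n),
                             covariates = Tm)
  st <- init_state(prob, 1)
  st <- update_unpenalized(st, prob)
  expect_equal(unname(st$alpha), c(3, -2), tolerance = 1e-10)
  # gradient of the lower bound w.r.t. alpha vanishes at the update
  L0 <- lower_bound(st, prob)
  for (k in 1:2) {
    eps <- 1e-6
    st2 <- st
    st2$alpha[k] <- st2$alpha[k] + eps
    st2$r <- st$r - eps * Tm[, k]
    st2$unpen_fit <- st$unpen_fit + eps * Tm[, k]
    expect_lt(abs(lower_bound(st2, prob) - L0) / eps, 1e-3)
  }
  # no covariates, centered response: intercept stays 0
  prob0 <- regression_problem(rnorm(30), matrix(rnorm(30 * 3), 30))
  st0 <- update_unpenalized(init_state(prob0, 1), prob0)
  expect_equal(st0$mu0, 0, tolerance = 1e-12)
})

test_that("lower bound is monotone over sweeps on random problems", {
  set.seed(10)
  for (i in 1:15) {
    n <- sample(40:150, 1)
    P <- sample(10:300, 1)
    W <- matrix(rnorm(n * P), n, P)
    nb <- rbinom(1, 6, 0.5)
    beta <- rep(0, P)
    if (nb > 0) beta[sample(P, nb)] <- rnorm(nb, 0, 2)
    y <- drop(W %*% beta) + rnorm(n)
    f <- suppressWarnings(fit_vb(regression_problem(y, W), seed = i,
                                 max_sweeps = 30))
    expect_true(elbo_monotone(f$trace))
  }
})

test_that("lower bound is invariant to feature reordering", {
  set.seed(11)
  prob <- regression_problem(rnorm(50), matrix(rnorm(50 * 12), 50))
  st <- init_state(prob, 5)
  st <- update_features(st, prob)
  L <- lower_bound(st, prob)
  perm <- sample(12)
  prob2 <- prob
  prob2$W <- prob$W[, perm]
  prob2$d <- prob$d[perm]
  prob2$active <- prob$active[perm]
  st2 <- st
  st2$p <- st$p[perm]; st2$mu <- st$mu[perm]; st2$s2 <- st$s2[perm]
  expect_equal(lower_bound(st2, prob2), L, tolerance = 1e-10)
})

test_that("exchangeability: permuted columns give permuted fits", {
  set.seed(12)
  pl <- make_planted(200, 30, c(3, 17), c(2, -2), seed = 12)
  perm <- sample(30)
  f1 <- fit_vb(regression_problem(pl$y, pl$W), seed = 4)
  f2 <- fit_vb(regression_problem(pl$y, pl$W[, perm]), seed = 9)
  expect_equal(f2$p, f1$p[perm], tolerance = 0.01)
})

test_that("null problem: intercept-only evidence approximates the bound", {
  # all p_j driven to ~0: the likelihood part of the bound approaches
  # the expected intercept-only Gaussian log-likelihood under q
  set.seed(13)
  y <- rnorm(200)
  prob <- regression_problem(y, matrix(rnorm(200 * 50), 200))
  f <- fit_vb(prob, seed = 1)
  expect_lt(max(f$p), 0.5)
  ll_ref <- -200 / 2 * log(2 * pi) + 200 / 2 * f$elog_e -
    f$ee / 2 * sum(prob$y^2)
  expect_lt(abs(f$elbo - ll_ref) / abs(ll_ref), 0.25)
})

test_that("fixed-hyperparameter mode matches exact enumeration", {
  ok_sp <- 0; ok_top <- 0
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 150; P <- 8
    W <- matrix(rnorm(n * P), n, P)
    beta <- rep(0, P); beta[sample(P, 2)] <- c(0.4, -0.3)
    y <- drop(W %*% beta) + rnorm(n)
    ex <- exact_enumeration_pip(y, W, 1, 1, 0.2)
    prob <- regression_problem(y, W)
    fx <- list(sigma_e2 = 1, sigma_beta2 = 1, pi = 0.2)
    fits <- lapply(spawn_seeds(seed, 5), function(s)
      suppressWarnings(fit_vb(prob, seed = s, fixed = fx)))
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "elbo"))]]
    ok_sp <- ok_sp +
      (cor(best$p, ex$pip, method = "spearman") >= 0.9)
    ok_top <- ok_top +
      identical(which(best$p > 0.5), which(ex$pip > 0.5))
  }
  expect_equal(ok_sp, 10)
  expect_equal(ok_top, 10)
})

test_that("fit_restarts averages with evidence weights", {
  set.seed(14)
  pl <- make_planted(120, 15, 4, 2.5, seed = 14)
  prob <- regression_problem(pl$y, pl$W)
  # single restart: identity
  f1 <- fit_restarts(prob, n_restarts = 1, master_seed = 7)
  single <- fit_vb(prob, seed = f1$seeds[1])
  expect_equal(f1$p_hat, single$p)
  # weights are a convex combination
  f5 <- fit_restarts(prob, n_restarts = 5, master_seed = 7)
  expect_equal(sum(f5$weights), 1)
  expect_true(all(f5$weights >= 0))
  expect_true(all(f5$p_hat >= 0 & f5$p_hat <= 1))
  # equal lower bounds average equally; 50-nat gap concentrates weight
  w <- exp(c(0, 0) - 0); w <- w / sum(w)
  expect_equal(w, c(0.5, 0.5))
  w2 <- exp(c(0, -50)); w2 <- w2 / sum(w2)
  expect_lt(w2[2], 1e-20)
  # serialization round-trip of the score table
  path <- file.path(withr::local_tempdir(), "fit.tsv")
  write_fit(f5, path)
  tab <- read.delim(path)
  expect_equal(tab$p_hat, f5$p_hat, tolerance = 1e-12)
})

test_that("planted effects are recovered without false positives", {
  hits <- 0
  for (seed in 1:5) {
    pl <- make_planted(300, 200, c(11, 101, 151), c(3, 3, -3),
                       seed = seed + 40)
    fit <- fit_restarts(regression_problem(pl$y, pl$W), n_restarts = 3,
                        master_seed = seed)
    sel <- which(fit$p_hat > 0.99)
    if (identical(sel, c(11L, 101L, 151L))) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
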
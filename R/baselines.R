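# Lasso baselines with bounded type-I error: plain lasso at the
# Meinshausen-Buhlmann penalty, randomized lasso with stability
# selection, and cross-validated (adaptive) lasso.  All solvers share one
# coordinate-descent core in covariance (Gram) form with the objective
#   (2n)^-1 ||y - X beta||^2 + lambda * sum_j pf_j |beta_j|
# on columns standardized to unit variance; coefficients are returned on
# the original scale.

# standardize columns to mean 0, variance 1 (1/n convention, so that the
# Gram diagonal equals n); zero-variance columns get scale NA
std_cols <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sc <- sqrt(colMeans(Xc^2))
  sc[sc == 0] <- NA_real_
  list(x = sweep(Xc, 2L, ifelse(is.na(sc), 1, sc), "/"), center = ctr,
       scale = sc)
}

#' Solve the lasso by coordinate descent
#'
#' Minimizes `(2n)^-1 ||y - X beta||^2 + lambda * sum_j pf_j |beta_j|`.
#' Columns are standardized to unit variance internally and the solution
#' is returned on the original scale together with the KKT subgradient
#' residual certifying optimality.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param lambda penalty (scalar) or decreasing vector for a path.
#' @param penalty_factor per-feature multipliers of `lambda`; `Inf`
#'   excludes a feature.  Default all 1.
#' @param tol coordinate-change convergence tolerance (standardized
#'   scale).
#' @param max_iter maximum full sweeps per lambda.
#' @return object of class `lasso_fit`: `beta` (original scale, one
#'   column per lambda), `beta_std`, `intercept`, `lambda`, `kkt`
#'   (subgradient residual per lambda), `active` (list of active sets).
#' @export
lasso_solve <- function(y, X, lambda, penalty_factor = NULL,
                        tol = 1e-9, max_iter = 100000L) {
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  P <- ncol(X)
  pf <- penalty_factor %||% rep(1, P)
  std <- std_cols(X)
  pf[is.na(std$scale)] <- Inf
  yc <- y - mean(y)
  G <- crossprod(std$x)
  cc <- drop(crossprod(std$x, yc))
  ord <- order(lambda, decreasing = TRUE)
  fit <- lasso_path_gram(G, cc, n, lambda[ord], pf, tol, max_iter)
  bstd <- fit$beta[, order(ord), drop = FALSE]
  kkt <- fit$kkt[order(ord)]
  if (any(kkt > 1e-6))
    warning(sprintf("lasso KKT residual %.2e exceeds 1e-6", max(kkt)))
  baug <- bstd / ifelse(is.na(std$scale), 1, std$scale)
  icpt <- mean(y) - drop(std$center %*% baug)
  structure(list(beta = baug, beta_std = bstd, intercept = icpt,
                 lambda = lambda, kkt = kkt,
                 objective = vapply(seq_along(lambda), function(l) {
                   r <- yc - std$x %*% bstd[, l]
                   sum(r^2) / (2 * n) +
                     lambda[l] * sum((pf * abs(bstd[, l]))[is.finite(pf)])
                 }, numeric(1)),
                 active = apply(bstd != 0, 2L, which, simplify = FALSE)),
            class = "lasso_fit")
}

#' Meinshausen-Buhlmann penalty with bounded type-I error
#'
#' The penalty `lambda(alpha) = (2 sigma_hat / sqrt(n)) *
#' qnorm(alpha / (2 p^2), lower.tail = FALSE)` controls, under the
#' neighborhood-selection construction, the probability `alpha` of
#' falsely connecting two distinct connectivity components, with
#' `sigma_hat = sqrt(mean(y^2))` for the response at hand.
#'
#' @param alpha type-I error probability in (0, 1].
#' @param n sample size.
#' @param p number of variables in the model.
#' @param sigma_hat response scale estimate `sqrt(mean(y^2))`.
#' @return the penalty value.
#' @export
mb_penalty <- function(alpha, n, p, sigma_hat) {
  if (!isTRUE(alpha > 0 && alpha <= 1)) stop("'alpha' must be in (0, 1]")
  if (alpha / (2 * p^2) >= 1)
    stop("alpha / (2 p^2) must be below 1")
  2 * sigma_hat / sqrt(n) * qnorm(alpha / (2 * p^2), lower.tail = FALSE)
}

#' Network selection via the MB penalty bound
#'
#' Regresses every node on all others with the lasso at
#' `lambda(alpha)`, `alpha = fp_bound / #responses`, so that the expected
#' number of network-wide false positives stays below `fp_bound`.
#' Nonzero coefficients become candidate edges; an undirected edge is
#' kept if selected in either direction.
#'
#' @param Y `n x p` node data matrix.
#' @param fp_bound expected false-positive bound for the whole network
#'   (1 or 1000 in the study design).
#' @return list with `edges` (two-column matrix of unordered pairs) and
#'   `lambda` (per-response penalties).
#' @export
bound_via_mb_penalty <- function(Y, fp_bound) {
  Y <- as.matrix(Y)
  p <- ncol(Y); n <- nrow(Y)
  # cap at 1 when the bound exceeds the number of responses (the formula
  # remains defined; the bound is simply loose there)
  alpha <- min(1, fp_bound / p)
  sel <- matrix(FALSE, p, p)
  lam <- numeric(p)
  for (r in seq_len(p)) {
    y <- Y[, r]
    lam[r] <- mb_penalty(alpha, n, p - 1, sqrt(mean(y^2)))
    fit <- lasso_solve(y, Y[, -r, drop = FALSE], lam[r])
    act <- fit$active[[1L]]
    sel[r, seq_len(p)[-r][act]] <- TRUE
  }
  both <- sel | t(sel)
  idx <- which(upper.tri(both) & both, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  list(edges = idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE],
       lambda = lam)
}

#' Randomized lasso
#'
#' Rescales the penalty of each feature by an independent
#' `Uniform(0.2, 1)` weight (equivalent to rescaling the columns) and
#' solves the lasso; the perturbation decorrelates the selection events
#' exploited by stability selection.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param lambda penalty.
#' @param weight_range range of the uniform weights.
#' @param seed integer seed.
#' @return integer vector: the active set (column indices of `X`).
#' @export
randomized_lasso <- function(y, X, lambda, weight_range = c(0.2, 1),
                             seed) {
  if (!isTRUE(lambda > 0)) stop("'lambda' must be positive")
  w <- with_seed(seed, runif(ncol(X), weight_range[1L], weight_range[2L]))
  fit <- lasso_solve(y, X, lambda, penalty_factor = 1 / w)
  fit$active[[1L]]
}

default_lambda_grid <- function() 10^seq(-2, 2, length.out = 100)

# shared stability-selection engine working on the Gram matrix of the
# standardized [y, X] block; returns Pi (P x L) and per-lambda q-bar
stability_engine <- function(Z, response_col, n_subsamples, grid, seeds,
                             weight_range, tol = 1e-7) {
  n <- nrow(Z); P <- ncol(Z) - 1L
  n2 <- floor(n / 2)
  ord <- order(grid, decreasing = TRUE)
  lam_sorted <- grid[ord]
  counts <- matrix(0, P, length(grid))
  qsum <- numeric(length(grid))
  for (s in seq_len(n_subsamples)) {
    rows <- with_seed(seeds[s], sample.int(n, n2))
    w <- with_seed((seeds[s] %% MAX_SEED) + 1L,
                   runif(P, weight_range[1L], weight_range[2L]))
    Zs <- std_cols(Z[rows, , drop = FALSE])
    pf <- 1 / w
    pf[is.na(Zs$scale[-response_col])] <- Inf
    G <- crossprod(Zs$x)
    fit <- lasso_path_gram(G[-response_col, -response_col, drop = FALSE],
                           G[-response_col, response_col], n2,
                           lam_sorted, pf, tol, 100000L)
    selected <- fit$beta != 0
    selected <- selected[, order(ord), drop = FALSE]
    counts <- counts + selected
    qsum <- qsum + colSums(selected)
  }
  list(Pi = counts / n_subsamples, q_bar = qsum / n_subsamples)
}

#' Randomized lasso with stability selection
#'
#' For every penalty on the grid, runs `n_subsamples` randomized-lasso
#' fits on subsamples of `floor(n/2)` observations (response and design
#' standardized within each subsample) and records per-feature selection
#' frequencies `Pi_j(lambda)` and the average selected count
#' `q_bar(lambda)`.  The expected number of false selections obeys
#' `E[V] <= q_bar^2 / ((2 threshold - 1) P)`; the chosen penalty is the
#' smallest grid value whose `q_bar` satisfies `E[V] <= fp_bound`, and
#' features with `Pi_j >= threshold` there are selected.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param grid penalty grid (default 100 log-spaced values in
#'   `[1e-2, 1e2]`).
#' @param n_subsamples number of subsample replicates.
#' @param threshold selection-frequency cutoff.
#' @param fp_bound bound on the expected number of false selections for
#'   this regression.
#' @param seed master seed (spawns one seed per subsample).
#' @param weight_range randomized-lasso weight range.
#' @return object of class `stability_result`: `Pi`, `q_bar`, `grid`,
#'   `lambda_star`, `selected`, `threshold`, `fp_bound`.
#' @export
stability_selection <- function(y, X, grid = default_lambda_grid(),
                                n_subsamples = 100, threshold = 0.9,
                                fp_bound, seed,
                                weight_range = c(0.2, 1)) {
  Z <- cbind(as.numeric(y), as.matrix(X))
  seeds <- spawn_seeds(seed, n_subsamples)
  eng <- stability_engine(Z, 1L, n_subsamples, grid, seeds, weight_range)
  P <- ncol(X)
  pick <- pick_stability_lambda(eng$q_bar, grid, threshold, fp_bound, P)
  sel <- which(eng$Pi[, pick$index] >= threshold)
  structure(list(Pi = eng$Pi, q_bar = eng$q_bar, grid = grid,
                 lambda_star = pick$lambda, selected = sel,
                 threshold = threshold, fp_bound = fp_bound),
            class = "stability_result")
}

pick_stability_lambda <- function(q_bar, grid, threshold, fp_bound,
                                  p_total) {
  q_max <- sqrt(fp_bound * (2 * threshold - 1) * p_total)
  o <- order(grid)
  ok <- q_bar[o] <= q_max
  if (!any(ok))
    stop("no penalty on the grid satisfies the false-positive bound; widen the grid upward")
  idx <- o[which(ok)[1L]]
  if (grid[idx] == min(grid))
    stop("bound satisfied on the lower grid boundary; widen the grid downward")
  list(lambda = grid[idx], index = idx)
}

#' Cross-validated lasso
#'
#' Ten-fold cross-validation over a data-driven penalty grid; the active
#' set at the CV-minimizing penalty, refit on the full data, is returned.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment).
#' @param grid optional penalty grid; defaults to 100 log-spaced values
#'   from the null-model threshold `max |x_j' y| / n` down by 3 decades.
#' @return list with `active`, `lambda_star`, `beta` (full-data refit),
#'   `cv_mse` (per grid value), `grid`.
#' @export
cv_lasso <- function(y, X, folds = 10, seed, grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (n < folds) stop("'folds' cannot exceed the sample size")
  if (is.null(grid)) {
    std <- std_cols(X)
    lmax <- max(abs(crossprod(std$x, y - mean(y)))) / n
    grid <- 10^seq(log10(lmax), log10(lmax) - 3, length.out = 100)
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- lasso_solve(y[tr], X[tr, , drop = FALSE], grid)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta +
      rep(fit$intercept, each = sum(!tr))
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv <- colMeans(err)
  lstar <- grid[which.min(cv)]
  full <- lasso_solve(y, X, lstar)
  list(active = full$active[[1L]], lambda_star = lstar,
       beta = drop(full$beta), intercept = full$intercept,
       cv_mse = cv, grid = grid, fold_id = fold_id)
}

#' Cross-validated adaptive lasso
#'
#' Re-weights the penalty of each feature by `1 / |beta_init|^gamma`
#' with `beta_init` the plain CV-lasso solution (features at zero are
#' excluded outright), then cross-validates the weighted problem.  The
#' selected set is necessarily a subset of the initial support.
#'
#' @inheritParams cv_lasso
#' @param gamma adaptive-weight exponent.
#' @return as [cv_lasso()], plus `init_active`.
#' @export
cv_adaptive_lasso <- function(y, X, folds = 10, gamma = 1, seed,
                              grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  seeds <- spawn_seeds(seed, 2L)
  init <- cv_lasso(y, X, folds = folds, seed = seeds[1L])
  binit <- abs(init$beta)
  if (all(binit == 0))
    return(list(active = integer(0), lambda_star = NA_real_,
                beta = rep(0, ncol(X)), intercept = mean(y),
                init_active = integer(0)))
  pf <- ifelse(binit > 0, 1 / binit^gamma, Inf)
  pf <- pf / min(pf[is.finite(pf)])  # normalize so min factor is 1
  if (is.null(grid)) {
    std <- std_cols(X)
    corr <- abs(crossprod(std$x, y - mean(y))) / n
    lmax <- max((corr / pf)[is.finite(pf)])
    grid <- 10^seq(log10(lmax), log10(lmax) - 3, length.out = 100)
  }
  fold_id <- with_seed(seeds[2L], sample(rep_len(seq_len(folds), n)))
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- lasso_solve(y[tr], X[tr, , drop = FALSE], grid,
                       penalty_factor = pf)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta +
      rep(fit$intercept, each = sum(!tr))
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv <- colMeans(err)
  lstar <- grid[which.min(cv)]
  full <- lasso_solve(y, X, lstar, penalty_factor = pf)
  list(active = full$active[[1L]], lambda_star = lstar,
       beta = drop(full$beta), intercept = full$intercept,
       cv_mse = cv, grid = grid, init_active = init$active)
}

#' Stability-selection network reconstruction
#'
#' Runs [stability_selection()] with every node as the response,
#' splitting the network-wide false-positive bound evenly across
#' responses, with the subsample row sets shared across responses so the
#' standardized Gram matrix is computed once per subsample.  Direction
#' handling follows the study design: selection frequencies at each
#' response's chosen penalty are either averaged across the two
#' directions of regression or combined by maximum before the 0.9
#' cutoff.
#'
#' @param Y `n x p` node data matrix.
#' @param fp_bound network-wide expected false-positive bound.
#' @param n_subsamples,threshold,grid,weight_range as
#'   [stability_selection()].
#' @param seed master seed.
#' @param average average selection frequencies across directions
#'   (`TRUE`) or take the per-direction maximum (`FALSE`).
#' @return list with `edges`, `score` (symmetric p x p frequency
#'   matrix), `lambda_star` (per response).
#' @export
stability_network <- function(Y, fp_bound, n_subsamples = 100,
                              threshold = 0.9,
                              grid = default_lambda_grid(),
                              weight_range = c(0.2, 1), seed,
                              average = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  n2 <- floor(n / 2)
  sub_seeds <- spawn_seeds(seed, n_subsamples)
  w_seeds <- spawn_seeds((seed %% MAX_SEED) + 1L, n_subsamples)
  lam_sorted <- sort(grid, decreasing = TRUE)
  L <- length(grid)
  # the chosen penalty lives where the average selected count is around
  # q_max; once a subsample's path exceeds this cap, smaller penalties
  # cannot influence the choice or the selection, so the solver skips
  # the saturated region (counts there are recorded >= cap, far above
  # the bound, leaving the lambda* decision unchanged)
  per_resp_fp <- fp_bound / p
  q_max <- sqrt(per_resp_fp * (2 * threshold - 1) * (p - 1))
  cap <- max(10L, ceiling(5 * q_max))
  counts <- integer(p * p * L)  # [feature, response, lambda(desc)]
  for (s in seq_len(n_subsamples)) {
    rows <- with_seed(sub_seeds[s], sample.int(n, n2))
    wts <- with_seed(w_seeds[s],
                     matrix(runif(p * p, weight_range[1L],
                                  weight_range[2L]), p, p))
    Zs <- std_cols(Y[rows, , drop = FALSE])
    wts[is.na(Zs$scale), ] <- NA_real_  # zero-variance columns excluded
    G <- crossprod(Zs$x)
    stability_accumulate(G, n2, lam_sorted, wts, 1e-6, 100000L, cap,
                         counts)
  }
  counts <- array(counts / n_subsamples, dim = c(p, p, L))
  lambda_star <- numeric(p)
  freq <- matrix(0, p, p)  # freq[r, j]: Pi_j at response r's lambda*
  for (r in seq_len(p)) {
    q_bar_desc <- colSums(counts[, r, , drop = FALSE][, 1L, ])
    pick <- pick_stability_lambda(q_bar_desc, lam_sorted, threshold,
                                  per_resp_fp, p - 1)
    lambda_star[r] <- pick$lambda
    freq[r, ] <- counts[, r, pick$index]
  }
  score <- if (average) (freq + t(freq)) / 2 else pmax(freq, t(freq))
  keep <- upper.tri(score) & score >= threshold
  idx <- which(keep, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  list(edges = idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE],
       score = score, lambda_star = lambda_star)
}
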
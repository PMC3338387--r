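# Spike-and-slab variational Bayes for one sparse regression.
#
# Model for a response y (one phenotype or expression trait):
#   y_i = mu + sum_j w_ij beta_j + sum_k t_ik alpha_k + e_i
# with w the penalized predictors (other traits + genotypes), t the
# unpenalized covariates (PCs, sex, ...), and
#   beta_j ~ (1 - pi) I[beta = 0] + pi N(0, sigma_beta^2)
#   pi ~ Beta(1, 1) truncated to (0, sqrt(n)/P]
#   sigma_beta^{-2} ~ Gamma(shape 2, rate 1/2)
#   sigma_e^{-2}    ~ Gamma(shape 2, rate 1/2)
# The truncation caps the prior inclusion fraction so the expected model
# size is O(sqrt(n)); this is the mechanism behind the aggressive false
# positive control.  mu and alpha are non-random and estimated by
# maximizing the evidence lower bound.

# Gamma(shape 2, rate 1/2), i.e. prior mean 4 for both precisions.
# Isolated here so a scale-parameter reading would be a one-line change.
GAMMA_PRIOR_SHAPE <- 2
GAMMA_PRIOR_RATE <- 0.5

#' Probabilistic bound on the prior inclusion fraction
#'
#' Returns `min(1, sqrt(n) / (m + p - 1))`, the upper truncation point of
#' the prior on the inclusion fraction.  With this cap the expected number
#' of selected features is at most `sqrt(n)`.
#'
#' @param n sample size.
#' @param p number of phenotypes/traits in the network (the regression has
#'   `p - 1` penalized trait predictors).
#' @param m number of genotype predictors.
#' @return a probability in `(0, 1]`.
#' @export
truncation_bound <- function(n, p, m = 0) {
  if (!isTRUE(n >= 1)) stop("'n' must be a positive integer")
  P <- m + p - 1
  if (!isTRUE(P >= 1)) stop("'m + p - 1' must be at least 1")
  min(1, sqrt(n) / P)
}

#' Construct a spike-and-slab regression problem
#'
#' Mean-centers the response and penalized design, records column norms
#' and the QR factorization of the unpenalized design, and attaches the
#' prior (Beta(1,1) on the inclusion fraction truncated at
#' `sqrt(n)/P`, Gamma(2, rate 1/2) on both precisions).
#'
#' Zero-variance penalized columns cannot carry signal; they are flagged
#' inactive (their inclusion probability is pinned at 0) with a warning.
#'
#' @param y numeric response vector.
#' @param penalized `n x P` matrix of penalized predictors (traits and/or
#'   genotypes).
#' @param covariates optional `n x k` matrix of unpenalized covariates.
#' @param feature_names optional names for the penalized columns.
#' @return an object of class `regression_problem`.
#' @export
regression_problem <- function(y, penalized, covariates = NULL,
                               feature_names = NULL) {
  y <- as.numeric(y)
  W <- as.matrix(penalized)
  n <- length(y)
  if (nrow(W) != n) stop("'penalized' must have length(y) rows")
  if (anyNA(y) || anyNA(W)) stop("missing values are not allowed")
  if (is.null(feature_names))
    feature_names <- colnames(W) %||% paste0("f", seq_len(ncol(W)))
  Tm <- NULL
  if (!is.null(covariates)) {
    Tm <- as.matrix(covariates)
    if (nrow(Tm) != n) stop("'covariates' must have length(y) rows")
    if (anyNA(Tm)) stop("missing values are not allowed")
  }
  W <- center_cols(W)
  d <- colSums(W^2)
  active <- d > 0
  if (any(!active))
    warning(sprintf("%d zero-variance penalized column(s) excluded",
                    sum(!active)))
  Xt <- cbind(`(Intercept)` = rep(1, n), Tm)
  qrT <- qr(Xt)
  if (qrT$rank < ncol(Xt))
    warning("rank-deficient unpenalized design; minimum-norm fit used")
  structure(list(
    y = y - mean(y), ybar = mean(y), W = W, d = d, active = active,
    Tq = qrT, k = if (is.null(Tm)) 0L else ncol(Tm),
    n = n, P = ncol(W), feature_names = feature_names,
    bound = min(1, sqrt(n) / ncol(W))), class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf(
    "regression_problem: n=%d, %d penalized features, %d covariates, inclusion bound %.4g\n",
    x$n, x$P, x$k, x$bound))
  invisible(x)
}

gamma_moments <- function(shape, rate) {
  if (shape <= 0 || rate <= 0)
    stop("degenerate Gamma factor (non-positive shape or rate)")
  list(mean = shape / rate, elog = digamma(shape) - log(rate))
}

#' Initialize a variational state
#'
#' Inclusion probabilities start at independent `Uniform(0.05, 0.95)`
#' draws (slab means at zero) and the hyper-factors at their priors, so
#' that restarts differing only by seed explore different posterior modes.
#'
#' @param problem a [regression_problem()].
#' @param seed integer seed (also drives the sweep orders in [fit_vb()]).
#' @param fixed optional list `list(sigma_e2=, sigma_beta2=, pi=)` pinning
#'   the hyperparameters (used for exact-enumeration validation).
#' @return an object of class `vb_state`.
#' @export
init_state <- function(problem, seed, fixed = NULL) {
  p0 <- with_seed(seed, runif(problem$P, 0.05, 0.95))
  p0[!problem$active] <- 0
  st <- list(p = p0, mu = rep(0, problem$P), s2 = rep(1, problem$P),
             a_pi = 1, b_pi = 1,
             a_b = GAMMA_PRIOR_SHAPE, b_b = GAMMA_PRIOR_RATE,
             a_e = GAMMA_PRIOR_SHAPE, b_e = GAMMA_PRIOR_RATE,
             mu0 = 0, alpha = rep(0, problem$k),
             r = problem$y + 0,  # residual: slab means start at zero
             elbo = -Inf, sweeps = 0L, converged = FALSE,
             seed = as.integer(seed), fixed = fixed)
  st <- refresh_moments(st, problem)
  st$s2 <- 1 / (st$ee * problem$d + st$eb)
  st$s2[!problem$active] <- 1
  class(st) <- "vb_state"
  st
}

# cache the expectations consumed by the feature updates
refresh_moments <- function(state, problem) {
  if (!is.null(state$fixed)) {
    f <- state$fixed
    state$ee <- 1 / f$sigma_e2
    state$eb <- 1 / f$sigma_beta2
    state$elog_e <- -log(f$sigma_e2)
    state$elog_b <- -log(f$sigma_beta2)
    state$elog_pi <- log(f$pi)
    state$elog1m_pi <- log1p(-f$pi)
    state$pi_mean <- f$pi
    state$logZ_pi <- NA_real_
    return(state)
  }
  ge <- gamma_moments(state$a_e, state$b_e)
  gb <- gamma_moments(state$a_b, state$b_b)
  tb <- trunc_beta_moments(state$a_pi, state$b_pi, problem$bound)
  state$ee <- ge$mean; state$elog_e <- ge$elog
  state$eb <- gb$mean; state$elog_b <- gb$elog
  state$elog_pi <- tb$elog; state$elog1m_pi <- tb$elog1m
  state$pi_mean <- tb$mean; state$logZ_pi <- tb$logZ
  state
}

#' Coordinate update of the penalized feature factors
#'
#' For each feature `j` in `order` (all features in index order by
#' default), updates the spike-and-slab factor holding everything else
#' fixed:
#' `s_j^2 = 1 / (E[sigma_e^-2] d_j + E[sigma_beta^-2])`,
#' `mu_j = E[sigma_e^-2] s_j^2 w_j' r_{-j}`, and
#' `logit(p_j) = E[log pi - log(1-pi)] +
#' (E[log sigma_beta^-2] + log s_j^2) / 2 + mu_j^2 / (2 s_j^2)`.
#' The log-moment of the slab precision (not the log of its mean) makes
#' this the exact coordinate-ascent update, so the lower bound can never
#' decrease.
#'
#' @param state a `vb_state`.
#' @param problem the matching [regression_problem()].
#' @param order integer vector of feature indices to update, in order.
#' @return the updated state (residual bookkeeping included).
#' @export
update_features <- function(state, problem, order = seq_len(problem$P)) {
  res <- vb_sweep_cpp(problem$W, problem$d, state$r + 0, state$p + 0,
                      state$mu + 0, state$s2 + 0, state$ee, state$eb, state$elog_b,
                      state$elog_pi - state$elog1m_pi,
                      as.integer(order) - 1L, problem$active)
  state$r <- res$r; state$p <- res$p; state$mu <- res$mu
  state$s2 <- res$s2
  state
}

#' Update the hyperparameter factors
#'
#' `q(pi)` becomes a `Beta(1 + sum p_j, 1 + P - sum p_j)` truncated at the
#' inclusion bound; the slab and noise precision factors are Gamma with
#' shape/rate accumulated from the prior plus the expected sufficient
#' statistics (`sum p_j` and `sum p_j <beta_j^2>` for the slab; `n` and
#' the expected squared residual for the noise).
#'
#' @inheritParams update_features
#' @return the updated state with refreshed moment caches.
#' @export
update_hyperparameters <- function(state, problem) {
  if (!is.null(state$fixed)) return(state)
  sp <- sum(state$p)
  sm2 <- sum(state$p * (state$mu^2 + state$s2))
  state$a_pi <- 1 + sp
  state$b_pi <- 1 + problem$P - sp
  state$a_b <- GAMMA_PRIOR_SHAPE + sp / 2
  state$b_b <- GAMMA_PRIOR_RATE + sm2 / 2
  state$a_e <- GAMMA_PRIOR_SHAPE + problem$n / 2
  state$b_e <- GAMMA_PRIOR_RATE + expected_rss(state, problem) / 2
  refresh_moments(state, problem)
}

# E ||y - mu - T alpha - W beta||^2 under q
expected_rss <- function(state, problem) {
  extra <- sum(problem$d * (state$p * (state$mu^2 + state$s2) -
                              (state$p * state$mu)^2))
  sum(state$r^2) + extra
}

#' Update the unpenalized effects
#'
#' Sets the intercept and covariate effects to the least-squares fit of
#' the partial residual (response minus expected penalized fit) on the
#' unpenalized design, which maximizes the lower bound over these
#' non-random parameters.
#'
#' @inheritParams update_features
#' @return the updated state.
#' @export
update_unpenalized <- function(state, problem) {
  # partial residual: add the current unpenalized fit back onto r
  target <- state$r + (state$unpen_fit %||% rep(0, problem$n))
  gamma <- qr.coef(problem$Tq, target)
  gamma[is.na(gamma)] <- 0
  fit <- drop(qr.fitted(problem$Tq, target))
  state$mu0 <- unname(gamma[1L])
  state$alpha <- gamma[-1L]
  state$unpen_fit <- fit
  state$r <- target - fit
  state
}

# full residual recomputation, used every `recompute_every` sweeps to
# bound incremental floating-point drift
recompute_residual <- function(state, problem) {
  wfit <- drop(problem$W %*% (state$p * state$mu))
  state$r <- problem$y - wfit - (state$unpen_fit %||% rep(0, problem$n))
  state
}

#' Evidence lower bound of a variational state
#'
#' Expected complete-data log-likelihood under the factorized posterior
#' minus the KL divergence from the priors, in natural log.  Exact
#' coordinate updates can never decrease this quantity, which is the
#' primary correctness oracle for the implementation.
#'
#' @inheritParams update_features
#' @return a finite scalar.
#' @export
lower_bound <- function(state, problem) {
  n <- problem$n
  erss <- expected_rss(state, problem)
  ll <- -n / 2 * log(2 * pi) + n / 2 * state$elog_e -
    state$ee / 2 * erss
  p <- state$p[problem$active]
  muv <- state$mu[problem$active]
  s2 <- state$s2[problem$active]
  xlogx <- function(z) ifelse(z > 0, z * log(z), 0)
  feat <- sum(p * (state$elog_pi + state$elog_b / 2 - log(2 * pi) / 2 -
                     state$eb / 2 * (muv^2 + s2)) +
                (1 - p) * state$elog1m_pi -
                xlogx(p) - xlogx(1 - p) +
                p / 2 * (log(2 * pi * s2) + 1))
  if (!is.null(state$fixed)) {
    L <- ll + feat
  } else {
    # KL terms for q(pi) against the truncated-uniform prior (density
    # 1/bound on (0, bound]) and for the two Gamma factors
    pi_term <- -log(problem$bound) + state$logZ_pi -
      (state$a_pi - 1) * state$elog_pi -
      (state$b_pi - 1) * state$elog1m_pi
    gterm <- function(a, b, elog, mean) {
      (GAMMA_PRIOR_SHAPE * log(GAMMA_PRIOR_RATE) -
         lgamma(GAMMA_PRIOR_SHAPE) +
         (GAMMA_PRIOR_SHAPE - 1) * elog - GAMMA_PRIOR_RATE * mean) +
        (a - log(b) + lgamma(a) + (1 - a) * digamma(a))
    }
    L <- ll + feat + pi_term +
      gterm(state$a_e, state$b_e, state$elog_e, state$ee) +
      gterm(state$a_b, state$b_b, state$elog_b, state$eb)
  }
  if (!is.finite(L)) stop("non-finite lower bound")
  L
}

#' Fit one spike-and-slab regression by coordinate-ascent VB
#'
#' Each sweep updates every penalized feature in a fresh random order,
#' then the hyperparameter factors, then the unpenalized effects, and
#' evaluates the lower bound.  Iteration stops when the relative change
#' in the bound falls below `rel_tol` or after `max_sweeps` sweeps
#' (non-convergence sets `converged = FALSE` with a warning, it is not an
#' error).
#'
#' @param problem a [regression_problem()].
#' @param seed integer seed controlling the initialization and the sweep
#'   orders of this run.
#' @param max_sweeps maximum number of sweeps.
#' @param rel_tol convergence tolerance on `|dL| / (1 + |L|)`.
#' @param fixed optional fixed hyperparameters (see [init_state()]).
#' @param keep_trace if `TRUE`, the per-sweep lower-bound trace is kept.
#' @param recompute_every full residual recomputation interval (sweeps).
#' @return a `vb_state` with elements `p` (inclusion probabilities), `mu`
#'   (slab means), `elbo`, `trace`, `converged`, `sweeps`.
#' @export
fit_vb <- function(problem, seed, max_sweeps = 500, rel_tol = 1e-6,
                   fixed = NULL, keep_trace = TRUE,
                   recompute_every = 50L) {
  stopifnot(inherits(problem, "regression_problem"))
  state <- init_state(problem, seed, fixed = fixed)
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_rng)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(as.integer((seed %% MAX_SEED) + 1))
  trace <- numeric(0)
  prev <- -Inf
  for (s in seq_len(max_sweeps)) {
    state <- update_features(state, problem, sample.int(problem$P))
    state <- update_hyperparameters(state, problem)
    state <- update_unpenalized(state, problem)
    if (s %% recompute_every == 0L)
      state <- recompute_residual(state, problem)
    L <- lower_bound(state, problem)
    trace <- c(trace, L)
    state$sweeps <- s
    if (is.finite(prev) && abs(L - prev) / (1 + abs(L)) < rel_tol) {
      state$converged <- TRUE
      state$elbo <- L
      break
    }
    prev <- L
    state$elbo <- L
  }
  if (!state$converged)
    warning(sprintf("VB did not converge in %d sweeps", max_sweeps))
  if (keep_trace) state$trace <- trace
  state
}

#' Multi-restart fit with Bayesian model averaging
#'
#' Runs [fit_vb()] from `n_restarts` seeds spawned from the master seed.
#' The spike-and-slab posterior is multi-modal; each restart lands in one
#' mode, and the restarts are combined by weighting each run by the
#' relative evidence of its mode, `w_r = exp(L_r - max L) / sum(...)`
#' (log-sum-exp stabilized).  The model-averaged inclusion probability is
#' `p_hat_j = sum_r w_r p_j^(r)`.
#'
#' @param problem a [regression_problem()].
#' @param n_restarts number of restarts (at least 1).
#' @param master_seed master seed spawning one child seed per restart.
#' @param ... passed to [fit_vb()].
#' @return object of class `vb_fit` with `p_hat`, `effect` (weighted mean
#'   effect `p_hat_j * mean_r w_r mu_j`), `weights`, `elbo` (per restart),
#'   `seeds`, `restarts` (matrix of per-restart inclusion probabilities),
#'   and `feature_names`.
#' @export
fit_restarts <- function(problem, n_restarts, master_seed, ...) {
  stopifnot(n_restarts >= 1)
  seeds <- spawn_seeds(master_seed, n_restarts)
  runs <- lapply(seeds, function(s)
    suppressWarnings(fit_vb(problem, seed = s, keep_trace = FALSE, ...)))
  L <- vapply(runs, function(r) r$elbo, numeric(1))
  if (!any(is.finite(L)))
    stop("no restart produced a finite lower bound")
  w <- exp(L - max(L, na.rm = TRUE))
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  pmat <- do.call(rbind, lapply(runs, `[[`, "p"))
  mmat <- do.call(rbind, lapply(runs, `[[`, "mu"))
  p_hat <- drop(w %*% pmat)
  effect <- drop(w %*% (pmat * mmat))
  structure(list(p_hat = p_hat, effect = effect, weights = w, elbo = L,
                 seeds = seeds, restarts = pmat,
                 converged = vapply(runs, `[[`, logical(1), "converged"),
                 feature_names = problem$feature_names),
            class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, digits = 3, ...) {
  cat(sprintf("vb_fit: %d restarts, best ELBO %.3f\n",
              length(x$elbo), max(x$elbo)))
  sel <- which(x$p_hat > 0.5)
  if (length(sel)) {
    cat("features with p_hat > 0.5:\n")
    print(data.frame(feature = x$feature_names[sel],
                     p_hat = round(x$p_hat[sel], digits),
                     effect = signif(x$effect[sel], digits)),
          row.names = FALSE)
  } else cat("no features with p_hat > 0.5\n")
  invisible(x)
}

#' Serialize a multi-restart fit to delimited text
#'
#' Writes one row per penalized feature (id, model-averaged inclusion
#' probability, weighted mean effect) and a companion file with the
#' per-restart lower bounds and weights.
#'
#' @param fit a `vb_fit`.
#' @param path output TSV path; the companion file gets the suffix
#'   `"_restarts.tsv"`.
#' @return invisibly, the paths written.
#' @export
write_fit <- function(fit, path) {
  write.table(data.frame(feature = fit$feature_names,
                         p_hat = fit$p_hat, effect = fit$effect),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- sub("(\\.[^.]+)?$", "_restarts.tsv", path)
  write.table(data.frame(restart = seq_along(fit$elbo), seed = fit$seeds,
                         elbo = fit$elbo, weight = fit$weights,
                         converged = fit$converged),
              comp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, comp))
}
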
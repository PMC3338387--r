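# Independent oracles and shared fixtures, built in code.

# Exact posterior inclusion probabilities for a spike-and-slab linear
# model with KNOWN hyperparameters, by enumerating all 2^P supports with
# the conjugate Gaussian evidence (Woodbury/Cholesky form).  Independent
# of the variational code path.
exact_enumeration_pip <- function(y, W, sigma_e2, sigma_b2, pi0) {
  n <- length(y)
  P <- ncol(W)
  W <- scale(W, scale = FALSE)
  y <- y - mean(y)
  logev <- function(S) {
    k <- length(S)
    base <- -n / 2 * log(2 * pi * sigma_e2)
    if (k == 0) return(base - sum(y^2) / (2 * sigma_e2))
    Ws <- W[, S, drop = FALSE]
    M <- diag(k) / sigma_b2 + crossprod(Ws) / sigma_e2
    cM <- chol(M)
    u <- backsolve(cM, crossprod(Ws, y) / sigma_e2, transpose = TRUE)
    base - k / 2 * log(sigma_b2) - sum(log(diag(cM))) -
      (sum(y^2) / sigma_e2 - sum(u^2)) / 2
  }
  lp <- numeric(2^P)
  incl <- matrix(FALSE, 2^P, P)
  for (s in 0:(2^P - 1)) {
    S <- which(bitwAnd(s, 2^(0:(P - 1))) > 0)
    incl[s + 1, S] <- TRUE
    lp[s + 1] <- logev(S) + length(S) * log(pi0) +
      (P - length(S)) * log1p(-pi0)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(pip = colSums(w * incl), map = which(incl[which.max(lp), ]))
}

# planted sparse regression problem used across tests
make_planted <- function(n, P, idx, effect, noise_sd = 1, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(n * P), n, P)
  beta <- rep(0, P)
  beta[idx] <- effect
  y <- drop(W %*% beta) + rnorm(n, sd = noise_sd)
  list(y = y, W = W, beta = beta)
}

elbo_monotone <- function(trace, tol = 1e-8) {
  all(diff(trace) >= -tol * (1 + abs(trace[-1])))
}
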
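# Moments of a Beta(a, b) distribution truncated to (0, bound].
#
# The variational factor for the prior inclusion fraction is a truncated
# Beta; its log-moments feed the prior-odds term of every feature update,
# so they must be accurate to well below the ELBO monotonicity tolerance.
#
# Default route: everything through the log of the truncated normalizer
#   log Z(a, b) = lbeta(a, b) + pbeta(bound, a, b, log.p = TRUE),
# which R evaluates to near machine precision.  Then
#   E[x]        = Z(a+1, b) / Z(a, b)            (exact identity)
#   E[log x]    = d/da log Z(a, b)               (differentiate under
#   E[log(1-x)] = d/db log Z(a, b)                the integral sign)
# with the derivatives taken by central differences.  A Gauss-Legendre
# quadrature over the window where the log-concave density is within
# exp(-45) of its maximum is kept as an independent cross-check route.

# Golub-Welsch nodes/weights for Legendre on [-1, 1]; memoized.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  ev <- eigen(J, symmetric = TRUE)
  x <- rev(ev$values)
  w <- rev(2 * ev$vectors[1L, ]^2)
  .gl_cache[[key]] <- list(x = x, w = w)
  .gl_cache[[key]]
}

log_trunc_beta_Z <- function(a, b, bound) {
  lbeta(a, b) + pbeta(bound, a, b, log.p = TRUE)
}

#' Log-moments of a truncated Beta distribution
#'
#' Computes `E[log(x)]`, `E[log(1 - x)]`, `E[x]` and the log-normalizer
#' of a `Beta(a, b)` distribution restricted to `(0, bound]`.  When
#' `bound >= 1` (no truncation) the digamma closed forms are used.
#' `method = "quadrature"` forces the independent Gauss-Legendre route
#' (used as a cross-check in the test suite).
#'
#' @param a,b Beta shape parameters (positive; the quadrature window
#'   construction assumes `a, b >= 1`, which always holds for the
#'   variational updates in this package).
#' @param bound upper truncation point in `(0, 1]`.
#' @param method `"auto"`, `"quadrature"` or `"closed"` (the latter only
#'   valid untruncated).
#' @param n_nodes number of Gauss-Legendre nodes for the quadrature
#'   route.
#' @return list with `elog` (`E[log x]`), `elog1m` (`E[log(1-x)]`),
#'   `mean` (`E[x]`), `logZ` (log of the truncated normalizing
#'   integral).
#' @export
trunc_beta_moments <- function(a, b, bound,
                               method = c("auto", "quadrature",
                                          "closed"),
                               n_nodes = 128L) {
  method <- match.arg(method)
  stopifnot(a > 0, b > 0, bound > 0)
  if (method == "closed" && bound < 1)
    stop("closed-form moments require bound >= 1")
  if (bound >= 1 && method != "quadrature") {
    return(list(elog = digamma(a) - digamma(a + b),
                elog1m = digamma(b) - digamma(a + b),
                mean = a / (a + b),
                logZ = lbeta(a, b)))
  }
  if (method == "quadrature")
    return(trunc_beta_moments_gl(a, b, min(bound, 1), n_nodes))
  logZ <- log_trunc_beta_Z(a, b, bound)
  # relative steps keep the difference quotient well-conditioned for
  # both small and large shape parameters
  ha <- 1e-4 * max(1, a)
  hb <- 1e-4 * max(1, b)
  list(elog = (log_trunc_beta_Z(a + ha, b, bound) -
                 log_trunc_beta_Z(a - ha, b, bound)) / (2 * ha),
       elog1m = (log_trunc_beta_Z(a, b + hb, bound) -
                   log_trunc_beta_Z(a, b - hb, bound)) / (2 * hb),
       mean = exp(log_trunc_beta_Z(a + 1, b, bound) - logZ),
       logZ = logZ)
}

# independent route: Gauss-Legendre on the window where the log-concave
# integrand is within exp(-45) of its maximum
trunc_beta_moments_gl <- function(a, b, bound, n_nodes) {
  logf <- function(x) (a - 1) * log(x) + (b - 1) * log1p(-x)
  xm <- if (a + b > 2) (a - 1) / (a + b - 2) else bound / 2
  xm <- min(max(xm, .Machine$double.xmin), bound)
  fmax <- if (a > 1) logf(xm) else max(logf(bound / 2), logf(bound), 0)
  drop <- 45
  lo <- 0
  if (a > 1) {
    h <- function(x) logf(x) - (fmax - drop)
    if (h(.Machine$double.eps) < 0 && xm > .Machine$double.eps)
      lo <- uniroot(h, c(.Machine$double.eps, xm),
                    tol = .Machine$double.eps^0.75)$root
  }
  hi <- bound
  if (logf(bound) < fmax - drop && xm < bound) {
    h <- function(x) logf(x) - (fmax - drop)
    hi <- uniroot(h, c(xm, bound), tol = .Machine$double.eps^0.75)$root
  }
  gl <- gauss_legendre(n_nodes)
  half <- (hi - lo) / 2
  x <- lo + half * (gl$x + 1)
  w <- gl$w * half
  g <- exp(logf(x) - fmax)
  Z <- sum(w * g)
  list(elog = sum(w * g * log(x)) / Z,
       elog1m = sum(w * g * log1p(-x)) / Z,
       mean = sum(w * g * x) / Z,
       logZ = fmax + log(Z))
}
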
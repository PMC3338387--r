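#' @useDynLib vbnetrec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats rnorm rbinom runif coef lm qt qnorm pbeta sd var uniroot
#'   integrate setNames quantile
#' @importFrom utils modifyList write.table read.delim
NULL

MAX_SEED <- 2147483646L

#' Spawn child seeds deterministically from a master seed
#'
#' One master seed drives every source of randomness in the package:
#' replicate simulations, restarts, subsamples and fold assignments each
#' receive a child seed drawn here, so that any stage can be reproduced in
#' isolation.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(MAX_SEED, n, replace = FALSE)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Center the columns of a matrix
#' @param x numeric matrix.
#' @return matrix with column means subtracted.
#' @keywords internal
center_cols <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  sweep(x, 2L, colMeans(x), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
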
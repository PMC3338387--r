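# Two-phase network reconstruction: phase 1 regresses each downstream
# phenotype on all expression traits and genotypes; phase 2 regresses
# each expression trait on all other expression traits and genotypes.
# Expression-expression pairs are scored in both directions and the
# posterior inclusion probabilities are averaged before thresholding;
# phenotype-feature and anything-genotype pairs exist in one direction
# only and pass through unchanged.  The final graph is the union of the
# thresholded edges of both phases.

#' Assemble an aligned multi-table dataset
#'
#' @param expression `n x p_expr` numeric matrix (probes in columns).
#' @param genotypes optional `n x m` matrix of additive allele dosages.
#' @param phenotypes optional `n x q` matrix of downstream phenotypes.
#' @param covariates optional `n x c` matrix of extra unpenalized
#'   covariates (e.g. sex).
#' @param sample_ids optional sample identifiers; defaults to the row
#'   names of `expression`.
#' @return object of class `net_dataset`.
#' @export
net_dataset <- function(expression, genotypes = NULL, phenotypes = NULL,
                        covariates = NULL, sample_ids = NULL) {
  expression <- as.matrix(expression)
  n <- nrow(expression)
  sample_ids <- sample_ids %||% rownames(expression) %||%
    paste0("s", seq_len(n))
  chk <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (nrow(x) != n)
      stop(sprintf("'%s' must have the same number of rows as 'expression'", what))
    if (!is.null(rownames(x)) && !identical(rownames(x), sample_ids))
      stop(sprintf("sample ordering of '%s' does not match", what))
    x
  }
  ds <- structure(list(expression = expression,
                       genotypes = chk(genotypes, "genotypes"),
                       phenotypes = chk(phenotypes, "phenotypes"),
                       covariates = chk(covariates, "covariates"),
                       sample_ids = sample_ids), class = "net_dataset")
  for (tbl in c("expression", "genotypes", "phenotypes", "covariates"))
    if (!is.null(ds[[tbl]]) && anyNA(ds[[tbl]]))
      stop(sprintf("'%s' contains missing values; apply the completeness filter first", tbl))
  ds
}

#' @export
print.net_dataset <- function(x, ...) {
  dims <- function(m) if (is.null(m)) 0L else ncol(m)
  cat(sprintf(
    "net_dataset: %d samples, %d expression traits, %d genotypes, %d phenotypes, %d covariates\n",
    length(x$sample_ids), dims(x$expression), dims(x$genotypes),
    dims(x$phenotypes), dims(x$covariates)))
  invisible(x)
}

#' Top principal-component covariates of the expression table
#'
#' Returns the top `k` across-sample eigenvectors (left singular vectors
#' of the column-mean-centered expression matrix, ordered by singular
#' value), used as unpenalized covariates to absorb systematic
#' confounding.  Each component's sign is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param expression `n x p_expr` matrix.
#' @param k number of components (default 20; must be below `n`).
#' @return `n x k` matrix with columns `PC1..PCk`.
#' @export
expression_pcs <- function(expression, k = 20) {
  expression <- as.matrix(expression)
  n <- nrow(expression)
  if (k >= n) stop("'k' must be smaller than the number of samples")
  sv <- svd(center_cols(expression), nu = k, nv = 0)
  U <- sv$u
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("PC", seq_len(ncol(U)))
  U
}

node_names <- function(ds) {
  list(expr = colnames(ds$expression) %||%
         paste0("expr", seq_len(ncol(ds$expression))),
       geno = if (is.null(ds$genotypes)) character(0) else
         colnames(ds$genotypes) %||%
         paste0("marker", seq_len(ncol(ds$genotypes))),
       pheno = if (is.null(ds$phenotypes)) character(0) else
         colnames(ds$phenotypes) %||%
         paste0("pheno", seq_len(ncol(ds$phenotypes))))
}

score_rows <- function(response, role_response, fit, feat_names,
                       feat_roles, phase) {
  data.frame(a = response, b = feat_names, role_a = role_response,
             role_b = feat_roles, p_hat = fit$p_hat, phase = phase,
             row.names = NULL)
}

#' Phase 1: phenotype neighborhoods
#'
#' Fits one multi-restart spike-and-slab regression per downstream
#' phenotype, with all expression traits and genotypes penalized and the
#' expression PCs (plus any extra covariates) unpenalized.
#'
#' @param ds a [net_dataset()] with phenotypes.
#' @param n_restarts restarts per phenotype (study default 1000).
#' @param seed master seed (one child seed per phenotype).
#' @param n_pcs number of expression PCs used as covariates.
#' @param ... passed to [fit_vb()] via [fit_restarts()].
#' @return an edge-score table: one row per (phenotype, feature) ordered
#'   pair with the model-averaged inclusion probability.
#' @export
phase1_phenotypes <- function(ds, n_restarts = 1000, seed, n_pcs = 20,
                              ...) {
  stopifnot(inherits(ds, "net_dataset"), !is.null(ds$phenotypes))
  nm <- node_names(ds)
  W <- cbind(ds$expression, ds$genotypes)
  feat_names <- c(nm$expr, nm$geno)
  feat_roles <- c(rep("expression", length(nm$expr)),
                  rep("genotype", length(nm$geno)))
  Tm <- cbind(expression_pcs(ds$expression, n_pcs), ds$covariates)
  seeds <- spawn_seeds(seed, ncol(ds$phenotypes))
  out <- lapply(seq_len(ncol(ds$phenotypes)), function(q) {
    fit <- tryCatch(
      fit_restarts(regression_problem(ds$phenotypes[, q], W,
                                      covariates = Tm,
                                      feature_names = feat_names),
                   n_restarts = n_restarts, master_seed = seeds[q], ...),
      error = function(e)
        stop(sprintf("phenotype '%s': %s", nm$pheno[q],
                     conditionMessage(e))))
    score_rows(nm$pheno[q], "phenotype", fit, feat_names, feat_roles, 1L)
  })
  do.call(rbind, out)
}

#' Phase 2: expression-trait neighborhoods
#'
#' Fits one multi-restart regression per expression trait on all other
#' expression traits and the genotypes (phenotypes are not predictors in
#' this phase), with the same unpenalized covariates as phase 1.
#'
#' @inheritParams phase1_phenotypes
#' @param n_restarts restarts per trait (study default 50).
#' @return edge-score table of (trait, feature) ordered pairs.
#' @export
phase2_expression <- function(ds, n_restarts = 50, seed, n_pcs = 20,
                              ...) {
  stopifnot(inherits(ds, "net_dataset"))
  nm <- node_names(ds)
  p <- ncol(ds$expression)
  Tm <- cbind(expression_pcs(ds$expression, n_pcs), ds$covariates)
  seeds <- spawn_seeds(seed, p)
  out <- lapply(seq_len(p), function(j) {
    W <- cbind(ds$expression[, -j, drop = FALSE], ds$genotypes)
    feat_names <- c(nm$expr[-j], nm$geno)
    feat_roles <- c(rep("expression", p - 1),
                    rep("genotype", length(nm$geno)))
    fit <- tryCatch(
      fit_restarts(regression_problem(ds$expression[, j], W,
                                      covariates = Tm,
                                      feature_names = feat_names),
                   n_restarts = n_restarts, master_seed = seeds[j], ...),
      error = function(e)
        stop(sprintf("expression trait '%s': %s", nm$expr[j],
                     conditionMessage(e))))
    score_rows(nm$expr[j], "expression", fit, feat_names, feat_roles, 2L)
  })
  do.call(rbind, out)
}

#' Average edge scores across the two directions of regression
#'
#' Pairs scored in both directions (expression-expression) receive the
#' mean of the two inclusion probabilities; pairs that exist in one
#' direction only (phenotype-feature, anything-genotype) pass through
#' unchanged.
#'
#' @param scores an edge-score table from [phase1_phenotypes()] or
#'   [phase2_expression()].
#' @return symmetric score table with columns `node_a`, `node_b`,
#'   `role_a`, `role_b`, `p_sym`, `n_directions`, `phase`.
#' @export
average_directions <- function(scores) {
  a_first <- scores$a <= scores$b
  na <- ifelse(a_first, scores$a, scores$b)
  nb <- ifelse(a_first, scores$b, scores$a)
  ra <- ifelse(a_first, scores$role_a, scores$role_b)
  rb <- ifelse(a_first, scores$role_b, scores$role_a)
  key <- paste(na, nb, sep = "\r")
  agg <- tapply(scores$p_hat, key, mean)
  ndir <- tapply(scores$p_hat, key, length)
  first <- !duplicated(key)
  ord <- match(names(agg), key[first])
  out <- data.frame(node_a = na[first][ord], node_b = nb[first][ord],
                    role_a = ra[first][ord], role_b = rb[first][ord],
                    p_sym = as.numeric(agg),
                    n_directions = as.integer(ndir),
                    phase = scores$phase[first][ord], row.names = NULL)
  out[order(out$node_a, out$node_b), ]
}

#' Build the union network graph from the two phases
#'
#' Retains edges whose direction-averaged score strictly exceeds the
#' threshold in either phase; an edge found in both phases is recorded
#' once with provenance `"both"` and the larger of its two symmetric
#' scores.  Vertices are those incident to a retained edge plus every
#' phenotype.
#'
#' @param phase1 symmetric score table (see [average_directions()]);
#'   may be `NULL`.
#' @param phase2 symmetric score table; may be `NULL`.
#' @param threshold inclusion cutoff (strict inequality; default 0.99).
#' @return object of class `net_graph` with `vertices` (id, role) and
#'   `edges` (node_a, node_b, role_a, role_b, p_sym, provenance).
#' @export
build_union_graph <- function(phase1, phase2, threshold = 0.99) {
  pick <- function(tab, prov) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    keep <- tab[tab$p_sym > threshold, , drop = FALSE]
    if (nrow(keep) == 0) return(NULL)
    keep$provenance <- prov
    keep
  }
  e1 <- pick(phase1, "phase1")
  e2 <- pick(phase2, "phase2")
  edges <- rbind(e1, e2)
  phen <- unique(c(
    if (!is.null(phase1)) c(phase1$node_a[phase1$role_a == "phenotype"],
                            phase1$node_b[phase1$role_b == "phenotype"]),
    if (!is.null(phase2)) c(phase2$node_a[phase2$role_a == "phenotype"],
                            phase2$node_b[phase2$role_b == "phenotype"])))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        role_a = character(0), role_b = character(0),
                        p_sym = numeric(0), provenance = character(0))
  } else {
    key <- paste(edges$node_a, edges$node_b, sep = "\r")
    if (anyDuplicated(key)) {
      split_idx <- split(seq_len(nrow(edges)), key)
      edges <- do.call(rbind, lapply(split_idx, function(ii) {
        e <- edges[ii[which.max(edges$p_sym[ii])], , drop = FALSE]
        if (length(unique(edges$provenance[ii])) > 1)
          e$provenance <- "both"
        e
      }))
    }
    edges <- edges[order(edges$node_a, edges$node_b),
                   c("node_a", "node_b", "role_a", "role_b", "p_sym",
                     "provenance")]
    rownames(edges) <- NULL
  }
  vid <- c(edges$node_a, edges$node_b, phen)
  vrole <- c(edges$role_a, edges$role_b,
             rep("phenotype", length(phen)))
  first <- !duplicated(vid)
  vertices <- data.frame(id = vid[first], role = vrole[first],
                         row.names = NULL)
  vertices <- vertices[order(vertices$id), ]
  rownames(vertices) <- NULL
  structure(list(vertices = vertices, edges = edges,
                 threshold = threshold), class = "net_graph")
}

#' @export
print.net_graph <- function(x, ...) {
  cat(sprintf("net_graph: %d vertices, %d edges (threshold > %g)\n",
              nrow(x$vertices), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Unpenalized OLS refit with confidence intervals
#'
#' Refits a phenotype on the features selected by the network model (plus
#' the unpenalized covariates) in an independent ordinary least-squares
#' regression, and reports t-based confidence intervals, flagging
#' features whose interval covers zero.
#'
#' @param ds a [net_dataset()].
#' @param phenotype phenotype column name.
#' @param features character vector of selected feature names (expression
#'   traits and/or genotypes).
#' @param level confidence level (default 0.95).
#' @param n_pcs number of expression PCs included as covariates.
#' @return data.frame with `feature`, `estimate`, `ci_low`, `ci_high`,
#'   `covers_zero`.
#' @export
refit_ols_ci <- function(ds, phenotype, features, level = 0.95,
                         n_pcs = 20) {
  nm <- node_names(ds)
  y <- ds$phenotypes[, match(phenotype, nm$pheno)]
  feat_mat <- cbind(ds$expression, ds$genotypes)
  colnames(feat_mat) <- c(nm$expr, nm$geno)
  miss <- setdiff(features, colnames(feat_mat))
  if (length(miss))
    stop("unknown features: ", paste(miss, collapse = ", "))
  S <- feat_mat[, features, drop = FALSE]
  Tm <- cbind(expression_pcs(ds$expression, n_pcs), ds$covariates)
  if (ncol(S) + ncol(Tm) + 1 >= length(y))
    stop("selected set plus covariates leaves no residual degrees of freedom")
  X <- cbind(`(Intercept)` = 1, Tm, S)
  fit <- lm(y ~ X - 1)
  cf <- coef(fit)
  feat_idx <- ncol(X) - ncol(S) + seq_len(ncol(S))
  aliased <- is.na(cf)[feat_idx]
  if (any(aliased))
    warning("collinear selected features dropped: ",
            paste(features[aliased], collapse = ", "))
  sm <- summary(fit)$coefficients  # rows only for non-aliased columns
  ok_rows <- paste0("X", colnames(X)[feat_idx][!aliased])
  est <- sm[ok_rows, 1L]
  se <- sm[ok_rows, 2L]
  tq <- qt(1 - (1 - level) / 2, df = fit$df.residual)
  data.frame(feature = features[!aliased], estimate = unname(est),
             ci_low = unname(est - tq * se),
             ci_high = unname(est + tq * se),
             covers_zero = unname((est - tq * se) <= 0 &
                                    (est + tq * se) >= 0),
             row.names = NULL)
}

#' Neighborhood-selection edge scores for a plain node network
#'
#' Simulation-protocol driver: regresses every column of `Y` on all
#' others with the multi-restart spike-and-slab model (no genotypes, no
#' unpenalized covariates) and collects the ordered-pair inclusion
#' probabilities.
#'
#' @param Y `n x p` node data matrix.
#' @param n_restarts restarts per node regression.
#' @param seed master seed (one child per node).
#' @param ... passed to [fit_restarts()].
#' @return `p x p` matrix `S` with `S[a, b]` the model-averaged inclusion
#'   probability of node `b` in the regression of node `a`; diagonal 0.
#' @export
neighborhood_scores <- function(Y, n_restarts = 5, seed, ...) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  seeds <- spawn_seeds(seed, p)
  S <- matrix(0, p, p)
  for (r in seq_len(p)) {
    fit <- fit_restarts(regression_problem(Y[, r],
                                           Y[, -r, drop = FALSE]),
                        n_restarts = n_restarts,
                        master_seed = seeds[r], ...)
    S[r, -r] <- fit$p_hat
  }
  S
}

#' Symmetrize ordered-pair scores
#'
#' `"average"` takes the mean of the two directions (the recommended,
#' conservative rule); `"max"` declares the score of the better-supported
#' direction (the non-averaged rule, where an edge enters if either
#' neighborhood contains it).
#'
#' @param S `p x p` ordered score matrix.
#' @param method `"average"` or `"max"`.
#' @return symmetric `p x p` score matrix.
#' @export
symmetrize_scores <- function(S, method = c("average", "max")) {
  method <- match.arg(method)
  if (method == "average") (S + t(S)) / 2 else pmax(S, t(S))
}

#' Edges of a symmetric score matrix above a threshold
#'
#' @param S_sym symmetric score matrix.
#' @param threshold strict cutoff.
#' @return two-column matrix of unordered pairs with score strictly
#'   above the threshold.
#' @export
edges_at <- function(S_sym, threshold) {
  idx <- which(upper.tri(S_sym) & S_sym > threshold, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
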
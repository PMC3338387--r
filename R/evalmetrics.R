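# Scoring recovered networks against simulated truth: confusion counts
# over unordered node pairs, precision-recall curves, and the replicate
# benchmark protocol comparing the spike-and-slab reconstruction with
# the bounded-type-I-error lasso baselines.

edge_key <- function(edges, p) {
  if (length(edges) == 0) return(integer(0))
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges < 1 | edges > p)) stop("edge indices out of range 1..p")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
  i <- pmin(edges[, 1L], edges[, 2L])
  j <- pmax(edges[, 1L], edges[, 2L])
  unique((i - 1) * p + j)
}

#' Confusion counts between predicted and true edge sets
#'
#' Set arithmetic over unordered node pairs; `power` (recall) is
#' `TP / (TP + FN)`.
#'
#' @param predicted two-column matrix of predicted unordered pairs.
#' @param truth two-column matrix of true unordered pairs.
#' @param p number of nodes.
#' @return list with `tp`, `fp`, `fn`, `tn`, `power`, `precision`
#'   (1 when nothing is predicted, by convention).
#' @export
confusion <- function(predicted, truth, p) {
  pred <- edge_key(predicted, p)
  tru <- edge_key(truth, p)
  tp <- length(intersect(pred, tru))
  fp <- length(setdiff(pred, tru))
  fn <- length(setdiff(tru, pred))
  tn <- p * (p - 1) / 2 - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       power = if (length(tru)) tp / length(tru) else 0,
       precision = if (length(pred)) tp / length(pred) else 1)
}

#' Precision-recall curve of a symmetric edge-score matrix
#'
#' Sweeps the strict threshold over the score support (or a supplied
#' grid) and records precision and recall at each point.  Precision at
#' zero predictions is defined as 1, so the curve is anchored at
#' recall 0.
#'
#' @param S_sym symmetric score matrix.
#' @param truth two-column matrix of true unordered pairs.
#' @param thresholds optional threshold vector; defaults to the sorted
#'   unique scores.
#' @return data.frame of class `pr_curve` with `threshold`, `precision`,
#'   `recall`, `tp`, `fp`.
#' @export
pr_curve <- function(S_sym, truth, thresholds = NULL) {
  p <- ncol(S_sym)
  sc <- S_sym[upper.tri(S_sym)]
  if (is.null(thresholds))
    thresholds <- sort(unique(c(sc, 0, 1)))
  tru <- edge_key(truth, p)
  ut <- which(upper.tri(S_sym))
  keys <- {
    ij <- arrayInd(ut, dim(S_sym))
    (pmin(ij[, 1L], ij[, 2L]) - 1) * p + pmax(ij[, 1L], ij[, 2L])
  }
  is_true <- keys %in% tru
  out <- do.call(rbind, lapply(thresholds, function(t) {
    sel <- sc > t
    tp <- sum(sel & is_true)
    fp <- sum(sel & !is_true)
    data.frame(threshold = t,
               precision = if (tp + fp > 0) tp / (tp + fp) else 1,
               recall = if (length(tru)) tp / length(tru) else 0,
               tp = tp, fp = fp)
  }))
  class(out) <- c("pr_curve", class(out))
  out
}

#' Precision-recall curve of non-averaged (per-regression) scores
#'
#' The non-averaged treatment of direction: every ordered pair keeps the
#' inclusion probability from its own regression, and each directed
#' claim is scored separately against the undirected truth (a true edge
#' can be recovered twice, once per direction).  Averaging the two
#' directions before thresholding ([pr_curve()] on the symmetrized
#' matrix) dominates this curve whenever single-direction false
#' positives occur, which is the operational content of the
#' direction-averaging rule.
#'
#' @param S `p x p` ordered score matrix (`S[a, b]` from the regression
#'   of `a`); the diagonal is ignored.
#' @param truth two-column matrix of true unordered pairs.
#' @param thresholds optional threshold vector; defaults to the sorted
#'   unique scores.
#' @return data.frame of class `pr_curve` with `threshold`, `precision`,
#'   `recall`, `tp`, `fp` (counts over ordered pairs).
#' @export
pr_curve_ordered <- function(S, truth, thresholds = NULL) {
  p <- ncol(S)
  off <- row(S) != col(S)
  sc <- S[off]
  if (is.null(thresholds))
    thresholds <- sort(unique(c(sc, 0, 1)))
  tru <- edge_key(truth, p)
  ij <- which(off, arr.ind = TRUE)
  keys <- (pmin(ij[, 1L], ij[, 2L]) - 1) * p + pmax(ij[, 1L], ij[, 2L])
  is_true <- keys %in% tru
  n_true <- sum(is_true)
  out <- do.call(rbind, lapply(thresholds, function(t) {
    sel <- sc > t
    tp <- sum(sel & is_true)
    fp <- sum(sel & !is_true)
    data.frame(threshold = t,
               precision = if (tp + fp > 0) tp / (tp + fp) else 1,
               recall = if (n_true) tp / n_true else 0,
               tp = tp, fp = fp)
  }))
  class(out) <- c("pr_curve", class(out))
  out
}

#' Area under a precision-recall curve
#'
#' Trapezoidal area over recall, with the curve anchored at
#' `(recall = 0, precision = 1)`.
#'
#' @param curve a [pr_curve()] result.
#' @return scalar area in `[0, 1]`.
#' @export
pr_auc <- function(curve) {
  o <- order(curve$recall, curve$precision)
  r <- c(0, curve$recall[o])
  pr <- c(1, curve$precision[o])
  sum(diff(r) * (pr[-1] + pr[-length(pr)]) / 2)
}

#' Replicate simulation benchmark
#'
#' For each replicate: simulate a network ([simulate_network()]), run the
#' requested reconstruction methods, and score them against the true
#' edge set.  Methods: `"vb"` (spike-and-slab neighborhood selection,
#' scored both direction-averaged and not, thresholded at each value of
#' `thresholds`), `"mb"` (lasso at the MB penalty, `fp_bound` false
#' positives network-wide) and `"stability"` (randomized lasso with
#' stability selection at the same bound).
#'
#' @param config list with `p`, `n`, `edge_prob` (default `1/p`),
#'   `replicates`, `methods` (character subset of
#'   `c("vb", "mb", "stability")`), `thresholds` (default
#'   `c(0.99, 0.5)`), `fp_bounds` (default `c(1, 1000)`), `n_restarts`
#'   (default 5), `seed`.
#' @return a report list (per-replicate results, per-method means, the
#'   config and seeds); serializable to JSON.
#' @export
run_benchmark <- function(config) {
  cfg <- modifyList(list(edge_prob = NULL, thresholds = c(0.99, 0.5),
                         fp_bounds = c(1, 1000), n_restarts = 5,
                         methods = c("vb", "mb", "stability")), config)
  stopifnot(!is.null(cfg$p), !is.null(cfg$n), !is.null(cfg$replicates),
            !is.null(cfg$seed))
  if (is.null(cfg$edge_prob)) cfg$edge_prob <- 1 / cfg$p
  seeds <- spawn_seeds(cfg$seed, cfg$replicates)
  reps <- lapply(seq_len(cfg$replicates), function(rep_i) {
    net <- simulate_network(cfg$p, cfg$n, cfg$edge_prob, seeds[rep_i])
    res <- list()
    ms <- spawn_seeds(seeds[rep_i], 4L)
    if ("vb" %in% cfg$methods) {
      S <- neighborhood_scores(net$Y, n_restarts = cfg$n_restarts,
                               seed = ms[1L])
      # thresholded edge sets: averaged scores vs the union of the two
      # directed neighborhoods; PR curves: averaged symmetric scores vs
      # the per-regression ordered scores
      for (avg in c(TRUE, FALSE)) {
        Ssym <- symmetrize_scores(S, if (avg) "average" else "max")
        tag <- if (avg) "vb_avg" else "vb_raw"
        for (t in cfg$thresholds) {
          cm <- confusion(edges_at(Ssym, t), net$edges, cfg$p)
          res[[sprintf("%s@%g", tag, t)]] <- cm
        }
        res[[paste0(tag, "_pr_auc")]] <- pr_auc(
          if (avg) pr_curve(Ssym, net$edges)
          else pr_curve_ordered(S, net$edges))
      }
    }
    if ("mb" %in% cfg$methods) {
      for (b in cfg$fp_bounds) {
        mb <- bound_via_mb_penalty(net$Y, b)
        res[[sprintf("mb_bound%g", b)]] <-
          confusion(mb$edges, net$edges, cfg$p)
      }
    }
    if ("stability" %in% cfg$methods) {
      for (b in cfg$fp_bounds) {
        st <- stability_network(net$Y, fp_bound = b, seed = ms[2L])
        res[[sprintf("stability_bound%g", b)]] <-
          confusion(st$edges, net$edges, cfg$p)
      }
    }
    list(seed = seeds[rep_i], n_true_edges = nrow(net$edges),
         methods = res)
  })
  keys <- unique(unlist(lapply(reps, function(r) names(r$methods))))
  means <- lapply(setNames(keys, keys), function(k) {
    vals <- lapply(reps, function(r) r$methods[[k]])
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (is.list(vals[[1L]])) {
      as.list(colMeans(do.call(rbind, lapply(vals, function(v)
        unlist(v)))))
    } else mean(unlist(vals))
  })
  list(config = cfg, replicate_seeds = seeds, replicates = reps,
       means = means)
}

#' Write a benchmark report to JSON
#'
#' @param report a [run_benchmark()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
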